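# Condition constructors. Every error raised by the package carries the
# class "gecco_error" plus a specific subclass so callers can branch on the
# failure mode (duplicate paths, dangling rules, linkId skew, ...).

stop_gecco <- function(subclass, message, ...) {
  cond <- structure(
    class = c(paste0("gecco_", subclass, "_error"), "gecco_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' @noRd
gecco_abort_if <- function(test, subclass, message) {
  if (isTRUE(test)) stop_gecco(subclass, message)
  invisible(NULL)
}
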