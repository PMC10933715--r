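# FHIR JSON I/O.  FHIR resources are held as plain R lists shaped exactly
# like their JSON form: repeating elements are unnamed lists (serialized as
# arrays), primitives are length-1 vectors (auto-unboxed).  Reading never
# simplifies, so structure survives a round trip.

#' Read a FHIR resource from JSON
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return The resource as a nested list.
#' @export
read_fhir <- function(path) {
  tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_gecco("parse", paste("cannot parse FHIR JSON:",
                                                  conditionMessage(e)))
  )
}

#' Serialize a FHIR resource to canonical JSON
#'
#' Serialization is deterministic: the same resource always yields the same
#' bytes (2-space pretty printing, no scientific notation, UTF-8).
#'
#' @param resource A FHIR resource list.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
write_fhir <- function(resource, path = NULL) {
  json <- jsonlite::toJSON(resource, auto_unbox = TRUE, pretty = 2,
                           digits = NA, null = "null")
  json <- as.character(json)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

# FHIR coding element from a gecco_coding.
fhir_coding <- function(x) {
  out <- list(system = x$system, code = x$code)
  if (!is.null(x$display)) out$display <- x$display
  out
}

# CodeableConcept carrying one or more codings.
fhir_codeable <- function(codings, text = NULL) {
  out <- list(coding = lapply(codings, fhir_coding))
  if (!is.null(text)) out$text <- text
  out
}

# 32-bit FNV-1a over a string, multiplication split into 16-bit halves so
# intermediates stay within double precision.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    # h * 16777619 mod 2^32, via (hi*2^16 + lo) * prime
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  lo <- as.integer(h %% 65536)
  hi <- as.integer((h - h %% 65536) / 65536)
  sprintf("%04x%04x", hi, lo)
}

# xor for doubles holding 32-bit unsigned values
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer((a - a %% 65536) / 65536),
                as.integer((b - b %% 65536) / 65536))
  hi * 65536 + lo
}

# Deterministic, FHIR-id-safe resource id: short content hash plus a
# readable path tail.  Identical inputs always produce identical ids, so
# re-running a mapping is idempotent.
deterministic_id <- function(...) {
  key <- paste(c(...), collapse = "|")
  tail <- gsub("[^A-Za-z0-9.-]", "-", key)
  tail <- substr(tail, max(1L, nchar(tail) - 50L), nchar(tail))
  tail <- sub("^[.-]+", "", tail)
  id <- paste0(fnv1a32(key), "-", tail)
  substr(id, 1L, 64L)
}
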