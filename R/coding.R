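#' Terminology codings
#'
#' A coding is a triple of a code system URI, a code token and an optional
#' human-readable display, as used by LOINC, SNOMED CT, ICD-10-GM, ATC and
#' the custom code systems of the bundled data set.
#'
#' @param system Canonical URI of the code system.
#' @param code Code token within the system.
#' @param display Optional display text.
#' @return A list of class `gecco_coding`.
#' @export
#' @examples
#' coding("http://snomed.info/sct", "373066001", "Yes")
coding <- function(system, code, display = NULL) {
  if (is.null(system) || !nzchar(system))
    stop_gecco("model_consistency", "coding system must be non-empty")
  if (is.null(code) || !nzchar(as.character(code)))
    stop_gecco("model_consistency", "coding code must be non-empty")
  out <- list(system = system, code = as.character(code))
  if (!is.null(display)) out$display <- display
  class(out) <- "gecco_coding"
  out
}

as_coding <- function(x) {
  if (inherits(x, "gecco_coding")) return(x)
  coding(x$system, x$code, x$display)
}

coding_key <- function(x) paste(x$system, x$code, sep = "|")

#' @export
print.gecco_coding <- function(x, ...) {
  cat(sprintf("<coding> %s | %s%s\n", x$system, x$code,
              if (!is.null(x$display)) paste0(" (", x$display, ")") else ""))
  invisible(x)
}

# Widely used terminology canonical URIs.
SYSTEMS <- list(
  snomed   = "http://snomed.info/sct",
  loinc    = "http://loinc.org",
  icd10gm  = "http://fhir.de/CodeSystem/bfarm/icd-10-gm",
  atc      = "http://fhir.de/CodeSystem/bfarm/atc",
  ucum     = "http://unitsofmeasure.org",
  admin_gender = "http://hl7.org/fhir/administrative-gender",
  gender_de    = "http://fhir.de/CodeSystem/gender-amtlich-de",
  ver_status   = "http://terminology.hl7.org/CodeSystem/condition-ver-status",
  obs_category = "http://terminology.hl7.org/CodeSystem/observation-category",
  consent_scope = "http://terminology.hl7.org/CodeSystem/consentscope",
  consent_category = "http://loinc.org"
)

# SNOMED CT qualifier values for the yes/no/unknown answer scale.
default_ynu_options <- function() {
  list(
    yes     = coding(SYSTEMS$snomed, "373066001", "Yes"),
    no      = coding(SYSTEMS$snomed, "373067005", "No"),
    unknown = coding(SYSTEMS$snomed, "261665006", "Unknown")
  )
}

# SNOMED CT severity qualifier values for the 3-point symptom scale.
default_severity_options <- function() {
  list(
    mild     = coding(SYSTEMS$snomed, "255604002", "Mild"),
    moderate = coding(SYSTEMS$snomed, "6736007", "Moderate"),
    severe   = coding(SYSTEMS$snomed, "24484000", "Severe")
  )
}

# Presence of a finding encoded on Condition.verificationStatus.
default_verification_codings <- function() {
  list(
    yes     = coding(SYSTEMS$ver_status, "confirmed", "Confirmed"),
    no      = coding(SYSTEMS$ver_status, "refuted", "Refuted"),
    unknown = coding(SYSTEMS$ver_status, "unconfirmed", "Unconfirmed")
  )
}

check_unique_codings <- function(codings, where) {
  keys <- vapply(codings, coding_key, character(1))
  gecco_abort_if(anyDuplicated(keys) > 0, "model_consistency",
                 sprintf("duplicate (system, code) pair in %s", where))
  invisible(codings)
}
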