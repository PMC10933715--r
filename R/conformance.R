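#' @title Rule-based conformance checking of mapped bundles
#'
#' @description
#' A lightweight, in-repo analog of an external profile-conformance
#' service: [validate_bundle()] checks a mapped transaction bundle against
#' an explicit, versioned rule catalog derived from the contextual
#' attribute table and the profile descriptions of the underlying data set
#' (exactly one Patient, subject/time attributes per resource type with the
#' Procedure/Immunization exceptions, concept codings present and drawn
#' from registered terminologies, fixed status elements, UCUM units).
#' Full StructureDefinition snapshot validation is out of scope.
#'
#' @name conformance
NULL

#' The conformance rule catalog
#'
#' @return A data frame with one row per rule: `rule_id`, `severity` and
#'   `description`.  `rule_id` values are stable and appear verbatim in
#'   [validate_bundle()] reports.
#' @export
conformance_rules <- function() {
  data.frame(
    rule_id = c("patient-single", "patient-identifier", "resource-type",
                "subject-required", "subject-ref-target", "time-context",
                "time-format", "code-required", "code-unknown",
                "system-registered", "status-fixed", "unit-ucum"),
    severity = "error",
    description = c(
      "bundle contains exactly one Patient resource",
      "the Patient carries a subject identifier",
      "every resource is one of the seven mapped types",
      "non-Patient resources carry their subject-specifying attribute",
      "the subject reference points at the bundle's Patient",
      "Observation/Condition/MedicationStatement carry their context time attribute",
      "time attributes are ISO 8601 dates or datetimes",
      "code-bearing resources carry a code element with at least one coding",
      "at least one coding matches a concept of the logical model",
      "all coding systems are registered terminologies of the model",
      "status and verification elements match the template's fixed values",
      "Observation quantity units match the model's UCUM unit"),
    stringsAsFactors = FALSE
  )
}

SUBJECT_ATTR <- c(Consent = "patient", Observation = "subject",
                  Condition = "subject", Procedure = "subject",
                  MedicationStatement = "subject", Immunization = "patient")
TIME_ATTR <- c(Observation = "effectiveDateTime", Condition = "recordedDate",
               MedicationStatement = "effectiveDateTime")
CODE_ATTR <- c(Observation = "code", Condition = "code", Procedure = "code",
               MedicationStatement = "medicationCodeableConcept",
               Immunization = "vaccineCode")

# All terminology system URIs a model's resources may legitimately use.
registered_systems <- function(model) {
  out <- unlist(SYSTEMS, use.names = FALSE)
  grab <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$system) && !is.null(x$code)) out <<- c(out, x$system)
      for (el in x) grab(el)
    }
  }
  grab(unclass(model))
  unique(out)
}

# Deep-scan a resource for coding-like objects.
collect_resource_codings <- function(resource) {
  out <- list()
  grab <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$system) && !is.null(x$code) && is.character(x$system))
        out[[length(out) + 1L]] <<- x
      for (el in x) grab(el)
    }
  }
  grab(resource)
  out
}

# Leaf node whose concept codings intersect the given codings, or NULL.
model_node_for_codings <- function(model, codings) {
  keys <- vapply(codings, function(cd) paste(cd$system, cd$code, sep = "|"),
                 character(1))
  for (leaf in walk_leaves(model)) {
    leaf_keys <- vapply(leaf$codings, coding_key, character(1))
    if (length(leaf_keys) > 0 && any(leaf_keys %in% keys)) return(leaf)
  }
  NULL
}

is_iso_time <- function(x) {
  is.character(x) && grepl(
    "^\\d{4}-\\d{2}-\\d{2}(T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?(Z|[+-]\\d{2}:\\d{2})?)?$",
    x)
}

ALLOWED_STATUS <- list(
  Observation = c("final", "amended", "corrected"),
  Procedure = c("completed"),
  MedicationStatement = c("active", "not-taken", "unknown"),
  Immunization = c("completed", "not-done"),
  Consent = c("active", "rejected", "proposed")
)

#' Validate a mapped bundle against the conformance rule catalog
#'
#' @param bundle A FHIR transaction Bundle as produced by [map_response()]
#'   (or read with [read_fhir()]).
#' @param model The `gecco_model` the bundle was mapped from.
#' @return A `gecco_validation_report`: a list with `issues` (data frame of
#'   severity, resource_index, rule_id, message), `resources_checked` and
#'   `passed` (`TRUE` iff there are no error-severity issues).
#' @export
#' @examples
#' m <- mini_gecco()
#' r <- generate_responses(render_questionnaire(m), 1, 1, seed = 1)[[1]]
#' validate_bundle(map_response(r, m), m)
validate_bundle <- function(bundle, model) {
  stopifnot(inherits(model, "gecco_model"))
  gecco_abort_if(!is.list(bundle) || !identical(bundle$resourceType, "Bundle"),
                 "parse", "input does not parse as a FHIR Bundle")
  entries <- bundle$entry %||% list()
  resources <- lapply(entries, `[[`, "resource")
  types <- vapply(resources, function(r) r$resourceType %||% "", character(1))

  issues <- list()
  add <- function(rule, message, index = NA_integer_, severity = "error") {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, resource_index = index, rule_id = rule,
      message = message, stringsAsFactors = FALSE)
  }

  n_patient <- sum(types == "Patient")
  if (n_patient != 1)
    add("patient-single", sprintf("bundle has %d Patient resources, expected exactly 1",
                                  n_patient))
  patient_ref <- if (n_patient >= 1) {
    pid <- resources[[which(types == "Patient")[1]]]$id
    paste0("Patient/", pid %||% "")
  } else ""
  if (n_patient >= 1) {
    p <- resources[[which(types == "Patient")[1]]]
    if (length(p$identifier %||% list()) == 0)
      add("patient-identifier", "Patient has no subject identifier",
          which(types == "Patient")[1])
  }

  systems <- registered_systems(model)

  for (i in seq_along(resources)) {
    res <- resources[[i]]
    rt <- types[i]
    if (!rt %in% RESOURCE_TYPES) {
      add("resource-type", sprintf("resource type '%s' is not mapped by the data set", rt), i)
      next
    }
    if (rt != "Patient") {
      sattr <- SUBJECT_ATTR[[rt]]
      ref <- res[[sattr]]$reference
      if (is.null(ref)) {
        add("subject-required",
            sprintf("%s lacks its subject attribute %s.%s", rt, rt, sattr), i)
      } else if (!identical(ref, patient_ref)) {
        add("subject-ref-target",
            sprintf("%s.%s references '%s', not the bundle Patient '%s'",
                    rt, sattr, ref, patient_ref), i)
      }
    }
    tattr <- TIME_ATTR[rt]
    if (!is.na(tattr)) {
      val <- res[[tattr]]
      if (is.null(val)) {
        add("time-context",
            sprintf("%s lacks its context time attribute %s.%s", rt, rt, tattr), i)
      } else if (!is_iso_time(val)) {
        add("time-format", sprintf("%s.%s is not an ISO 8601 time: '%s'",
                                   rt, tattr, val), i)
      }
    }
    # Procedure/Immunization times are answer-driven; when present they
    # still have to be well-formed.
    for (aattr in c("performedDateTime", "occurrenceDateTime")) {
      if (!is.null(res[[aattr]]) && !is_iso_time(res[[aattr]]))
        add("time-format", sprintf("%s.%s is not an ISO 8601 time: '%s'",
                                   rt, aattr, res[[aattr]]), i)
    }

    cattr <- CODE_ATTR[rt]
    node <- NULL
    if (!is.na(cattr)) {
      concept <- res[[cattr]]
      if (is.null(concept) || length(concept$coding %||% list()) == 0) {
        add("code-required",
            sprintf("%s lacks a %s element with codings", rt, cattr), i)
      } else {
        node <- model_node_for_codings(model, concept$coding)
        if (is.null(node)) {
          add("code-unknown",
              sprintf("no logical-model concept matches the codings of this %s", rt), i)
        }
      }
    }

    for (cd in collect_resource_codings(res)) {
      if (!cd$system %in% systems) {
        add("system-registered",
            sprintf("coding system '%s' is not registered in the model", cd$system), i)
      }
    }

    if (rt == "Condition") {
      vs <- res$verificationStatus$coding %||% list()
      ok <- length(vs) > 0 && any(vapply(vs, function(cd) {
        any(vapply(model$settings$verification_codings,
                   function(v) same_coding(cd, v), logical(1)))
      }, logical(1)))
      if (!ok) add("status-fixed",
                   "Condition.verificationStatus is missing or not a registered presence coding", i)
    } else if (rt != "Patient") {
      allowed <- ALLOWED_STATUS[[rt]]
      if (!is.null(allowed) && !(res$status %||% "") %in% allowed)
        add("status-fixed",
            sprintf("%s.status '%s' is not among the template's fixed values (%s)",
                    rt, res$status %||% "<missing>", paste(allowed, collapse = "/")), i)
    }

    if (rt == "Observation" && !is.null(res$valueQuantity) && !is.null(node)) {
      want <- node$answer$unit
      got <- res$valueQuantity$code %||% ""
      if (!is.null(want) && !identical(got, want))
        add("unit-ucum", sprintf("Observation unit '%s' does not match the model unit '%s'",
                                 got, want), i)
    }
  }

  issues_df <- if (length(issues) > 0) do.call(rbind, issues) else
    data.frame(severity = character(0), resource_index = integer(0),
               rule_id = character(0), message = character(0),
               stringsAsFactors = FALSE)
  structure(
    list(issues = issues_df,
         resources_checked = length(resources),
         passed = !any(issues_df$severity == "error")),
    class = "gecco_validation_report"
  )
}

#' @export
print.gecco_validation_report <- function(x, ...) {
  verdict <- if (x$passed) "PASSED" else "FAILED"
  cat(sprintf("<validation report> %s — %d resource(s) checked, %d issue(s)\n",
              verdict, x$resources_checked, nrow(x$issues)))
  if (nrow(x$issues) > 0) {
    for (j in seq_len(nrow(x$issues))) {
      cat(sprintf("  [%s] %s (resource %s): %s\n",
                  x$issues$severity[j], x$issues$rule_id[j],
                  x$issues$resource_index[j], x$issues$message[j]))
    }
  }
  invisible(x)
}

# JSON-serializable form of a report (used by the CLI and pipeline).
report_to_list <- function(report) {
  list(passed = report$passed,
       resources_checked = report$resources_checked,
       issues = report$issues)
}
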