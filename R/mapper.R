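#' @title Mapping QuestionnaireResponses to profiled FHIR resources
#'
#' @description
#' [map_response()] is the core transformation: it binds an annotated
#' QuestionnaireResponse to the logical model via the per-item path
#' extensions and emits a FHIR transaction Bundle of profiled resources —
#' one Patient per bundle plus one resource per answered, template-bearing
#' element.  Contextual attributes (subject reference, recording time) are
#' filled per resource type by [resolve_context()]; category-level meta
#' elements answered "no"/"unknown" are expanded into refuted/unconfirmed
#' Conditions for all their children by [expand_meta()].
#'
#' @name gecco-mapper
NULL

same_coding <- function(a, b) {
  identical(a$code, b$code) &&
    (is.null(a$system) || is.null(b$system) || identical(a$system, b$system))
}

# "yes" / "no" / "unknown" token for a drawn coding, or NA.
ynu_token <- function(model, value_coding) {
  for (tok in names(model$settings$ynu_options)) {
    if (same_coding(value_coding, model$settings$ynu_options[[tok]])) return(tok)
  }
  NA_character_
}

#' Contextual attribute assignment per resource type
#'
#' Returns, for one of the seven mapped resource types, which attribute
#' carries the subject reference and which carries the recording time, and
#' the values to fill in.  Patient gets neither; Consent gets only the
#' subject; for Procedure and Immunization the time attribute is
#' deliberately *not* context-filled — their dates are domain data and must
#' come from answer content.
#'
#' @param resource_type One of Patient, Consent, Observation, Condition,
#'   Procedure, MedicationStatement, Immunization.
#' @param ctx Binding context: a list with `subject_id`, `authored` and
#'   optionally `patient_ref` (defaults to the deterministic Patient id).
#' @return A list with components `subject` (`NULL` or
#'   `list(attr, reference)`) and `time` (`NULL` or `list(attr, value)`).
#' @export
resolve_context <- function(resource_type, ctx) {
  gecco_abort_if(!resource_type %in% RESOURCE_TYPES, "unknown_resource_type",
                 sprintf("'%s' is not a mapped resource type", resource_type))
  patient_ref <- ctx$patient_ref %||%
    paste0("Patient/", deterministic_id(ctx$subject_id, "Patient", ctx$authored))
  subject_attr <- switch(resource_type,
    Patient = NULL,
    Consent = "patient",
    Immunization = "patient",
    "subject")
  time_attr <- switch(resource_type,
    Observation = "effectiveDateTime",
    Condition = "recordedDate",
    MedicationStatement = "effectiveDateTime",
    NULL)  # Patient, Consent: N/A; Procedure, Immunization: answer-driven
  list(
    subject = if (!is.null(subject_attr))
      list(attr = subject_attr, reference = list(reference = patient_ref)),
    time = if (!is.null(time_attr))
      list(attr = time_attr, value = ctx$authored)
  )
}

check_answer_value <- function(node, part, ans, model) {
  fail <- function(what) {
    stop_gecco("value_domain",
               sprintf("answer for '%s%s' %s", node$path,
                       if (is.na(part)) "" else paste0(".", part), what))
  }
  if (!is.na(part)) {
    if (part == "date") {
      if (is.null(ans$valueDate)) fail("must be a date")
    } else {
      ok <- !is.null(ans$valueCoding) &&
        any(vapply(model$settings$severity_options,
                   function(cd) same_coding(ans$valueCoding, cd), logical(1)))
      if (!ok) fail("is not on the severity scale")
    }
    return(invisible(TRUE))
  }
  kind <- node$answer$kind
  if (kind %in% c("yes_no_unknown", "yes_no_unknown_with_date",
                  "yes_no_unknown_with_severity")) {
    if (is.null(ans$valueCoding) || is.na(ynu_token(model, ans$valueCoding)))
      fail("is not a yes/no/unknown option")
  } else if (kind == "coded_choice") {
    ok <- !is.null(ans$valueCoding) &&
      any(vapply(node$answer$options,
                 function(o) same_coding(ans$valueCoding, o$coding), logical(1)))
    if (!ok) fail("is not among the defined answer options")
  } else if (kind == "quantity") {
    q <- ans$valueQuantity
    if (is.null(q) || is.null(q$value)) fail("must be a quantity")
    if (!is.null(q$code) && !identical(q$code, node$answer$unit))
      fail(sprintf("has unit '%s' but the model requires '%s'",
                   q$code, node$answer$unit))
  } else if (kind == "date") {
    if (is.null(ans$valueDate)) fail("must be a date")
  } else if (kind == "datetime") {
    if (is.null(ans$valueDateTime)) fail("must be a dateTime")
  } else if (kind == "text") {
    if (is.null(ans$valueString)) fail("must be a string")
  } else if (kind == "integer") {
    if (is.null(ans$valueInteger)) fail("must be an integer")
  }
  invisible(TRUE)
}

map_gender_code <- function(code) {
  switch(code, male = "male", female = "female", unknown = "unknown", "other")
}

#' Instantiate a profile template for one answered element
#'
#' Builds a single profiled FHIR resource from a template, the model node
#' it maps, the typed answer record and the binding context.  Used
#' internally by [map_response()]; exposed for targeted transformations of
#' individual items.
#'
#' @param template A `gecco_template` from the model's registry.
#' @param node The `gecco_node` being mapped.
#' @param answer Answer record: `list(main = <answer>, date = <answer>,
#'   severity = <answer>)` (parts optional).
#' @param ctx Binding context as for [resolve_context()].
#' @param model The `gecco_model` (settings and canonical base).
#' @param forced_status For meta-element expansion: `"no"` or `"unknown"`
#'   to force the presence status without consulting `answer`.
#' @return A FHIR resource list.
#' @export
apply_template <- function(template, node, answer, ctx, model,
                           forced_status = NULL) {
  rt <- template$resource_type
  res <- list(
    resourceType = rt,
    id = deterministic_id(ctx$subject_id, node$path, ctx$authored),
    meta = list(profile = list(
      template$profile %||%
        paste0(model$canonical_base, "/StructureDefinition/", template$id)))
  )
  context <- resolve_context(rt, ctx)
  fixed <- template$fixed
  main <- answer$main
  token <- forced_status
  if (is.null(token) && !is.null(main$valueCoding) &&
      node$answer$kind %in% c("yes_no_unknown", "yes_no_unknown_with_date",
                              "yes_no_unknown_with_severity")) {
    token <- ynu_token(model, main$valueCoding)
  }

  bind_error <- function(msg) stop_gecco("template_binding",
                                         sprintf("node '%s': %s", node$path, msg))

  if (rt == "Patient") {
    res$meta <- NULL  # merged into the bundle Patient; no own profile tag
    if (identical(node$answer$kind, "coded_choice") && !is.null(main$valueCoding)) {
      res$gender <- map_gender_code(main$valueCoding$code)
    } else if (identical(node$answer$kind, "date") && !is.null(main$valueDate)) {
      res$birthDate <- main$valueDate
    } else bind_error("no Patient field binding for this answer kind")
    return(res)
  }

  if (rt == "Condition") {
    ver <- model$settings$verification_codings[[token %||% "unknown"]]
    if (is.null(ver)) bind_error("answer does not map to a presence status")
    res$verificationStatus <- fhir_codeable(list(ver))
    if (!is.null(fixed$category))
      res$category <- list(fhir_codeable(list(fixed$category)))
    if (is.null(forced_status) && identical(token, "yes") &&
        !is.null(answer$severity$valueCoding)) {
      sev <- answer$severity$valueCoding
      res$severity <- list(coding = list(sev))
    }
    res$code <- fhir_codeable(node$codings, text = node$question)
  } else if (rt == "Observation") {
    res$status <- fixed$status %||% "final"
    if (!is.null(fixed$category))
      res$category <- list(fhir_codeable(list(fixed$category)))
    res$code <- fhir_codeable(node$codings, text = node$question)
    kind <- node$answer$kind
    if (kind == "quantity") {
      res$valueQuantity <- list(value = main$valueQuantity$value,
                                unit = node$answer$unit,
                                system = SYSTEMS$ucum,
                                code = node$answer$unit)
    } else if (kind == "datetime") {
      res$valueDateTime <- main$valueDateTime
    } else if (kind == "text") {
      res$valueString <- main$valueString
    } else if (kind == "integer") {
      res$valueInteger <- main$valueInteger
    } else if (kind == "coded_choice") {
      res$valueCodeableConcept <- list(coding = list(main$valueCoding))
    } else bind_error("no Observation value binding for this answer kind")
  } else if (rt == "Procedure") {
    res$status <- fixed$status %||% "completed"
    if (!is.null(fixed$category))
      res$category <- fhir_codeable(list(fixed$category))
    res$code <- fhir_codeable(node$codings, text = node$question)
    if (is.null(main$valueDate)) bind_error("Procedure needs a date answer")
    res$performedDateTime <- main$valueDate  # answer-driven, never the context
  } else if (rt == "MedicationStatement") {
    if (is.null(token)) bind_error("MedicationStatement needs a yes/no/unknown answer")
    res$status <- switch(token, yes = "active", no = "not-taken", "unknown")
    res$medicationCodeableConcept <- fhir_codeable(node$codings,
                                                   text = node$question)
  } else if (rt == "Immunization") {
    if (is.null(token)) bind_error("Immunization needs a yes/no/unknown answer")
    res$status <- if (identical(token, "yes")) "completed" else "not-done"
    if (identical(token, "unknown")) {
      res$statusReason <- fhir_codeable(list(model$settings$ynu_options$unknown))
    }
    res$vaccineCode <- fhir_codeable(node$codings, text = node$question)
    if (identical(token, "yes") && !is.null(answer$date$valueDate)) {
      res$occurrenceDateTime <- answer$date$valueDate  # answer-driven (not context)
    } else {
      res$occurrenceString <- "unknown"
    }
  } else if (rt == "Consent") {
    if (is.null(token)) bind_error("Consent needs a yes/no/unknown answer")
    res$status <- switch(token, yes = "active", no = "rejected", "proposed")
    if (!is.null(fixed$scope)) res$scope <- fhir_codeable(list(fixed$scope))
    if (!is.null(fixed$category))
      res$category <- list(fhir_codeable(list(fixed$category)))
    if (!is.null(fixed$policy_uri))
      res$policy <- list(list(uri = fixed$policy_uri))
  }

  if (!is.null(context$subject))
    res[[context$subject$attr]] <- context$subject$reference
  if (!is.null(context$time))
    res[[context$time$attr]] <- context$time$value
  res
}

#' Expand a meta element into per-child Condition resources
#'
#' Category-level ("meta") elements gate a block of disease items.  When
#' the category question is answered "no" or "unknown", no child item was
#' shown to the patient, yet the data set still expects one Condition per
#' disease: each child is emitted with a refuted (for "no") or unconfirmed
#' (for "unknown") verification status, ignoring any child answers.  When
#' the category is answered "yes", the children are mapped individually
#' from their own answers in the response.
#'
#' @param category_answer `"yes"`, `"no"` or `"unknown"`.
#' @param category_node The meta `gecco_node` (must have `is_meta`).
#' @param response The QuestionnaireResponse (consulted only for
#'   `category_answer == "yes"` and for the binding context).
#' @param model The `gecco_model`.
#' @return A list of Condition resources.
#' @export
expand_meta <- function(category_answer, category_node, response, model) {
  gecco_abort_if(!isTRUE(category_node$is_meta), "model_consistency",
                 sprintf("'%s' is not a meta element", category_node$path))
  ctx <- response_context(response)
  templates <- model$templates
  for (child in category_node$children) {
    tpl <- templates[[child$template %||% ""]]
    gecco_abort_if(is.null(tpl) || !identical(tpl$resource_type, "Condition"),
                   "model_consistency",
                   sprintf("meta element '%s' has non-Condition child '%s'",
                           category_node$path, child$path))
  }
  if (category_answer %in% c("no", "unknown")) {
    return(lapply(category_node$children, function(child) {
      apply_template(templates[[child$template]], child, list(), ctx, model,
                     forced_status = category_answer)
    }))
  }
  # "yes": map answered children from their own answers
  records <- collect_answers(response, model)
  out <- list()
  for (child in category_node$children) {
    rec <- records[[child$path]]
    if (is.null(rec)) next
    out[[length(out) + 1L]] <-
      apply_template(templates[[child$template]], child, rec, ctx, model)
  }
  out
}

response_context <- function(response) {
  subject_id <- response$subject$identifier$value
  authored <- response$authored
  gecco_abort_if(is.null(subject_id) || is.null(authored), "context",
                 "response must carry a subject identifier and an authored timestamp")
  list(subject_id = subject_id, authored = authored,
       patient_ref = paste0("Patient/",
                            deterministic_id(subject_id, "Patient", authored)))
}

# Flatten a response into per-node answer records keyed by model path:
# list(node, main, date, severity).  Enforces annotation, path kind,
# value-domain and single-occurrence rules.
collect_answers <- function(response, model) {
  records <- list()
  seen <- character(0)
  visit <- function(items) {
    for (it in items) {
      if (length(it$answer %||% list()) > 0) {
        path <- item_gecco_path(it)
        gecco_abort_if(is.na(path), "unmapped_item",
                       sprintf("answered item '%s' carries no logical-model path annotation",
                               it$linkId %||% "<no linkId>"))
        resolved <- resolve_path(model, path)
        gecco_abort_if(is.null(resolved), "unmapped_item",
                       sprintf("annotated path '%s' does not resolve in the model", path))
        gecco_abort_if(is.null(resolved$node$answer), "path_kind",
                       sprintf("annotated path '%s' resolves to a group, not an answerable element",
                               path))
        gecco_abort_if(path %in% seen, "duplicate_answer",
                       sprintf("model element '%s' is answered more than once", path))
        seen <<- c(seen, path)
        ans <- it$answer[[1]]
        check_answer_value(resolved$node, resolved$part, ans, model)
        key <- resolved$node$path
        rec <- records[[key]] %||% list(node = resolved$node)
        rec[[if (is.na(resolved$part)) "main" else resolved$part]] <- ans
        records[[key]] <<- rec
      }
      if (!is.null(it$item)) visit(it$item)
    }
  }
  visit(response$item %||% list())
  records
}

#' Map an annotated QuestionnaireResponse to a profiled resource bundle
#'
#' @param response A FHIR R4 QuestionnaireResponse whose answered items
#'   carry logical-model path annotations (run [annotate_response()] first
#'   if they do not) and which has a subject identifier and an `authored`
#'   timestamp.
#' @param model The `gecco_model` the annotations refer to.
#' @return A FHIR R4 transaction Bundle (nested list) with exactly one
#'   Patient — identified by the response's subject token, carrying any
#'   answered demographics — plus one profiled resource per answered,
#'   template-bearing element; meta elements answered "no"/"unknown"
#'   contribute one Condition per child via [expand_meta()].  Resource ids
#'   are deterministic in (subject, path, authored), so remapping the same
#'   response is idempotent.
#' @export
#' @examples
#' m <- mini_gecco()
#' q <- render_questionnaire(m)
#' r <- generate_responses(q, 1, 1, seed = 7)[[1]]
#' b <- map_response(r, m)
#' vapply(b$entry, function(e) e$resource$resourceType, character(1))
map_response <- function(response, model) {
  stopifnot(inherits(model, "gecco_model"))
  gecco_abort_if(!identical(response$resourceType, "QuestionnaireResponse"),
                 "parse", "input is not a FHIR QuestionnaireResponse")
  ctx <- response_context(response)
  records <- collect_answers(response, model)

  # Patient: always emitted, identifier = subject token, demographics merged.
  patient <- list(
    resourceType = "Patient",
    id = deterministic_id(ctx$subject_id, "Patient", ctx$authored),
    identifier = list(list(system = SUBJECT_ID_SYSTEM, value = ctx$subject_id))
  )
  consumed <- character(0)
  for (rec in records) {
    tpl <- model$templates[[rec$node$template %||% ""]]
    if (!is.null(tpl) && identical(tpl$resource_type, "Patient")) {
      part <- apply_template(tpl, rec$node, rec, ctx, model)
      if (!is.null(part$gender)) patient$gender <- part$gender
      if (!is.null(part$birthDate)) patient$birthDate <- part$birthDate
      consumed <- c(consumed, rec$node$path)
    }
  }

  resources <- list(patient)

  # Meta-element expansion.
  for (node in model_nodes(model)) {
    if (!node$is_meta || is.null(node$enable)) next
    gate <- records[[node$enable$path]]
    if (is.null(gate) || is.null(gate$main$valueCoding)) next
    token <- ynu_token(model, gate$main$valueCoding)
    if (is.na(token)) next
    child_paths <- vapply(node$children, `[[`, character(1), "path")
    consumed <- c(consumed, child_paths)
    resources <- c(resources, expand_meta(token, node, response, model))
  }

  # Ordinary template-bearing leaves.
  for (leaf in walk_leaves(model)) {
    if (leaf$path %in% consumed) next
    rec <- records[[leaf$path]]
    if (is.null(rec) || is.null(rec$main)) next
    tpl <- model$templates[[leaf$template %||% ""]]
    if (is.null(tpl)) next
    resources[[length(resources) + 1L]] <-
      apply_template(tpl, leaf, rec, ctx, model)
  }

  list(
    resourceType = "Bundle",
    id = deterministic_id(ctx$subject_id, "Bundle",
                          response$id %||% "", ctx$authored),
    type = "transaction",
    entry = lapply(resources, function(r) list(
      fullUrl = paste0(model$canonical_base, "/", r$resourceType, "/", r$id),
      resource = r,
      request = list(method = "PUT",
                     url = paste0(r$resourceType, "/", r$id))
    ))
  )
}
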