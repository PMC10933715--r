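#' @title Reference-questionnaire generation
#'
#' @description
#' [render_questionnaire()] turns a logical model into an annotated FHIR R4
#' Questionnaire: one item per model node with the hierarchy preserved,
#' deterministic hierarchical linkIds, answerOptions with exactly one coding
#' each, enableWhen conditions, and a path annotation extension
#' (`.../StructureDefinition/compass-gecco-item`) on every item so that
#' responses can later be bound back to the model.
#'
#' @name questionnaire-gen
NULL

ITEM_EXT_SUFFIX <- "/StructureDefinition/compass-gecco-item"

item_extension_url <- function(model) {
  paste0(model$canonical_base, ITEM_EXT_SUFFIX)
}

#' Hierarchical linkId scheme
#'
#' Maps tree coordinates (1-based positions along the path from the root)
#' to a linkId token: `c(1)` is `"1"`, `c(1, 2)` is `"1.2"`.  The scheme is
#' injective, so linkIds are unique whenever coordinates are.
#'
#' @param position Integer vector of 1-based tree coordinates.
#' @return The linkId string.
#' @export
linkid_scheme <- function(position) {
  stopifnot(length(position) > 0, all(position >= 1))
  paste(as.integer(position), collapse = ".")
}

item_type_for_kind <- function(kind) {
  switch(kind,
    yes_no_unknown = ,
    yes_no_unknown_with_date = ,
    yes_no_unknown_with_severity = ,
    coded_choice = "choice",
    date = "date",
    datetime = "dateTime",
    quantity = "quantity",
    text = "string",
    integer = "integer",
    stop_gecco("model_consistency", paste("unknown answer kind", kind))
  )
}

path_annotation <- function(url, path) {
  list(url = url, valueString = path)
}

ynu_answer_options <- function(model) {
  lapply(unname(model$settings$ynu_options),
         function(cd) list(valueCoding = fhir_coding(cd)))
}

# linkIds for every model path (composite part items get "<linkId>.1")
# computed ahead of rendering so enableWhen can reference any item.
assign_linkids <- function(model) {
  out <- character(0)
  recurse <- function(node, pos) {
    lid <- linkid_scheme(pos)
    out[node$path] <<- lid
    if (!is.null(node$answer) &&
        node$answer$kind %in% c("yes_no_unknown_with_date",
                                "yes_no_unknown_with_severity")) {
      part <- if (node$answer$kind == "yes_no_unknown_with_date") "date" else "severity"
      out[paste0(node$path, ".", part)] <<- paste0(lid, ".1")
    }
    for (i in seq_along(node$children)) recurse(node$children[[i]], c(pos, i))
  }
  for (i in seq_along(model$roots)) recurse(model$roots[[i]], i)
  out
}

render_enable_when <- function(rule, model, linkids) {
  controlling <- resolve_path(model, rule$path)
  required <- rule$answer
  if (!inherits(required, "gecco_coding")) {
    # token form: resolve against the controlling item's option scale
    opts <- if (controlling$node$answer$kind == "coded_choice") {
      stats::setNames(lapply(controlling$node$answer$options, `[[`, "coding"),
                      vapply(controlling$node$answer$options,
                             function(o) o$coding$code, character(1)))
    } else {
      model$settings$ynu_options
    }
    gecco_abort_if(is.null(opts[[required]]), "dangling_rule",
                   sprintf("enable rule answer token '%s' is not an option of '%s'",
                           required, rule$path))
    required <- opts[[required]]
  }
  list(question = unname(linkids[[rule$path]]), operator = "=",
       answerCoding = fhir_coding(required))
}

render_item <- function(node, pos, model, linkids, ext_url) {
  lid <- linkid_scheme(pos)
  item <- list(linkId = lid, text = node$question)
  if (is.null(node$answer)) {
    item$type <- "group"
  } else {
    spec <- node$answer
    item$type <- item_type_for_kind(spec$kind)
    if (item$type == "choice") {
      item$answerOption <- if (spec$kind == "coded_choice") {
        lapply(spec$options, function(o) list(valueCoding = fhir_coding(o$coding)))
      } else {
        ynu_answer_options(model)
      }
    }
  }
  item$required <- FALSE
  ext <- list(path_annotation(ext_url, node$path))
  if (!is.null(node$answer)) {
    spec <- node$answer
    if (spec$kind == "quantity") {
      ext <- c(ext, list(list(
        url = "http://hl7.org/fhir/StructureDefinition/questionnaire-unit",
        valueCoding = list(system = SYSTEMS$ucum, code = spec$unit))))
    }
    if (!is.null(spec$range)) {
      vkey <- switch(spec$kind, quantity = "valueDecimal", integer = "valueInteger",
                     date = "valueDate", datetime = "valueDateTime")
      if (!is.null(vkey)) {
        ext <- c(ext, list(
          stats::setNames(list("http://hl7.org/fhir/StructureDefinition/minValue",
                               spec$range[[1]]), c("url", vkey)),
          stats::setNames(list("http://hl7.org/fhir/StructureDefinition/maxValue",
                               spec$range[[2]]), c("url", vkey))))
      }
    }
  }
  item$extension <- ext
  if (!is.null(node$enable)) {
    item$enableWhen <- list(render_enable_when(node$enable, model, linkids))
  }

  children <- list()
  if (!is.null(node$answer) &&
      node$answer$kind %in% c("yes_no_unknown_with_date",
                              "yes_no_unknown_with_severity")) {
    part <- if (node$answer$kind == "yes_no_unknown_with_date") "date" else "severity"
    child <- list(
      linkId = paste0(lid, ".1"),
      text = paste0(node$question, if (part == "date") " (date)" else " (severity)"),
      type = if (part == "date") "date" else "choice"
    )
    if (part == "severity") {
      child$answerOption <- lapply(unname(model$settings$severity_options),
                                   function(cd) list(valueCoding = fhir_coding(cd)))
    }
    child$required <- FALSE
    child$extension <- list(path_annotation(ext_url, paste0(node$path, ".", part)))
    child$enableWhen <- list(list(
      question = lid, operator = "=",
      answerCoding = fhir_coding(model$settings$ynu_options$yes)))
    children <- list(child)
  }
  for (i in seq_along(node$children)) {
    children[[length(children) + 1L]] <-
      render_item(node$children[[i]], c(pos, i), model, linkids, ext_url)
  }
  if (length(children) > 0) item$item <- children
  item
}

#' Render the annotated reference questionnaire
#'
#' @param model A `gecco_model`.
#' @return A FHIR R4 Questionnaire as a nested list (serialize with
#'   [write_fhir()]).  Rendering is deterministic: the same model always
#'   yields byte-identical canonical JSON.
#' @export
#' @examples
#' q <- render_questionnaire(mini_gecco())
#' q$item[[3]]$item[[1]]$text
render_questionnaire <- function(model) {
  stopifnot(inherits(model, "gecco_model"))
  linkids <- assign_linkids(model)
  ext_url <- item_extension_url(model)
  items <- lapply(seq_along(model$roots), function(i) {
    render_item(model$roots[[i]], i, model, linkids, ext_url)
  })
  q <- list(
    resourceType = "Questionnaire",
    url = paste0(model$canonical_base, "/Questionnaire/", model$name),
    version = "1.0.0",
    name = gsub("[^A-Za-z0-9]", "_", model$name),
    title = model$name,
    status = "active"
  )
  if (length(items) > 0) q$item <- items
  q
}

# ---- questionnaire introspection helpers -------------------------------

# Annotation path of an item, or NA.
item_gecco_path <- function(item) {
  for (ext in item$extension %||% list()) {
    if (grepl(paste0(ITEM_EXT_SUFFIX, "$"), ext$url %||% "")) {
      return(ext$valueString)
    }
  }
  NA_character_
}

# Depth-first flat list of all items of a questionnaire (or response).
flatten_items <- function(doc) {
  out <- list()
  recurse <- function(items) {
    for (it in items) {
      out[[length(out) + 1L]] <<- it
      if (!is.null(it$item)) recurse(it$item)
    }
  }
  recurse(doc$item %||% list())
  out
}

# Named lookup linkId -> item.
questionnaire_index <- function(questionnaire) {
  items <- flatten_items(questionnaire)
  stats::setNames(items, vapply(items, `[[`, character(1), "linkId"))
}

# Structural FHIR R4 sanity check used as a precondition by consumers.
check_questionnaire <- function(questionnaire) {
  ok <- is.list(questionnaire) &&
    identical(questionnaire$resourceType, "Questionnaire") &&
    !is.null(questionnaire$status)
  gecco_abort_if(!ok, "invalid_questionnaire",
                 "not a FHIR R4 Questionnaire (resourceType/status missing)")
  items <- flatten_items(questionnaire)
  for (it in items) {
    gecco_abort_if(is.null(it$linkId) || is.null(it$type), "invalid_questionnaire",
                   "questionnaire item lacks linkId or type")
    gecco_abort_if(!is.null(it$answerOption) &&
                     !it$type %in% c("choice", "open-choice"),
                   "invalid_questionnaire",
                   sprintf("item '%s': answerOption on non-choice item", it$linkId))
  }
  lids <- vapply(items, `[[`, character(1), "linkId")
  gecco_abort_if(anyDuplicated(lids) > 0, "invalid_questionnaire",
                 "duplicate linkIds in questionnaire")
  invisible(questionnaire)
}
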