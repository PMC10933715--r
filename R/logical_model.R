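#' @title Hierarchical logical model of a patient-reported-outcome data set
#'
#' @description
#' The logical model is the single source of truth for everything this
#' package does: a tree of clinical concepts, each annotated with a textual
#' question, an answer specification, terminology codings and (for
#' answer-bearing leaves) the profile template that maps it to a FHIR
#' resource.  Groups structure the questionnaire; *meta* groups additionally
#' gate a block of disease items behind a category-level yes/no/unknown
#' question and default their children when that question is answered
#' "no" or "unknown".
#'
#' Models are defined declaratively in a YAML document; see the bundled
#' `mini-gecco.yaml` under `inst/extdata` for the reference fixture and the
#' methods vignette for the schema.
#'
#' @name logical-model
NULL

ANSWER_KINDS <- c("yes_no_unknown", "yes_no_unknown_with_date",
                  "yes_no_unknown_with_severity", "coded_choice",
                  "date", "datetime", "quantity", "text", "integer")

RESOURCE_TYPES <- c("Patient", "Consent", "Observation", "Condition",
                    "Procedure", "MedicationStatement", "Immunization")

TEMPLATE_BINDINGS <- c("patient-field", "consent-status",
                       "condition-presence", "observation-value",
                       "procedure-date", "medication-presence",
                       "immunization-presence")

parse_answer_spec <- function(x, path) {
  kind <- x$kind
  gecco_abort_if(is.null(kind) || !kind %in% ANSWER_KINDS,
                 "model_consistency",
                 sprintf("node '%s': unknown answer kind '%s'", path, kind))
  spec <- list(kind = kind)
  if (kind == "coded_choice") {
    gecco_abort_if(length(x$options) == 0, "model_consistency",
                   sprintf("node '%s': coded_choice needs options", path))
    spec$options <- lapply(x$options, function(o) {
      list(coding = as_coding(o$coding),
           additional = lapply(o$additional %||% list(), as_coding))
    })
    check_unique_codings(lapply(spec$options, `[[`, "coding"),
                         sprintf("options of '%s'", path))
  } else {
    gecco_abort_if(length(x$options) > 0, "model_consistency",
                   sprintf("node '%s': options only allowed for coded_choice", path))
  }
  if (kind == "quantity") {
    gecco_abort_if(is.null(x$unit), "model_consistency",
                   sprintf("node '%s': quantity needs a UCUM unit", path))
    spec$unit <- x$unit
  } else {
    gecco_abort_if(!is.null(x$unit), "model_consistency",
                   sprintf("node '%s': unit only allowed for quantity", path))
  }
  if (!is.null(x$range)) {
    # numeric bounds for quantity/integer, ISO dates for date/datetime
    spec$range <- if (kind %in% c("date", "datetime")) as.character(x$range)
                  else as.numeric(x$range)
    gecco_abort_if(length(spec$range) != 2, "model_consistency",
                   sprintf("node '%s': range must have two bounds", path))
  }
  class(spec) <- "gecco_answer"
  spec
}

parse_enable_rule <- function(x, path) {
  gecco_abort_if(is.null(x$path), "model_consistency",
                 sprintf("node '%s': enable rule needs a controlling path", path))
  ans <- x$answer
  gecco_abort_if(is.null(ans), "model_consistency",
                 sprintf("node '%s': enable rule needs a required answer", path))
  if (is.list(ans)) ans <- as_coding(ans)
  structure(list(path = x$path, answer = ans), class = "gecco_enable_rule")
}

parse_node <- function(x) {
  gecco_abort_if(is.null(x$path) || !nzchar(x$path), "model_consistency",
                 "every node needs a non-empty path")
  node <- list(
    path     = x$path,
    question = x$question %||% x$path,
    answer   = if (!is.null(x$answer)) parse_answer_spec(x$answer, x$path),
    codings  = lapply(x$codings %||% list(), as_coding),
    template = x$template,
    enable   = if (!is.null(x$enable)) parse_enable_rule(x$enable, x$path),
    is_meta  = isTRUE(x$meta),
    children = lapply(x$children %||% list(), parse_node)
  )
  check_unique_codings(node$codings, sprintf("concept codings of '%s'", x$path))
  class(node) <- "gecco_node"
  node
}

parse_template <- function(x) {
  gecco_abort_if(is.null(x$id), "model_consistency", "template needs an id")
  gecco_abort_if(!x$resource_type %in% RESOURCE_TYPES, "unknown_resource_type",
                 sprintf("template '%s': resource type '%s' is not one of the seven mapped types",
                         x$id, x$resource_type))
  gecco_abort_if(!x$binding %in% TEMPLATE_BINDINGS, "model_consistency",
                 sprintf("template '%s': unknown answer binding '%s'", x$id, x$binding))
  fixed <- lapply(x$fixed %||% list(), function(f) {
    if (is.list(f) && !is.null(f$system)) as_coding(f) else f
  })
  structure(
    list(id = x$id, resource_type = x$resource_type, binding = x$binding,
         fixed = fixed, profile = x$profile),
    class = "gecco_template"
  )
}

default_settings <- function() {
  list(
    ynu_options          = default_ynu_options(),
    severity_options     = default_severity_options(),
    verification_codings = default_verification_codings(),
    subject_system       = "https://example.org/fhir/NamingSystem/subject-id"
  )
}

merge_settings <- function(user) {
  s <- default_settings()
  for (key in c("ynu_options", "severity_options", "verification_codings")) {
    if (!is.null(user[[key]])) s[[key]] <- lapply(user[[key]], as_coding)
  }
  if (!is.null(user$subject_system)) s$subject_system <- user$subject_system
  s
}

#' Load a logical model from a YAML definition
#'
#' Parses and validates a declarative model document: path uniqueness over
#' the whole tree, resolvable templates, resolvable and acyclic enableWhen
#' rules, and structural constraints (leaves carry answers, meta groups
#' carry children but no template, template-bearing nodes carry concept
#' codings).
#'
#' @param source Path to a YAML model definition, or a YAML string.
#' @return A validated object of class `gecco_model`.
#' @seealso [mini_gecco()] for the bundled reference model.
#' @export
load_model <- function(source) {
  doc <- tryCatch(
    if (file.exists(source)) yaml::read_yaml(source) else yaml::yaml.load(source),
    error = function(e) stop_gecco("parse", paste("cannot parse model document:",
                                                  conditionMessage(e)))
  )
  gecco_abort_if(!is.list(doc) || is.null(doc$roots), "parse",
                 "model document must define 'roots'")
  templates <- lapply(doc$templates %||% list(), parse_template)
  names(templates) <- vapply(templates, `[[`, character(1), "id")
  model <- structure(
    list(
      name           = doc$name %||% "unnamed-model",
      canonical_base = doc$canonical_base %||% "https://example.org/fhir/compass",
      settings       = merge_settings(doc$settings),
      templates      = templates,
      roots          = lapply(doc$roots, parse_node)
    ),
    class = "gecco_model"
  )
  validate_model(model)
}

#' @export
print.gecco_model <- function(x, ...) {
  leaves <- walk_leaves(x)
  cat(sprintf("<gecco_model> %s\n", x$name))
  cat(sprintf("  canonical base: %s\n", x$canonical_base))
  cat(sprintf("  %d answer-bearing elements, %d profile templates (%s)\n",
              length(leaves), length(x$templates),
              paste(sort(unique(vapply(x$templates, `[[`, character(1),
                                       "resource_type"))), collapse = ", ")))
  invisible(x)
}

# Flat list of every node in document order (depth first).
model_nodes <- function(model) {
  out <- list()
  recurse <- function(node) {
    out[[length(out) + 1L]] <<- node
    for (child in node$children) recurse(child)
  }
  for (root in model$roots) recurse(root)
  out
}

# Named lookup table path -> node.
node_index <- function(model) {
  nodes <- model_nodes(model)
  names(nodes) <- vapply(nodes, `[[`, character(1), "path")
  nodes
}

validate_model <- function(model) {
  nodes <- model_nodes(model)
  paths <- vapply(nodes, `[[`, character(1), "path")
  dup <- paths[duplicated(paths)]
  gecco_abort_if(length(dup) > 0, "duplicate_path",
                 sprintf("model element path appears more than once: %s",
                         paste(unique(dup), collapse = ", ")))

  for (node in nodes) {
    leaf <- length(node$children) == 0
    if (leaf && is.null(node$answer) && !node$is_meta)
      stop_gecco("model_consistency",
                 sprintf("leaf '%s' has no answer specification", node$path))
    if (node$is_meta) {
      gecco_abort_if(leaf, "model_consistency",
                     sprintf("meta element '%s' must have children", node$path))
      gecco_abort_if(!is.null(node$template), "model_consistency",
                     sprintf("meta element '%s' must not carry a template", node$path))
      gecco_abort_if(length(node$codings) > 0, "model_consistency",
                     sprintf("meta element '%s' must not carry concept codings", node$path))
    }
    if (!is.null(node$template)) {
      gecco_abort_if(is.null(model$templates[[node$template]]), "unknown_template",
                     sprintf("node '%s' references unknown template '%s'",
                             node$path, node$template))
      gecco_abort_if(length(node$codings) == 0, "model_consistency",
                     sprintf("template-bearing node '%s' needs concept codings", node$path))
    }
  }

  # enableWhen rules must resolve to existing answer-bearing nodes ...
  idx <- stats::setNames(nodes, paths)
  for (node in nodes) {
    if (is.null(node$enable)) next
    target <- idx[[node$enable$path]]
    gecco_abort_if(is.null(target), "dangling_rule",
                   sprintf("enable rule of '%s' points at nonexistent path '%s'",
                           node$path, node$enable$path))
    gecco_abort_if(is.null(target$answer), "dangling_rule",
                   sprintf("enable rule of '%s' points at group '%s', which has no answer",
                           node$path, node$enable$path))
  }

  # ... and must not create cycles.  The effective controller of a node is
  # its own rule or the rule of its nearest enclosing group.
  eff <- effective_controllers(model)
  for (start in names(eff)) {
    seen <- character(0)
    cur <- start
    while (cur %in% names(eff)) {
      gecco_abort_if(cur %in% seen, "cycle",
                     sprintf("enable rules form a cycle through '%s'", cur))
      seen <- c(seen, cur)
      cur <- eff[[cur]]
    }
  }
  model
}

# path -> controlling path of the innermost applicable enable rule.
effective_controllers <- function(model) {
  out <- character(0)
  recurse <- function(node, inherited) {
    rule <- if (!is.null(node$enable)) node$enable$path else inherited
    if (!is.null(rule)) out[node$path] <<- rule
    for (child in node$children) recurse(child, rule)
  }
  for (root in model$roots) recurse(root, NULL)
  out
}

#' Enumerate the answer-bearing elements of a model
#'
#' Depth-first, document-order traversal over all nodes that carry an
#' answer specification (groups and meta groups are skipped).  The order is
#' deterministic and matches the item order of the rendered questionnaire.
#'
#' @param model A `gecco_model`.
#' @return A list of `gecco_node` objects.
#' @export
walk_leaves <- function(model) {
  stopifnot(inherits(model, "gecco_model"))
  Filter(function(n) !is.null(n$answer), model_nodes(model))
}

#' Resolve a logical-model path
#'
#' Resolves a dot-separated element path to its node.  Composite answer
#' kinds occupy two questionnaire items; the secondary item carries the
#' node path plus a reserved part suffix (`.date` for
#' `yes_no_unknown_with_date`, `.severity` for
#' `yes_no_unknown_with_severity`), which this resolver understands.
#'
#' @param model A `gecco_model`.
#' @param path Element path, optionally with a part suffix.
#' @return `NULL` if the path does not resolve, otherwise a list with
#'   elements `node` (the `gecco_node`) and `part` (`NA`, `"date"` or
#'   `"severity"`).
#' @export
resolve_path <- function(model, path) {
  idx <- node_index(model)
  if (!is.null(idx[[path]])) return(list(node = idx[[path]], part = NA_character_))
  part <- sub("^.*\\.", "", path)
  base <- sub("\\.[^.]+$", "", path)
  node <- idx[[base]]
  if (is.null(node) || is.null(node$answer)) return(NULL)
  if (part == "date" && node$answer$kind == "yes_no_unknown_with_date")
    return(list(node = node, part = "date"))
  if (part == "severity" && node$answer$kind == "yes_no_unknown_with_severity")
    return(list(node = node, part = "severity"))
  NULL
}

#' The bundled mini-GECCO reference model
#'
#' Loads the model definition shipped with the package: a compact subset of
#' the German Corona Consensus (GECCO) COVID-19 core data set that exercises
#' every answer kind and all seven mapped FHIR resource types — an anamnesis
#' branch with a meta-gated chronic-lung-disease block (asthma, COPD),
#' demographics (biological sex, birth date), symptoms with severity scales,
#' a COVID-19 vaccination item, vital-sign and epidemiology observations, a
#' dialysis procedure, an ACE-inhibitor medication item and a consent item.
#'
#' @return A `gecco_model`.
#' @export
#' @examples
#' m <- mini_gecco()
#' length(walk_leaves(m))
mini_gecco <- function() {
  load_model(system.file("extdata", "mini-gecco.yaml", package = "geccomap",
                         mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
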