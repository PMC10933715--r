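# Shared fixtures and independent oracles.  The oracles deliberately avoid
# the package's own traversal/evaluation code paths: they re-derive the
# expected quantities with plain recursive walks over the raw lists.

SNOMED <- "http://snomed.info/sct"
YES_CODE <- "373066001"
NO_CODE <- "373067005"
UNKNOWN_CODE <- "261665006"

yes_answer <- function() list(valueCoding = list(system = SNOMED, code = YES_CODE, display = "Yes"))
no_answer <- function() list(valueCoding = list(system = SNOMED, code = NO_CODE, display = "No"))
unknown_answer <- function() list(valueCoding = list(system = SNOMED, code = UNKNOWN_CODE, display = "Unknown"))

# -- tiny model document builder -----------------------------------------

minimal_model_yaml <- function(extra_nodes = "", templates = NULL) {
  templates <- templates %||% '
templates:
  - id: condition-any
    resource_type: Condition
    binding: condition-presence
'
  paste0('
name: tiny
canonical_base: https://example.org/fhir/tiny
', templates, '
roots:
  - path: a
    question: "Block A"
    children:
      - path: a.x
        question: "X present?"
        answer: {kind: yes_no_unknown}
        codings:
          - {system: "http://snomed.info/sct", code: "111", display: X}
        template: condition-any
', extra_nodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- independent oracles --------------------------------------------------

# Count of answer-bearing nodes by brute-force recursion over the raw tree.
oracle_leaf_count <- function(model) {
  count <- function(node) {
    sum(vapply(node$children, count, numeric(1))) +
      as.numeric(!is.null(node$answer))
  }
  sum(vapply(model$roots, count, numeric(1)))
}

# Flat linkId -> first answer, by recursion over raw response items.
oracle_answers <- function(response) {
  out <- list()
  walk <- function(items) {
    for (it in items) {
      if (length(it$answer) > 0) out[[it$linkId]] <<- it$answer[[1]]
      if (!is.null(it$item)) walk(it$item)
    }
  }
  walk(response$item %||% list())
  out
}

# Brute-force enableWhen check: for every answered linkId, walk the
# questionnaire tree to the item, collect every enableWhen on the item and
# its ancestors, and evaluate each against the response's answers.
# Returns character(0) when consistent, else the offending linkIds.
oracle_enablewhen_violations <- function(response, questionnaire) {
  answers <- oracle_answers(response)
  chains <- list()
  walk <- function(items, inherited) {
    for (it in items) {
      conds <- c(inherited, it$enableWhen %||% list())
      chains[[it$linkId]] <<- conds
      if (!is.null(it$item)) walk(it$item, conds)
    }
  }
  walk(questionnaire$item %||% list(), list())
  bad <- character(0)
  for (lid in names(answers)) {
    if (is.null(chains[[lid]])) {
      bad <- c(bad, lid)  # fabricated linkId
      next
    }
    for (cond in chains[[lid]]) {
      got <- answers[[cond$question]]
      ok <- !is.null(got) && !is.null(got$valueCoding) &&
        identical(got$valueCoding$code, cond$answerCoding$code)
      if (!ok) bad <- c(bad, lid)
    }
  }
  unique(bad)
}

# Independent expected bundle size: 1 Patient + answered template-bearing
# leaves with non-Patient templates, with meta expansion applied.  Works
# directly on the raw model document and raw response items.
oracle_bundle_size <- function(response, model) {
  # path -> TRUE for answered items (main part only)
  answered <- character(0)
  walk <- function(items) {
    for (it in items) {
      if (length(it$answer) > 0) {
        for (ext in it$extension %||% list()) {
          if (grepl("compass-gecco-item$", ext$url %||% ""))
            answered <<- c(answered, ext$valueString)
        }
      }
      if (!is.null(it$item)) walk(it$item)
    }
  }
  walk(response$item %||% list())

  n <- 0
  count_node <- function(node, inside_expanded_meta) {
    if (isTRUE(node$is_meta)) {
      gate <- node$enable$path
      gate_ans <- NA_character_
      # find the gate's drawn code via the response (gate path is answered)
      if (gate %in% answered) {
        gate_ans <- oracle_gate_code(response, gate)
      }
      if (identical(gate_ans, NO_CODE) || identical(gate_ans, UNKNOWN_CODE)) {
        n <<- n + length(node$children)  # one Condition per child
        return(invisible())
      }
      for (ch in node$children) count_node(ch, FALSE)
      return(invisible())
    }
    if (!is.null(node$answer) && !is.null(node$template) &&
        node$path %in% answered) {
      tpl <- model$templates[[node$template]]
      if (!identical(tpl$resource_type, "Patient")) n <<- n + 1
    }
    for (ch in node$children) count_node(ch, FALSE)
  }
  for (root in model$roots) count_node(root, FALSE)
  n + 1
}

oracle_gate_code <- function(response, path) {
  found <- NA_character_
  walk <- function(items) {
    for (it in items) {
      if (length(it$answer) > 0) {
        for (ext in it$extension %||% list()) {
          if (grepl("compass-gecco-item$", ext$url %||% "") &&
              identical(ext$valueString, path)) {
            found <<- it$answer[[1]]$valueCoding$code
          }
        }
      }
      if (!is.null(it$item)) walk(it$item)
    }
  }
  walk(response$item %||% list())
  found
}

# -- response construction helpers ---------------------------------------

# Hand-build an annotated response answering the given model paths.
# `values` is a named list path -> answer (e.g. list(valueCoding = ...)).
make_response <- function(values, subject = "subject-900",
                          authored = "2021-05-01T10:00:00Z",
                          annotate = TRUE) {
  items <- lapply(names(values), function(p) {
    it <- list(linkId = paste0("manual-", p))
    if (annotate) {
      it$extension <- list(list(
        url = "https://example.org/fhir/compass/StructureDefinition/compass-gecco-item",
        valueString = p))
    }
    it$answer <- list(values[[p]])
    it
  })
  resp <- list(
    resourceType = "QuestionnaireResponse",
    id = paste0("qr-", subject),
    status = "completed",
    subject = list(identifier = list(
      system = "https://example.org/fhir/NamingSystem/subject-id",
      value = subject)),
    authored = authored
  )
  if (length(items) > 0) resp$item <- items
  resp
}

bundle_resources <- function(bundle) lapply(bundle$entry, `[[`, "resource")

resource_types <- function(bundle) {
  vapply(bundle_resources(bundle), function(r) r$resourceType, character(1))
}

# Small seeded corpus shared by several acceptance checks; built once.
corpus_env <- new.env(parent = emptyenv())
get_corpus <- function(n_subjects = 50, per_subject = 2, seed = 42) {
  key <- paste(n_subjects, per_subject, seed, sep = "-")
  if (is.null(corpus_env[[key]])) {
    model <- mini_gecco()
    q <- render_questionnaire(model)
    responses <- generate_responses(q, n_subjects, per_subject, seed)
    corpus_env[[key]] <- list(model = model, questionnaire = q,
                              responses = responses)
  }
  corpus_env[[key]]
}
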