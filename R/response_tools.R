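#' @title Random response generation and path annotation
#'
#' @description
#' [generate_responses()] draws random but enableWhen-consistent answers
#' from a Questionnaire's own answer domains so the whole mapping pipeline
#' can be exercised, and every answer option reached, without any patient
#' data.  [annotate_response()] transfers the logical-model path
#' annotations of a known Questionnaire onto a QuestionnaireResponse that
#' lacks them.
#'
#' @name response-tools
NULL

SUBJECT_ID_SYSTEM <- "https://example.org/fhir/NamingSystem/subject-id"

# Does `item` become visible given the answers drawn so far?
# FHIR semantics for operator "=": an unanswered controlling item never
# satisfies the condition.
eval_enable_when <- function(item, answers) {
  conditions <- item$enableWhen %||% list()
  if (length(conditions) == 0) return(TRUE)
  for (cond in conditions) {
    got <- answers[[cond$question]]
    if (is.null(got) || is.null(got$valueCoding)) return(FALSE)
    want <- cond$answerCoding
    if (!identical(got$valueCoding$code, want$code)) return(FALSE)
    if (!is.null(want$system) && !is.null(got$valueCoding$system) &&
        !identical(got$valueCoding$system, want$system)) return(FALSE)
  }
  TRUE
}

item_ext_value <- function(item, url_suffix, field) {
  for (ext in item$extension %||% list()) {
    if (grepl(paste0(url_suffix, "$"), ext$url %||% "")) return(ext[[field]])
  }
  NULL
}

random_datetime <- function(window) {
  lo <- as.POSIXct(window[1], tz = "UTC")
  hi <- as.POSIXct(window[2], tz = "UTC")
  t <- lo + floor(stats::runif(1, 0, as.numeric(difftime(hi, lo, units = "secs")) + 1))
  format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

random_date <- function(window) {
  lo <- as.Date(window[1])
  hi <- as.Date(window[2])
  format(lo + floor(stats::runif(1, 0, as.numeric(hi - lo) + 1)), "%Y-%m-%d")
}

TEXT_POOL <- c("headache", "fatigue", "loss of taste", "sore throat",
               "none", "shortness of breath on exertion")

draw_answer <- function(item) {
  type <- item$type
  if (type %in% c("choice", "open-choice")) {
    opts <- item$answerOption %||% list()
    if (length(opts) == 0) return(NULL)
    pick <- opts[[sample.int(length(opts), 1)]]
    return(list(valueCoding = pick$valueCoding))
  }
  min_ext <- function(f) item_ext_value(item, "minValue", f)
  max_ext <- function(f) item_ext_value(item, "maxValue", f)
  switch(type,
    date = {
      window <- c(min_ext("valueDate") %||% "2020-03-01",
                  max_ext("valueDate") %||% "2021-06-30")
      list(valueDate = random_date(window))
    },
    dateTime = {
      window <- c(min_ext("valueDateTime") %||% "2020-03-01T00:00:00",
                  max_ext("valueDateTime") %||% "2021-06-30T23:59:59")
      list(valueDateTime = random_datetime(window))
    },
    quantity = {
      lo <- min_ext("valueDecimal") %||% 0
      hi <- max_ext("valueDecimal") %||% 100
      unit <- item_ext_value(item, "questionnaire-unit", "valueCoding")
      val <- round(stats::runif(1, lo, hi), 1)
      q <- list(value = val)
      if (!is.null(unit)) {
        q$unit <- unit$code
        q$system <- unit$system
        q$code <- unit$code
      }
      list(valueQuantity = q)
    },
    integer = {
      lo <- min_ext("valueInteger") %||% 0
      hi <- max_ext("valueInteger") %||% 10
      list(valueInteger = lo + sample.int(hi - lo + 1L, 1) - 1L)
    },
    string = list(valueString = TEXT_POOL[sample.int(length(TEXT_POOL), 1)]),
    text = list(valueString = TEXT_POOL[sample.int(length(TEXT_POOL), 1)]),
    NULL
  )
}

#' Generate random, condition-consistent QuestionnaireResponses
#'
#' Walks the questionnaire in document order, evaluates each item's
#' enableWhen against the answers drawn so far (conditions only ever
#' reference earlier items) and, for visible items, draws an answer
#' uniformly from the item's own domain: its answerOptions for choice
#' items, its min/max bounds for dates, quantities and integers, a small
#' phrase pool for free text.  Disabled items are left unanswered.
#'
#' @param questionnaire A FHIR R4 Questionnaire (e.g. from
#'   [render_questionnaire()]).
#' @param n_subjects Number of synthetic subjects.
#' @param per_subject Responses per subject.
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   output.
#' @param authored_window Two timestamps between which `authored` is drawn.
#' @param skip_prob Probability that a visible, answerable item is left
#'   unanswered (simulates skipped optional questions; default 0).
#' @return A list of `n_subjects * per_subject` QuestionnaireResponse lists.
#' @export
generate_responses <- function(questionnaire, n_subjects, per_subject, seed,
                               authored_window = c("2021-01-01T00:00:00",
                                                   "2021-06-30T23:59:59"),
                               skip_prob = 0) {
  check_questionnaire(questionnaire)
  stopifnot(n_subjects >= 0, per_subject >= 0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  responses <- list()
  for (s in seq_len(n_subjects)) {
    subject_id <- sprintf("subject-%03d", s)
    for (k in seq_len(per_subject)) {
      authored <- random_datetime(authored_window)
      answers <- new.env(parent = emptyenv())

      fill <- function(items) {
        out <- list()
        for (it in items) {
          if (!eval_enable_when(it, answers)) next
          ri <- list(linkId = it$linkId)
          if (!is.null(it$text)) ri$text <- it$text
          if (!is.null(it$extension)) ri$extension <- it$extension
          if (identical(it$type, "group")) {
            kids <- fill(it$item %||% list())
            if (length(kids) == 0) next
            ri$item <- kids
          } else {
            if (skip_prob > 0 && stats::runif(1) < skip_prob) next
            ans <- draw_answer(it)
            if (is.null(ans)) next
            assign(it$linkId, ans, envir = answers)
            ri$answer <- list(ans)
            kids <- fill(it$item %||% list())
            if (length(kids) > 0) ri$item <- kids
          }
          out[[length(out) + 1L]] <- ri
        }
        out
      }

      items <- fill(questionnaire$item %||% list())
      resp <- list(
        resourceType = "QuestionnaireResponse",
        id = sprintf("qr-%s-%02d", subject_id, k),
        questionnaire = questionnaire$url,
        status = "completed",
        subject = list(identifier = list(system = SUBJECT_ID_SYSTEM,
                                         value = subject_id)),
        authored = authored
      )
      if (length(items) > 0) resp$item <- items
      responses[[length(responses) + 1L]] <- resp
    }
  }
  responses
}

#' Transfer logical-model path annotations onto a response
#'
#' For apps that do not copy the item annotation extension into their
#' QuestionnaireResponses, the paths can be recovered as long as the source
#' Questionnaire is known: each response item gains the
#' `compass-gecco-item` extension of the Questionnaire item with the same
#' linkId.  Already-annotated items are left untouched, so the operation is
#' idempotent; answer values are never modified.
#'
#' @param response A FHIR R4 QuestionnaireResponse.
#' @param questionnaire The Questionnaire the response was collected with.
#' @return The annotated response.
#' @export
annotate_response <- function(response, questionnaire) {
  check_questionnaire(questionnaire)
  idx <- questionnaire_index(questionnaire)
  annotate <- function(items) {
    lapply(items, function(ri) {
      qi <- idx[[ri$linkId %||% ""]]
      gecco_abort_if(is.null(qi), "linkid_mismatch",
                     sprintf("response linkId '%s' does not exist in the questionnaire (version skew?)",
                             ri$linkId %||% "<missing>"))
      if (is.na(item_gecco_path(ri))) {
        path <- item_gecco_path(qi)
        if (!is.na(path)) {
          url <- vapply(qi$extension, function(e) e$url %||% "", character(1))
          ext <- qi$extension[[which(grepl(paste0(ITEM_EXT_SUFFIX, "$"), url))[1]]]
          ri$extension <- c(ri$extension %||% list(), list(ext))
        }
      }
      if (!is.null(ri$item)) ri$item <- annotate(ri$item)
      ri
    })
  }
  if (!is.null(response$item)) response$item <- annotate(response$item)
  response
}
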