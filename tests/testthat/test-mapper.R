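UCUM <- "http://unitsofmeasure.org"

test_that("context attributes follow the per-type contextual mapping table", {
  ctx <- list(subject_id = "S1", authored = "2021-05-01T10:00:00Z",
              patient_ref = "Patient/p1")

  cond <- resolve_context("Condition", ctx)
  expect_identical(cond$subject$attr, "subject")
  expect_identical(cond$subject$reference$reference, "Patient/p1")
  expect_identical(cond$time$attr, "recordedDate")
  expect_identical(cond$time$value, ctx$authored)

  med <- resolve_context("MedicationStatement", ctx)
  expect_identical(med$subject$attr, "subject")
  expect_identical(med$time$attr, "effectiveDateTime")

  obs <- resolve_context("Observation", ctx)
  expect_identical(obs$time$attr, "effectiveDateTime")

  pat <- resolve_context("Patient", ctx)
  expect_null(pat$subject)
  expect_null(pat$time)

  consent <- resolve_context("Consent", ctx)
  expect_identical(consent$subject$attr, "patient")
  expect_null(consent$time)

  # domain-specific exception: times of these two come from answers
  expect_null(resolve_context("Procedure", ctx)$time)
  expect_null(resolve_context("Immunization", ctx)$time)
  expect_identical(resolve_context("Immunization", ctx)$subject$attr, "patient")

  expect_error(resolve_context("Device", ctx),
               class = "gecco_unknown_resource_type_error")
})

test_that("an answered quantity item maps to an Observation bound to subject and authored time", {
  m <- mini_gecco()
  r <- make_response(list(
    "vitalSigns.bodyTemperature" = list(valueQuantity = list(
      value = 37.8, unit = "Cel", system = UCUM, code = "Cel"))
  ), subject = "S1", authored = "2021-05-01T10:00:00Z")
  b <- map_response(r, m)
  types <- resource_types(b)
  expect_identical(sort(types), c("Observation", "Patient"))
  obs <- bundle_resources(b)[[which(types == "Observation")]]
  pat <- bundle_resources(b)[[which(types == "Patient")]]
  expect_identical(obs$subject$reference, paste0("Patient/", pat$id))
  expect_identical(obs$effectiveDateTime, "2021-05-01T10:00:00Z")
  expect_identical(obs$valueQuantity$value, 37.8)
  expect_identical(obs$valueQuantity$code, "Cel")
  # both model codings are emitted into the code element
  systems <- vapply(obs$code$coding, `[[`, character(1), "system")
  expect_setequal(systems, c("http://loinc.org", SNOMED))
})

test_that("a vaccination answered yes takes its date from the answer, not the context", {
  m <- mini_gecco()
  r <- make_response(list(
    "vaccination.covid19" = yes_answer(),
    "vaccination.covid19.date" = list(valueDate = "2021-04-01")
  ), authored = "2021-05-01T10:00:00Z")
  b <- map_response(r, m)
  imm <- bundle_resources(b)[[which(resource_types(b) == "Immunization")]]
  expect_identical(imm$status, "completed")
  expect_identical(imm$occurrenceDateTime, "2021-04-01")
  expect_false(identical(imm$occurrenceDateTime, r$authored))
  expect_null(imm$effectiveDateTime)
})

test_that("a response with no answers maps to a bundle containing only the Patient", {
  m <- mini_gecco()
  r <- make_response(list(), subject = "S7")
  b <- map_response(r, m)
  expect_identical(resource_types(b), "Patient")
  pat <- bundle_resources(b)[[1]]
  expect_identical(pat$identifier[[1]]$value, "S7")
})

test_that("demographics answers merge into the single Patient resource", {
  m <- mini_gecco()
  r <- make_response(list(
    "demographics.biologicalSex" = list(valueCoding = list(
      system = "http://hl7.org/fhir/administrative-gender", code = "female",
      display = "Female")),
    "demographics.birthDate" = list(valueDate = "1965-03-02")
  ))
  b <- map_response(r, m)
  expect_identical(resource_types(b), "Patient")
  pat <- bundle_resources(b)[[1]]
  expect_identical(pat$gender, "female")
  expect_identical(pat$birthDate, "1965-03-02")

  # the German administrative codes map onto FHIR's gender tokens
  r2 <- make_response(list(
    "demographics.biologicalSex" = list(valueCoding = list(
      system = "http://fhir.de/CodeSystem/gender-amtlich-de", code = "X",
      display = "Divers"))))
  expect_identical(bundle_resources(map_response(r2, m))[[1]]$gender, "other")
})

test_that("meta category answered no or unknown defaults every child Condition", {
  m <- mini_gecco()

  for (case in list(list(ans = no_answer(), code = "refuted"),
                    list(ans = unknown_answer(), code = "unconfirmed"))) {
    r <- make_response(list("anamnesis.hasChronicLungDisease" = case$ans))
    b <- map_response(r, m)
    types <- resource_types(b)
    conds <- bundle_resources(b)[types == "Condition"]
    expect_length(conds, 2)  # one per child of the meta block
    for (cond in conds) {
      expect_identical(cond$verificationStatus$coding[[1]]$code, case$code)
      expect_null(cond$severity)
    }
    names_ <- vapply(conds, function(c) c$code$text, character(1))
    expect_setequal(names_, c("Asthma", "COPD"))
  }
})

test_that("meta category answered yes maps only the answered children", {
  m <- mini_gecco()
  r <- make_response(list(
    "anamnesis.hasChronicLungDisease" = yes_answer(),
    "anamnesis.chronicLungDisease.asthma" = yes_answer()
    # copd left unanswered
  ))
  b <- map_response(r, m)
  conds <- bundle_resources(b)[resource_types(b) == "Condition"]
  expect_length(conds, 1)
  expect_identical(conds[[1]]$verificationStatus$coding[[1]]$code, "confirmed")
  codes <- vapply(conds[[1]]$code$coding, `[[`, character(1), "code")
  expect_true("195967001" %in% codes)  # asthma SNOMED coding present
})

test_that("expand_meta rejects non-Condition children", {
  m <- mini_gecco()
  meta <- resolve_path(m, "anamnesis.chronicLungDisease")$node
  broken <- meta
  broken$children[[1]]$template <- "observation-vital"
  r <- make_response(list())
  expect_error(expand_meta("no", broken, r, m),
               class = "gecco_model_consistency_error")
})

test_that("mapper errors: duplicates, missing annotations, bad values, group paths", {
  m <- mini_gecco()

  dup <- make_response(list("medication.aceInhibitors" = yes_answer()))
  dup$item <- c(dup$item, dup$item)  # same path answered twice
  expect_error(map_response(dup, m), class = "gecco_duplicate_answer_error")

  unann <- make_response(list("medication.aceInhibitors" = yes_answer()),
                         annotate = FALSE)
  expect_error(map_response(unann, m), class = "gecco_unmapped_item_error")

  stray <- make_response(list("no.such.path" = yes_answer()))
  expect_error(map_response(stray, m), class = "gecco_unmapped_item_error")

  grp <- make_response(stats::setNames(list(yes_answer()), "anamnesis"))
  expect_error(map_response(grp, m), class = "gecco_path_kind_error")

  bad_code <- make_response(list("medication.aceInhibitors" = list(
    valueCoding = list(system = SNOMED, code = "999999", display = "Maybe"))))
  expect_error(map_response(bad_code, m), class = "gecco_value_domain_error")

  bad_unit <- make_response(list("vitalSigns.bodyTemperature" = list(
    valueQuantity = list(value = 99.1, unit = "mm", system = UCUM, code = "mm"))))
  expect_error(map_response(bad_unit, m), class = "gecco_value_domain_error")

  no_subject <- make_response(list())
  no_subject$subject <- NULL
  expect_error(map_response(no_subject, m), class = "gecco_context_error")
})

test_that("apply_template binds presence, quantities and severities as documented", {
  m <- mini_gecco()
  ctx <- list(subject_id = "S1", authored = "2021-05-01T10:00:00Z")

  asthma <- resolve_path(m, "anamnesis.chronicLungDisease.asthma")$node
  cond <- apply_template(m$templates[["condition-lung"]], asthma,
                         list(main = yes_answer()), ctx, m)
  expect_identical(cond$resourceType, "Condition")
  expect_identical(cond$verificationStatus$coding[[1]]$code, "confirmed")
  systems <- vapply(cond$code$coding, `[[`, character(1), "system")
  expect_setequal(systems, c("http://fhir.de/CodeSystem/bfarm/icd-10-gm", SNOMED))

  cough <- resolve_path(m, "symptoms.cough")$node
  sev <- apply_template(m$templates[["condition-symptom"]], cough,
                        list(main = yes_answer(),
                             severity = list(valueCoding = list(
                               system = SNOMED, code = "255604002",
                               display = "Mild"))),
                        ctx, m)
  expect_identical(sev$severity$coding[[1]]$code, "255604002")

  temp <- resolve_path(m, "vitalSigns.bodyTemperature")$node
  obs <- apply_template(m$templates[["observation-vital"]], temp,
                        list(main = list(valueQuantity = list(value = 37.8,
                                                              code = "Cel"))),
                        ctx, m)
  expect_identical(obs$valueQuantity$value, 37.8)
  expect_identical(obs$valueQuantity$system, UCUM)
  expect_identical(obs$status, "final")
})

test_that("medication and consent presence answers map to the documented statuses", {
  m <- mini_gecco()
  cases <- list(list(a = yes_answer(), med = "active", consent = "active"),
                list(a = no_answer(), med = "not-taken", consent = "rejected"),
                list(a = unknown_answer(), med = "unknown", consent = "proposed"))
  for (cs in cases) {
    r <- make_response(list("medication.aceInhibitors" = cs$a,
                            "consent.dataProcessing" = cs$a))
    b <- map_response(r, m)
    types <- resource_types(b)
    med <- bundle_resources(b)[[which(types == "MedicationStatement")]]
    con <- bundle_resources(b)[[which(types == "Consent")]]
    expect_identical(med$status, cs$med)
    expect_identical(con$status, cs$consent)
    expect_identical(med$effectiveDateTime, r$authored)
    expect_identical(con$patient$reference,
                     paste0("Patient/", bundle_resources(b)[[1]]$id))
  }
})

test_that("mapping is idempotent: identical input yields identical bytes", {
  corpus <- get_corpus(2, 1, seed = 21)
  for (r in corpus$responses) {
    expect_identical(write_fhir(map_response(r, corpus$model)),
                     write_fhir(map_response(r, corpus$model)))
  }
})

test_that("bundle size equals the independent counting oracle on generated responses", {
  corpus <- get_corpus(50, 2, seed = 42)  # 100 seeded responses
  for (r in corpus$responses) {
    b <- map_response(r, corpus$model)
    expect_identical(length(b$entry), as.integer(oracle_bundle_size(r, corpus$model)))
    expect_identical(sum(resource_types(b) == "Patient"), 1L)
  }
})
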