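test_that("the bundled model contains the documented anamnesis structure", {
  m <- mini_gecco()
  asthma <- resolve_path(m, "anamnesis.chronicLungDisease.asthma")
  expect_false(is.null(asthma))
  expect_identical(asthma$node$question, "Asthma")
  expect_identical(asthma$node$answer$kind, "yes_no_unknown")

  gate <- resolve_path(m, "anamnesis.hasChronicLungDisease")
  expect_identical(gate$node$question,
                   "Does the patient suffer from a chronic lung disease?")

  meta <- resolve_path(m, "anamnesis.chronicLungDisease")
  expect_true(meta$node$is_meta)
  expect_identical(meta$node$enable$path, "anamnesis.hasChronicLungDisease")
  expect_identical(meta$node$enable$answer, "yes")
  expect_gte(length(meta$node$children), 2)
})

test_that("the template registry spans exactly the seven mapped resource types", {
  m <- mini_gecco()
  types <- unique(vapply(m$templates, function(t) t$resource_type, character(1)))
  expect_setequal(types, c("Patient", "Consent", "Observation", "Condition",
                           "Procedure", "MedicationStatement", "Immunization"))
  # every leaf's template resolves and is one of the seven
  for (leaf in walk_leaves(m)) {
    if (is.null(leaf$template)) next
    tpl <- m$templates[[leaf$template]]
    expect_false(is.null(tpl))
    expect_true(tpl$resource_type %in% types)
  }
})

test_that("walk_leaves enumerates exactly the answer-bearing nodes, in document order", {
  m <- mini_gecco()
  leaves <- walk_leaves(m)
  expect_identical(length(leaves), as.integer(oracle_leaf_count(m)))
  expect_true(all(vapply(leaves, function(n) !is.null(n$answer), logical(1))))
  # document order: first leaf is the consent item, stable across calls
  expect_identical(leaves[[1]]$path, "consent.dataProcessing")
  expect_identical(vapply(leaves, `[[`, character(1), "path"),
                   vapply(walk_leaves(m), `[[`, character(1), "path"))
})

test_that("every answer kind of the schema occurs in the bundled model", {
  m <- mini_gecco()
  kinds <- vapply(walk_leaves(m), function(n) n$answer$kind, character(1))
  expect_setequal(unique(kinds),
                  c("yes_no_unknown", "yes_no_unknown_with_date",
                    "yes_no_unknown_with_severity", "coded_choice",
                    "date", "datetime", "quantity", "text", "integer"))
})

test_that("duplicate paths are rejected wherever the duplicate sits", {
  dup_top <- minimal_model_yaml('
  - path: a
    question: "Again"
    children: []
')
  expect_error(load_model(dup_top), class = "gecco_duplicate_path_error")

  dup_leaf <- minimal_model_yaml('
  - path: b
    question: "Block B"
    children:
      - path: a.x
        question: "duplicate leaf"
        answer: {kind: yes_no_unknown}
')
  expect_error(load_model(dup_leaf), class = "gecco_duplicate_path_error")
})

test_that("dangling and cyclic enable rules are rejected", {
  dangling <- minimal_model_yaml('
  - path: b
    question: "B"
    children:
      - path: b.y
        question: "Y?"
        answer: {kind: yes_no_unknown}
        enable: {path: nowhere.special, answer: "yes"}
')
  expect_error(load_model(dangling), class = "gecco_dangling_rule_error")

  to_group <- minimal_model_yaml('
  - path: b
    question: "B"
    children:
      - path: b.y
        question: "Y?"
        answer: {kind: yes_no_unknown}
        enable: {path: a, answer: "yes"}
')
  expect_error(load_model(to_group), class = "gecco_dangling_rule_error")

  cyclic <- minimal_model_yaml('
  - path: b
    question: "B"
    children:
      - path: b.y
        question: "Y?"
        answer: {kind: yes_no_unknown}
        enable: {path: b.z, answer: "yes"}
      - path: b.z
        question: "Z?"
        answer: {kind: yes_no_unknown}
        enable: {path: b.y, answer: "yes"}
')
  expect_error(load_model(cyclic), class = "gecco_cycle_error")
})

test_that("unknown templates and missing codings are rejected", {
  unknown <- minimal_model_yaml('
  - path: b
    question: "B"
    children:
      - path: b.y
        question: "Y?"
        answer: {kind: yes_no_unknown}
        codings:
          - {system: "http://snomed.info/sct", code: "222"}
        template: does-not-exist
')
  expect_error(load_model(unknown), class = "gecco_unknown_template_error")

  uncoded <- minimal_model_yaml('
  - path: b
    question: "B"
    children:
      - path: b.y
        question: "Y?"
        answer: {kind: yes_no_unknown}
        template: condition-any
')
  expect_error(load_model(uncoded), class = "gecco_model_consistency_error")
})

test_that("path resolution understands composite part suffixes", {
  m <- mini_gecco()
  main <- resolve_path(m, "vaccination.covid19")
  expect_identical(main$part, NA_character_)
  date <- resolve_path(m, "vaccination.covid19.date")
  expect_identical(date$part, "date")
  expect_identical(date$node$path, "vaccination.covid19")
  sev <- resolve_path(m, "symptoms.cough.severity")
  expect_identical(sev$part, "severity")
  # a part suffix on a non-composite node does not resolve
  expect_null(resolve_path(m, "symptoms.cough.date"))
  expect_null(resolve_path(m, "medication.aceInhibitors.severity"))
  expect_null(resolve_path(m, "no.such.path"))
})

test_that("inserting a duplicate of any existing path makes loading fail", {
  base <- yaml::read_yaml(system.file("extdata", "mini-gecco.yaml",
                                      package = "geccomap"))
  victim_paths <- c("consent.dataProcessing", "anamnesis.hasChronicLungDisease",
                    "symptoms.cough", "therapy.dialysis")
  for (p in victim_paths) {
    doc <- base
    doc$roots[[length(doc$roots) + 1L]] <- list(
      path = "intruder", question = "intruder",
      children = list(list(path = p, question = "dup",
                           answer = list(kind = "yes_no_unknown"))))
    expect_error(load_model(yaml::as.yaml(doc)),
                 class = "gecco_duplicate_path_error")
  }
})
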