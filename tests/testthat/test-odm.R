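test_that("export produces one ItemDef per questionnaire leaf, with path aliases", {
  m <- mini_gecco()
  q <- render_questionnaire(m)
  study <- parse_odm(odm_export(q))

  non_group <- Filter(function(it) !identical(it$type, "group"),
                      geccomap:::flatten_items(q))
  expect_identical(length(study$items), length(non_group))

  q_paths <- vapply(non_group, geccomap:::item_gecco_path, character(1))
  odm_paths <- vapply(study$items, function(it) {
    for (al in it$aliases) if (identical(al$context, "gecco-path")) return(al$name)
    NA_character_
  }, character(1))
  expect_setequal(unname(odm_paths), q_paths)
})

test_that("export then convert reproduces paths, texts, codings and conditions", {
  m <- mini_gecco()
  q <- render_questionnaire(m)
  study <- parse_odm(odm_export(q))

  with_ref <- convert_odm(study, reference = q)
  expect_true(questionnaire_equivalent(q, with_ref))

  # single-coded code lists need no reference
  without_ref <- convert_odm(study)
  expect_true(questionnaire_equivalent(q, without_ref))

  # converted form keeps the source url
  expect_identical(with_ref$url, q$url)
})

test_that("an empty questionnaire survives the ODM round trip", {
  q <- render_questionnaire(load_model('
name: empty
roots: []
'))
  study <- parse_odm(odm_export(q))
  expect_length(study$items, 0)
  converted <- convert_odm(study)
  expect_null(converted$item)
  expect_true(questionnaire_equivalent(q, converted))
})

test_that("multi-coded code lists resolve via the reference questionnaire or fail", {
  study <- parse_odm(multi_coded_odm())
  expect_error(convert_odm(study), class = "gecco_ambiguous_coding_error")

  # the bundled reference questionnaire codes yes/no/unknown with SNOMED
  ref <- render_questionnaire(mini_gecco())
  converted <- convert_odm(study, reference = ref)
  gate <- converted$item[[1]]$item[[1]]
  systems <- vapply(gate$answerOption, function(o) o$valueCoding$system,
                    character(1))
  expect_identical(unique(systems), "http://snomed.info/sct")

  # a reference coding the options with LOINC picks LOINC instead
  loinc_ref <- ref
  relabel <- function(items) lapply(items, function(it) {
    if (!is.null(it$answerOption)) {
      it$answerOption <- lapply(it$answerOption, function(o) {
        o$valueCoding$system <- "http://loinc.org"
        o
      })
    }
    if (!is.null(it$item)) it$item <- relabel(it$item)
    it
  })
  loinc_ref$item <- relabel(loinc_ref$item)
  converted2 <- convert_odm(study, reference = loinc_ref)
  systems2 <- vapply(converted2$item[[1]]$item[[1]]$answerOption,
                     function(o) o$valueCoding$system, character(1))
  expect_identical(unique(systems2), "http://loinc.org")
})

test_that("collection conditions become enableWhen with the controlling coding", {
  m <- mini_gecco()
  q <- render_questionnaire(m)
  converted <- convert_odm(parse_odm(odm_export(q)))
  items <- geccomap:::flatten_items(converted)
  paths <- vapply(items, geccomap:::item_gecco_path, character(1))
  lids <- vapply(items, `[[`, character(1), "linkId")

  asthma <- items[[match("anamnesis.chronicLungDisease.asthma", paths)]]
  expect_length(asthma$enableWhen, 1)
  ew <- asthma$enableWhen[[1]]
  expect_identical(ew$answerCoding$code, YES_CODE)
  expect_identical(ew$answerCoding$system, SNOMED)
  expect_identical(unname(paths[match(ew$question, lids)]),
                   "anamnesis.hasChronicLungDisease")
})

test_that("broken ODM documents raise the documented errors", {
  expect_error(parse_odm("<ODM><oops"), class = "gecco_parse_error")

  dangling <- sub('CodeListOID="CL.1"', 'CodeListOID="CL.missing"',
                  multi_coded_odm())
  expect_error(parse_odm(dangling), class = "gecco_reference_error")

  bad_cond <- sub('<ItemRef ItemOID="I.anamnesis.hasChronicLungDisease" Mandatory="No"/>',
                  paste0('<ItemRef ItemOID="I.anamnesis.hasChronicLungDisease" ',
                         'Mandatory="No" CollectionExceptionConditionOID="C.1"/>'),
                  multi_coded_odm())
  bad_cond <- sub('</MetaDataVersion>',
                  paste0('<ConditionDef OID="C.1" Name="c">',
                         '<FormalExpression Context="mdm-equality">',
                         'I.x &gt; 5</FormalExpression></ConditionDef>',
                         '</MetaDataVersion>'),
                  bad_cond)
  ref <- render_questionnaire(mini_gecco())
  expect_error(convert_odm(parse_odm(bad_cond), reference = ref),
               class = "gecco_unsupported_condition_error")
})

test_that("unknown metadata elements are skipped with a warning", {
  extra <- sub('</MetaDataVersion>',
               '<SomeVendorExtension/></MetaDataVersion>', multi_coded_odm())
  expect_warning(parse_odm(extra), "SomeVendorExtension")
})
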