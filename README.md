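# geccomap

Patient-reported outcomes (PROs) for COVID-19 research are collected with
apps that speak generic FHIR `Questionnaire` / `QuestionnaireResponse`
resources, while central research platforms only accept strictly profiled,
terminology-coded resources such as those of the German Corona Consensus
(GECCO) core data set — `Patient`, `Consent`, `Observation`, `Condition`,
`Procedure`, `MedicationStatement` and `Immunization`, coded with LOINC,
SNOMED CT, ICD-10-GM and ATC. A response is just linkIds and raw values;
a platform-ready `Condition` needs codings, a verification status, a
subject reference and a recording time. `geccomap` is an interface
component that closes this gap for study developers and data engineers.

At its core is a **hierarchical logical model** `M`: a tree of clinical
concepts, each with a unique path `p` (e.g.
`anamnesis.chronicLungDisease.asthma`), a question text, an answer
specification, concept codings `{(system, code)}` and a profile template
`T(p)`. From `M` the package derives everything:

* **Questionnaire generation** — `render_questionnaire(M)` emits a FHIR R4
  Questionnaire with one item per node; every item carries `p` in a
  `compass-gecco-item` extension, composite answer types
  (`YesNoUnknownWithDate`, `YesNoUnknownWithSeverity`) expand into a
  choice plus a conditionally enabled child item, and model-level
  visibility rules become `enableWhen`.
* **Response simulation** — `generate_responses(Q, n, k, seed)` draws
  uniform random answers from each item's own domain while honoring every
  `enableWhen`, so all answer options can be tested without patient data.
* **Mapping** — `map_response(R, M)` resolves each answered item's path,
  applies `T(p)` and emits a transaction bundle: exactly one `Patient`
  (identifier = the pseudonymous SubjectID) plus one profiled resource per
  answered template-bearing element. Subject references and recording
  times are filled per resource type (`Condition.recordedDate = authored`,
  …), except `Procedure`/`Immunization` dates, which are domain data and
  come from answers. Category-level *meta elements* answered "no"/
  "unknown" expand into one refuted/unconfirmed `Condition` per child.
* **Conformance validation** — `validate_bundle(B, M)` checks every bundle
  against an explicit rule catalog (`conformance_rules()`).
* **CDISC ODM bridge** — `odm_export()` / `parse_odm()` / `convert_odm()`
  round-trip annotated questionnaires through ODM study definitions,
  carrying paths in `Alias` tags and resolving multi-coded code-list items
  via a reference questionnaire.

The bundled `mini_gecco()` model is a compact synthetic subset of GECCO
covering every answer kind and all seven resource types.

## Worked example

```r
library(geccomap)

m <- mini_gecco()
m
#> <gecco_model> mini-gecco
#>   canonical base: https://example.org/fhir/compass
#>   16 answer-bearing elements, 9 profile templates (Condition, Consent,
#>   Immunization, MedicationStatement, Observation, Patient, Procedure)

q <- render_questionnaire(m)
r <- generate_responses(q, n_subjects = 1, per_subject = 1, seed = 7)[[1]]
b <- map_response(r, m)
table(vapply(b$entry, function(e) e$resource$resourceType, character(1)))
#>           Condition             Consent        Immunization MedicationStatement
#>                   4                   1                   1                   1
#>         Observation             Patient           Procedure
#>                   5                   1                   1

validate_bundle(b, m)
#> <validation report> PASSED — 14 resource(s) checked, 0 issue(s)
```

Fourteen resources: the `Patient` for `subject-001`, four `Condition`s
(two chronic lung diseases from the meta block plus two graded symptoms),
five `Observation`s, and one each of `Consent`, `Immunization`,
`MedicationStatement` and `Procedure`. With this seed the vaccination
question was answered "no", so the `Immunization` is emitted with status
`not-done` rather than omitted; the body-temperature `Observation` reads
`38.2 Cel` with `effectiveDateTime` equal to the response's `authored`
timestamp (`2021-06-28T00:05:18Z`), because Observation times are
context-filled while Immunization dates must come from answers.

The whole pipeline as one call:

```r
run_pipeline(n_subjects = 10, per_subject = 2, seed = 1, out_dir = "run")
#> <pipeline summary> seed 1: 20 responses, 20 bundles, 20 passed conformance
```

A command-line wrapper with subcommands `render`, `simulate`, `map`,
`validate`, `odm-export`, `odm-convert` and `pipeline` is installed at
`system.file("cli", "geccomap.R", package = "geccomap")`.

## Package layout

* `R/` — logical model (`load_model`, `mini_gecco`, `walk_leaves`,
  `resolve_path`), questionnaire renderer, response tools, mapper
  (`map_response`, `resolve_context`, `expand_meta`, `apply_template`),
  conformance checker, ODM bridge, pipeline.
* `inst/extdata/mini-gecco.yaml` — the bundled model definition (and the
  schema by example).
* `vignettes/gecco-mapping.Rmd` — the methods vignette: model semantics,
  mapping and encoding decisions, generator scope, rule catalog,
  limitations.
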