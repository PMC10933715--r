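---
title: "From a logical model to profiled FHIR resources: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a logical model to profiled FHIR resources: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geccomap)
```

## The problem

Patient-reported outcomes for COVID-19 research are typically collected
with apps that exchange FHIR `Questionnaire` and `QuestionnaireResponse`
resources. These two types only guarantee *syntactic* interoperability: a
response is a tree of linkIds and raw values, with no medical terminology
attached. Central research platforms, on the other hand, accept strictly
profiled resources — `Patient`, `Condition`, `Observation`, `Procedure`,
`MedicationStatement`, `Immunization`, `Consent` — whose `code` elements
are bound to LOINC, SNOMED CT, ICD-10-GM or ATC. The German Corona
Consensus (GECCO) core data set is the canonical example of such a profile
family.

`geccomap` closes that gap with a *logical model*: a hierarchical,
terminology-annotated definition of the data set that is questionnaire-
shaped. Everything else is derived from it:

1. `render_questionnaire()` generates the annotated reference
   questionnaire (one item per model element, each carrying its model path
   in an extension);
2. `generate_responses()` produces seeded random, condition-consistent
   responses for testing;
3. `map_response()` binds an annotated response back to the model and
   emits a transaction bundle of profiled resources;
4. `validate_bundle()` checks every bundle against an explicit conformance
   rule catalog;
5. `parse_odm()` / `convert_odm()` / `odm_export()` bridge to CDISC ODM
   study definitions so items authored in metadata registries keep their
   model annotations.

## The logical model

A model document (YAML) defines a tree of nodes. Each node has a unique
dot-separated `path`, a question text, and — for answer-bearing leaves —
an answer specification, a set of concept codings, and the id of the
profile template that maps it. The bundled `mini_gecco()` fixture is a
compact, fully synthetic subset of GECCO that exercises every structural
pattern; real deployments would write their own document against the same
schema.

Answer kinds:

| kind | questionnaire item | mapped value |
|---|---|---|
| `yes_no_unknown` | choice (3 SNOMED qualifier options) | presence status |
| `yes_no_unknown_with_date` | choice + gated date child | presence + event date |
| `yes_no_unknown_with_severity` | choice + gated severity child | presence + severity |
| `coded_choice` | choice over the node's options | coded value |
| `date`, `datetime` | date / dateTime | date value |
| `quantity` | quantity with UCUM unit and range | `valueQuantity` |
| `text`, `integer` | string / integer | `valueString` / `valueInteger` |

The composite kinds exist because one clinical fact often needs two
questions — it is pointless to ask for the severity of a cough the patient
denies having. A composite renders as a choice item plus one child item
that is enabled only when the choice is "yes". Both carry the model path;
the child's path gets a reserved suffix (`.date`, `.severity`) that
`resolve_path()` understands, so the two questionnaire items merge back
into *one* resource at mapping time and are not mistaken for a duplicate
answer.

**Meta elements.** A category question ("Does the patient suffer from a
chronic lung disease?") gates a block of disease items. In the model the
gate is an ordinary `yes_no_unknown` leaf *without* a template; the block
is a group with `meta: true` whose enable rule points at the gate. When
the gate is answered "no" or "unknown" the apps never show the children —
but the data set still expects one `Condition` per disease, so
`expand_meta()` emits each child with a `refuted` (respectively
`unconfirmed`) verification status and ignores any child content. Only a
"yes" lets the children speak for themselves. The verification codings are
settings of the model document, not hard-coded.

**Invariants enforced at load time**: global path uniqueness (each model
element may appear exactly once in a questionnaire, because a single model
instance drives the transformation), resolvable and acyclic enable rules
(cycles are detected by following each node's innermost applicable rule to
its controlling item), resolvable templates, concept codings on every
template-bearing node.

## Rendering choices

* linkIds are hierarchical position numbers (`"3.2.1"`), generated by
  `linkid_scheme()`. They are questionnaire-local; the model path lives
  only in the annotation extension
  (`<canonical_base>/StructureDefinition/compass-gecco-item`), which is
  what the mapper keys on. This keeps linkIds free to change when a
  researcher edits the questionnaire.
* Each `answerOption` carries exactly one coding — a FHIR limitation.
  One coding is sufficient to identify an option; the mapper re-attaches
  *all* concept codings of the node when it builds the resource.
* Composite expansion order is fixed: choice first, then the date/severity
  child as its first child item. enableWhen conditions therefore only ever
  reference earlier items in document order.
* `required` is `false` everywhere: skipping a question must never block
  submission in an ePRO setting.
* Quantity/integer/date items carry their admissible range as standard
  `minValue`/`maxValue` extensions and their unit as the
  `questionnaire-unit` extension, so the questionnaire alone is enough for
  the response generator.

Rendering is deterministic; two renders of the same model serialize to
identical bytes, which makes reference questionnaires diffable.

## The response generator

The generator emulates the test traffic of a study: `n_subjects ×
per_subject` responses, subjects tokenized `subject-001, …`, `authored`
drawn uniformly from a configurable window (default the first half of
2021). Items are walked in document order; an item whose enableWhen (its
own or an ancestor's) is unsatisfied is skipped entirely; visible items
draw uniformly from their own domain — answerOptions for choices, the
min/max range for dates, quantities and integers, a small phrase pool for
free text. An optional `skip_prob` leaves visible items unanswered to
simulate optional questions; the default is 0 so that option coverage is
reached quickly.

All randomness runs through one seed, and the global RNG state is saved
and restored, so generation is reproducible and byte-identical per seed.

What the generator does *not* emulate: realistic answer prevalences
(everything is uniform), correlated symptoms, free-text in natural
language, device or transport failures, or repeated questionnaire
versions. Passing the round-trip suite therefore demonstrates structural
and semantic correctness of the pipeline over the full answer space — not
epidemiological plausibility of the synthetic cohort.

## Mapping

The contextual attributes are fixed per resource type:

| resource | subject attribute | time attribute |
|---|---|---|
| Patient | — | — |
| Consent | `Consent.patient` | — |
| Observation | `Observation.subject` | `Observation.effectiveDateTime` |
| Condition | `Condition.subject` | `Condition.recordedDate` |
| Procedure | `Procedure.subject` | (from answer: `performedDateTime`) |
| MedicationStatement | `MedicationStatement.subject` | `MedicationStatement.effectiveDateTime` |
| Immunization | `Immunization.patient` | (from answer: `occurrenceDateTime`) |

Context-filled times are the response's `authored` timestamp. Procedure
and Immunization dates are domain data — when a vaccination happened, not
when the patient filled in the form — so they bind from answer content
only.

Design decisions worth recording:

* **Presence encoding.** yes/no/unknown on `Condition` maps to
  `verificationStatus` confirmed/refuted/unconfirmed (configurable in the
  model document). `MedicationStatement` uses status
  active/not-taken/unknown; `Immunization` uses completed/not-done with a
  `statusReason` of "unknown" for the unknown case, and an
  `occurrenceString` of `"unknown"` when no date is available (FHIR
  requires *some* occurrence); `Consent` uses active/rejected/proposed.
* **The Patient is always emitted**, even for an empty response: every
  other resource needs a reference target. Its identifier is the
  pseudonymous subject token; answered demographics (biological sex, birth
  date) merge into `Patient.gender`/`Patient.birthDate` rather than
  producing separate resources. The five-valued German sex options fold
  onto FHIR's administrative gender (`X`/`D` → `other`).
* **Deterministic ids.** Every resource id is a 32-bit FNV-1a hash of
  (subject, path, authored) plus a readable path tail, truncated to FHIR's
  64-character limit. Remapping the same response reproduces the same
  bundle byte for byte, and resubmission via PUT-based transaction entries
  is idempotent on a server.
* **Unanswered enabled items produce nothing.** No data-absent-reason
  resources are fabricated; the only exception is meta expansion, where
  the data set semantics demand defaulted children.

Mapping rejects, with typed conditions: answered items without a path
annotation (`annotate_response()` fixes this when the questionnaire is
known), paths that resolve to groups, values outside the node's answer
domain (including a wrong UCUM unit), and the same path answered twice.

## Conformance checking

`validate_bundle()` implements an explicit rule catalog
(`conformance_rules()`): exactly one Patient with an identifier; subject
and time attributes per the table above, including the two answer-driven
exceptions; a `code` element whose codings match a model concept; all
coding systems registered in the model; status/verification elements
within the template's fixed values; UCUM units matching the model. The
report is a plain data frame plus a boolean verdict (`passed` ⇔ no
error-severity issue), serialized as JSON by the CLI. Full
StructureDefinition snapshot validation (cardinalities, slicing,
terminology-server expansion) is deliberately out of scope — the catalog
covers exactly the properties the mapper promises.

## The ODM bridge

Metadata registries describe forms in CDISC ODM. The bridge keeps the
model linkage through two conventions: an item's model path travels in an
ODM `Alias` with context `"gecco-path"`, and each `CodeListItem` carries
one `Alias` per coding with the code system URI as context. ODM allows
several such aliases per code-list item while FHIR allows exactly one
coding per answerOption; `convert_odm()` resolves the ambiguity by
choosing the system that the supplied reference questionnaire uses for the
same model path, and fails loudly without one.

Conditions use an equality-only grammar — `I.<path> == "<code>"` in a
`FormalExpression` referenced from the ItemRef's collection condition,
read as "collect when true". Anything else raises an explicit
unsupported-condition error rather than guessing.

ODM item groups do not nest, so `odm_export()` flattens the item tree into
one ItemGroupDef per top-level branch and attaches each leaf's *effective*
enable condition (its own, else the innermost enclosing group's). The
round-trip guarantee is therefore semantic, not structural:
`questionnaire_equivalent()` compares, per model path, the question text,
the set of option codings, and the effective enable condition — and the
bundled model is designed so that no leaf needs more than one stacked
condition, which the export format can represent.

## Problem sizes and numerical choices

The test suite runs the integration scenario at 10 subjects × 2 responses
(the scale at which such interface components are typically smoke-tested
against a platform), the round-trip and counting properties over 100
seeded responses, and the enableWhen oracle over 200 — sizes at which
every answer option of every reachable item is drawn many times over while
the whole suite stays in the tens of seconds. Quantity values are drawn
uniformly within the model's per-item range and rounded to one decimal;
body temperature uses 35–42 °C; the authored window is
2021-01-01–2021-06-30. Degenerate inputs are defined, not errors: an empty
model renders a zero-item (still schema-valid) questionnaire, an empty
questionnaire generates answerless completed responses, and an answerless
response maps to a Patient-only bundle.

## Known limitations

* Each model element may be answered at most once per response; repeating
  questionnaires or repeated elements are rejected by design.
* The conformance checker validates the package's own contract, not the
  full profile snapshots of an external implementation guide.
* The ODM subset covers study-definition metadata only (no clinical data
  sections, measurement units, or administrative metadata), and condition
  expressions are limited to single equalities.
* The bundled model is a representative subset; it does not reproduce the
  several hundred elements of the full GECCO data set, only every
  structural pattern needed to drive and test the machinery.
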