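Package: geccomap
Title: Logical-Model-Driven Mapping of FHIR Questionnaire Responses to
    COVID-19 Core Data Set Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for collecting COVID-19 patient-reported outcomes in an
    interoperable way. A hierarchical, terminology-annotated logical model
    (a bundled subset of the German Corona Consensus core data set) drives
    the generation of an annotated FHIR R4 reference Questionnaire, the
    transformation of QuestionnaireResponses into profiled FHIR resources
    (Patient, Consent, Observation, Condition, Procedure,
    MedicationStatement, Immunization), and a rule-based conformance check
    of the resulting transaction bundles. Includes a seeded random-response
    generator for end-to-end testing without patient data, and a CDISC ODM
    bridge that converts study definitions to annotated Questionnaires and
    back.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
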