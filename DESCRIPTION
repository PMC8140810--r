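Package: oncomop
Title: OMOP Oncology Extension Toolkit for Observational Cancer Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing oncology data under an OMOP-style common
    data model. Precoordinates ICD-O-3 histology/behavior/topography codes
    into single condition concepts and integrates them into a SNOMED-style
    disease hierarchy by a two-step equivalence-or-insertion algorithm;
    represents diagnostic modifiers as measurements explicitly linked to
    their diagnosis; models nested disease and treatment episodes
    (EPISODE/EPISODE_EVENT); detects chemotherapy regimens and lines of
    therapy from drug-exposure records against HemOnc-style regimen
    definitions; performs a vocabulary-driven tumor-registry to CDM ETL with
    registry/EHR death reconciliation; and characterizes first-line
    treatment patterns in derived cohorts. Includes a seeded synthetic-data
    generator for vocabularies, patients, planted regimen histories, and
    registry abstracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
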