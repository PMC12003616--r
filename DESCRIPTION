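Package: psprules
Title: Rule-Based Phenotyping for Progressive Supranuclear Palsy
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, scriptable implementation of the Movement Disorder
    Society (MDS) clinical diagnostic criteria for progressive supranuclear
    palsy (PSP). Maps per-patient binary core clinical features (ocular
    motor, postural instability, akinesia, cognitive) and clinical clues to
    phenotype allocations with diagnostic-certainty levels, resolves
    simultaneous allocations to a single diagnosis with the Multiple
    Allocations eXtinction (MAX) precedence rules, and flags the joint
    "probable 4R-tauopathy" category. Includes derivation of composite
    features from raw clinical sub-observations (frontal cognitive items,
    corticobasal signs, levodopa challenge, pull test), a three-year
    temporal gate, CSV/JSON batch classification with explanation traces, a
    command-line interface, and synthetic-cohort and exhaustive-profile
    generators so the whole rule set is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
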