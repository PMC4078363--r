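Package: raclaims
Title: Rule-Based Rheumatoid Arthritis Case Ascertainment in Health Administrative Claims
Version: 1.0.0
Authors@R:
    person("Claims", "Phenotyping Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A rule engine for identifying rheumatoid arthritis (RA) patients in
    health administrative claims data (physician billing, hospital discharge
    abstracts, emergency department records, and pharmacy claims), together with
    the diagnostic-accuracy machinery used to validate such case definitions
    against a chart-review reference standard. Case definitions are expressed in
    a small declarative grammar (counts of RA-coded encounters within temporal
    windows, minimum gaps between codes, musculoskeletal-specialist and
    drug-exposure requirements, and exclusion rules), evaluated deterministically
    per patient. Includes sensitivity/specificity/predictive-value computation
    with binomial confidence intervals, lexicographic algorithm ranking, a seeded
    synthetic-cohort generator emulating an Ontario primary-care population, and
    a reproducible simulate/evaluate/rank pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
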