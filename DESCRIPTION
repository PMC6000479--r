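Package: acsnorms
Title: Regression-Based Normative Data and Test-Retest Reliability for
    Online Cognitive Test Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for establishing regression-based
    normative data for computerized neuropsychological test batteries such
    as the Amsterdam Cognition Scan. Implements robust outlier cleaning
    (per-age-group median-absolute-deviation limits and zero-score rules),
    normalizing transforms and standardization against a reference cohort,
    composite battery scoring, test-retest reliability (two-way
    absolute-agreement intraclass correlation, standard error of
    measurement, smallest detectable change with practice-effect
    adjustment), demographic multiple-regression norm models with pruning
    and diagnostics, demographically corrected norm scoring of new
    individuals, and a calibrated two-occasion synthetic cohort generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    car,
    lmtest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
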