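Package: efrailch
Title: Electronic Frailty Measurement from Routine Hospital Register Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs and validates an electronic frailty score (0-12)
    for older adult inpatients from routinely collected hospital register
    data. Eight frailty dimensions (cognition, general health, functional
    independence, social support, medication, mood, continence,
    self-reported performance) are scored at hospital admission and
    discharge, four of them via a two-step mixed-type cluster analysis
    (log-likelihood distance preclustering, hierarchical agglomeration,
    Schwarz-Bayesian criterion model selection). Includes a calibrated
    synthetic hospital-register cohort generator, inclusion/exclusion and
    sparse-dimension filtering, score distribution and prevalence
    summaries, admission-discharge change statistics, and ROC/cutpoint
    validation against the Functional Independence Measure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    nortest,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
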