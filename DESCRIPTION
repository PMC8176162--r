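Package: peepchallenge
Title: PEEP-Challenge Dynamic Indices for Predicting Fluid Responsiveness
    During One-Lung Ventilation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes pulse pressure variation (PPV) and stroke volume
    variation (SVV) from beat-level hemodynamic records, evaluates whether
    a PEEP-challenge-induced change in these dynamic preload indices
    predicts fluid responsiveness during one-lung ventilation, and carries
    the full downstream analysis: responder classification from the
    stroke-volume response to a fluid bolus, empirical ROC curves with
    Hanley-McNeil standard errors, confidence intervals and AUC comparison
    tests, Youden-optimal cutoffs with operating-point statistics,
    gray-zone (inconclusive range) analysis by stratified bootstrap of
    optimal thresholds and by sensitivity/specificity floors, group
    comparison tables, and an AUC-based sample-size calculation. A
    synthetic cohort and beat-series generator parameterized by published
    group distributions makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
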