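Package: dsrscreen
Title: Validation Toolkit for the Delayed Story Recall Screening Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating story-recall screening tests for mild
    cognitive impairment and dementia: idea-unit scoring and retention
    percentages, operational diagnostic classification from clinical scale
    gates, age- and education-stratified normative tables with Petersen-style
    cutoffs, regression-based demographically adjusted T scores, ROC analysis
    with Mann-Whitney AUC, Hanley-McNeil confidence intervals and
    Youden-optimal cutoffs, base-rate-adjusted positive and negative
    predictive values, test-retest and partial-correlation reliability, and a
    seeded synthetic-cohort generator (moment-matched truncated and censored
    normals) so the whole pipeline is reproducible without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
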