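Package: oncomatch
Title: Biomarker-Drug Matching Scores and Combination-Therapy Ranking for
    Precision Oncology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rating how well a drug regimen covers the pathogenic
    molecular alterations of a tumor. Provides a curated drug-biomarker
    knowledge-base data model with direct, indirect (pathway-level) and
    resistance match rules; a per-regimen matching score expressed as an
    integer percentage of the profile's maximum attainable hit score;
    exhaustive enumeration and ranking of drug combinations under clinical
    eligibility constraints; retrospective validation statistics (RECIST-based
    outcome classification, confusion matrices with exact binomial confidence
    intervals, ROC curves and AUC via the Mann-Whitney identity, Youden-index
    threshold selection); and a seeded synthetic-cohort simulator with a
    logistic score-outcome model for end-to-end testing without patient data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
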