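Package: snpconsensus
Title: Consensus Classification of Missense Variant Effects with
    Confidence Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines the class calls of heterogeneous missense-variant
    effect predictors into a single weighted majority-vote consensus.
    Raw, tool-specific confidence scores (continuous or categorical) are
    calibrated to observed accuracy on a labelled benchmark by
    equal-count binning with moving-average smoothing, fitted separately
    per predicted class; the consensus score is the mean of calibrated
    confidences signed by each tool's call, and its own confidence is
    calibrated the same way. Includes normalized (class-balanced)
    evaluation metrics (accuracy, Matthews correlation coefficient,
    ROC AUC), a leakage-free benchmark construction workflow
    (conflict purging, deduplication, alignment-based removal of
    positions overlapping training data), and a synthetic
    predictor-ensemble simulator with controlled accuracy, confidence
    informativeness, inter-tool correlation and missingness so every
    stage is testable without running any external prediction tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
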