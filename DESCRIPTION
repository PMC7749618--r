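Package: alphassa
Title: Adaptive Singular Spectrum Analysis of Resting-State EEG Alpha Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Extraction and classification of occipital alpha rhythms from
    multichannel resting-state EEG using adaptive singular spectrum analysis
    (SSA). Provides epoch segmentation with amplitude-threshold artifact
    rejection, anti-aliased resampling, Hankel-embedding SSA decomposition
    with eigenvalue-similarity and peak-frequency component grouping,
    amplitude-adaptive ocular (EOG) subspace removal, individualized alpha
    peak frequency (center-of-gravity) and absolute alpha power features,
    two-sample group statistics, and linear support-vector-machine
    classification with stratified cross-validation and ROC/AUC. Includes a
    synthetic two-group cohort generator with known ground truth for
    validation, and a small command-line driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
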