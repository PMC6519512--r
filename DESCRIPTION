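Package: FCSelect
Title: Stability Selection of Discriminative Functional-Connectivity Edges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for two-group resting-state functional
    connectivity studies: temporal cleaning of ROI time series (detrending,
    confound regression, band-pass filtering), Pearson connectivity and edge
    vectorization, two-sample t-test screening, nested cross-validated LASSO
    stability selection with the one-standard-error rule, linear support
    vector machine classification, repeated k-fold cross-validation with grid
    search over the selection parameters, permutation testing of accuracy and
    AUC, and cross-fold feature-occurrence reporting with family-wise-error
    corrected group-difference tests. Includes a synthetic-data module that
    generates two-group cohorts with a known sparse set of discriminative
    edges so that every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    e1071,
    signal,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
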