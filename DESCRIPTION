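Package: emrprep
Title: Preprocessing and Modeling of Missing, Imbalanced, and Sparse
    Emergency Medical Record Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A systematic pipeline for developing clinical prediction
    models from low-quality emergency-department tabular data. Provides
    random-forest single imputation of missing values with R-squared and
    kappa validation, k-means centroid-proximal undersampling of the
    majority class to user-chosen class ratios, principal-component
    reduction of sparse binary diagnosis features with cumulative-variance
    rank selection, variable screening (synonym merging, missingness and
    prevalence thresholds, low/normal/high discretization against
    reference ranges), chi-square and univariate logistic prefilters with
    AUROC-driven forward group selection, multivariate logistic fits with
    odds ratios and separation diagnostics, principal-component logistic
    regression, a comparison model zoo, repeated stratified subsampling
    evaluation with percentile confidence intervals, and calibration
    assessment via Brier scores and reliability curves. A synthetic
    electronic-medical-record cohort generator reproduces the targeted
    pathologies (class imbalance, MCAR/MAR/MNAR missingness, sparse and
    perfectly separating diagnosis indicators) with ground truth retained
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    glmnet,
    e1071,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
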