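Package: strokeconsensus
Title: Consensus Ensemble Classification of Ischemic Stroke Etiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the etiology of ischemic stroke (TOAST
    classes 1-4) from tabular features derived from electronic health
    records. Implements a nine-classifier consensus ensemble: four tuned
    base learners (elastic-net logistic regression, kernel support vector
    classifier, random forest, gradient-boosted trees), an alternative
    margin-based SVC calibration, four summary-statistic probability
    ensembles (mean, median, maximum, minimum), and majority-vote
    meta-classification with a support-quantile certainty heuristic that
    abstains to "persistently cryptogenic". Includes the surrounding
    machinery: clinical feature discretization, MaxInfo completeness
    filtering, chained-equation imputation with predictive mean matching,
    PCA with variance-threshold component selection, stratified and
    repeated multi-fold cross-validation, a seven-metric multi-class
    evaluation panel, subgroup and misclassification analyses, and a
    synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
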