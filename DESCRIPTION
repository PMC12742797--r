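Package: chdrisk
Title: Enhanced Tree, Boosting and SVM Ensembles for Imbalanced Coronary
    Heart Disease Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating coronary heart disease (CHD)
    risk classifiers on imbalanced survey-style cohorts. Implements four
    enhanced base learners (a soft-split adaptive noise-resistant decision
    tree, a SMOTE-balanced Shapley-weighted random forest, a Huber-loss
    gradient boosting machine with early stopping, and an RBF-kernel support
    vector machine tuned by Gaussian-process expected improvement), five
    ensemble combiners (bagging, AdaBoost, stacking, majority voting and
    Bayesian model averaging), SMOTE oversampling with Yamane-sized
    stratified subsampling, a confusion-matrix / ROC / precision-recall /
    calibration / learning-curve evaluation suite, domain-wise k-means risk
    subgroup analysis with chi-square tests and cluster-dummy logistic
    regression, and Shapley-value plus surrogate-tree explainability. A
    synthetic survey-style cohort generator makes every component testable
    without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    kernlab,
    pROC,
    rpart
Config/testthat/edition: 3
RoxygenNote: 7.3.3
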