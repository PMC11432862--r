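Package: edrva
Title: Outcome-Aware Clustering and Risk Prediction for 72-Hour Emergency
    Department Return-Visit Admissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting 72-hour emergency department (ED)
    return-visit admissions (RVA) from tabular per-visit EHR-style data.
    Implements deep significance clustering (DICE): joint optimization of an
    autoencoder, k-means centroids and a logistic outcome head under a Wald
    significance constraint on the cluster-outcome association; greedy forward
    feature search maximizing validation AUC; Youden-index thresholding;
    likelihood-ratio, subgroup, ablation and chart-review-style categorical
    evaluation; a clinical risk-score baseline; and a synthetic ED-visit
    cohort generator with planted risk-tiered cluster structure, monthly
    seasonality and rare-outcome class imbalance for end-to-end testing.
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
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
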