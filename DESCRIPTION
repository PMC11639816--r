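Package: news2plus
Title: Age-Stratified Early-Warning Scoring and Five-Minute-Ahead Hypoxemia
    Severity Prediction for ICU Vital-Sign Time Series
Version: 0.1.0
Authors@R:
    person("VIMY", "Triage Analytics", email = "triage@example.org",
           role = c("aut", "cre"))
Description: Implements an age-stratified extension of the NEWS2 early-warning
    score (per-vital 0-3 "TAG" scores and SpO2-based hypoxemia severity labels
    for adults with and without COPD and for pediatric age groups), together
    with the full modelling pipeline that consumes it: mask-aware cleaning,
    chained-equation imputation with gradient-boosted regressors,
    minute-level linear interpolation of irregular ICU observations,
    five-minute shift-lag dataset construction with sliding windows and
    patient-wise splits, gradient-boosted tree and random-forest classifiers
    with Tree-structured Parzen Estimator hyperparameter search, soft/hard
    voting ensembles, masked LSTM/GRU sequence classifiers, multi-class
    evaluation (MCC, one-vs-rest AUROC/AUPRC), and a synthetic ICU cohort
    generator for end-to-end testing without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
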