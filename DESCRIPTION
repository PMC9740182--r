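Package: hairdyn
Title: Recurrence Dynamics of Hair Elemental Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of single-strand hair elemental
    time series measured along the strand (as by laser-ablation
    ICP-MS), with a complete recurrence-dynamics workflow: a synthetic
    cohort generator with controllable case/control attenuation of
    periodic elemental dynamics, element-to-sulfur ratio preprocessing,
    delay-embedding parameter selection (average mutual information and
    false nearest neighbours), recurrence and cross-recurrence matrices
    calibrated to a fixed recurrence rate, the standard recurrence
    quantification feature set, a feature-wide logistic association
    scan with false-discovery-rate control, and a gradient-boosted
    diagnostic classifier evaluated at the Youden-optimal operating
    point with stratified AUC comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    ranger,
    Rcpp,
    stats,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
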