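Package: optimbias
Title: Valence-Asymmetric Reinforcement Learning and the Development of
    Optimism Bias
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for studying optimism bias in
    effortful reward-learning tasks. Provides a drifting reward/effort task
    simulator with staircase effort calibration, a family of Rescorla-Wagner
    belief-learning models with separate learning rates for positive and
    negative prediction errors, truncated-Gaussian maximum-likelihood fitting
    with multi-start optimisation and BIC model comparison, parameter and
    model recovery diagnostics, behavioural statistics (per-subject optimism
    bias, trial-lagged belief regression with summary-statistics group
    inference, ANOVA and t-tests with effect sizes), and a three-variable
    path mediation analysis with bias-corrected accelerated (BCa) bootstrap
    confidence intervals. A synthetic-cohort generator emulates a
    three-age-group developmental study so the full pipeline runs without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
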