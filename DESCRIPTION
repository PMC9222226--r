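Package: plasmodeRF
Title: Plasmode Simulation of Variable Preselection for Probability Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for plasmode-style simulation studies that ask whether
    probability random forests benefit from variable preselection carried
    over from preceding studies that used Lasso logistic regression or
    univariate significance screening. Provides a synthetic population
    generator emulating registries of sparse binary predictors, a
    semi-synthetic outcome-reinforcement procedure, the five candidate-set
    strategies with their fallback rules, validation metrics (AUROC, Brier
    score, calibration slope, cross-entropy), and an orchestrator that runs
    the full scenario grid with reproducible per-replication seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    stats,
    utils,
    withr,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
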