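Package: stentrisk
Title: Explainable AutoML Risk Prediction for Iliac-Vein Stent Occlusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and interrogating clinical risk models of
    one-year iliac-vein stent occlusion from tabular cohort data. Implements
    a chaotic-initialisation, Levy-flight swarm optimizer (ISequoiaOA) with a
    benchmark harness; a dual-stage AutoML engine that selects a feature
    subset in a discrete space and tunes gradient-boosted-tree
    hyperparameters in a continuous space under cross-validated, SMOTE
    rebalanced fitness; a six-model comparison zoo; an evaluation layer with
    discrimination, calibration (Brier) and decision-curve net-benefit
    analysis; an interpretability layer (L1-penalised logistic path with
    lambda-1se selection, Shapley-value attribution, threshold-interaction
    summaries); and a schema-driven synthetic cohort generator emulating the
    study population so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    e1071,
    rpart,
    jsonlite,
    glmnet,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
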