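Package: metadann
Title: Meta-Prediction of miRNA Targets by Decision-Tree Routed Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Ensemble meta-prediction of miRNA:mRNA interactions from the
    numeric scores of four established target predictors (miRanda, miRDB,
    PITA, TargetScan). Scores are min-max scaled onto a common (-1,1) axis,
    records are routed by score availability into eleven predictor-specific
    modules, and each module combines a dual-threshold two-step
    significance-voting decision tree (thresholds selected from spikes of
    the information-gain curve) with a small fully connected neural network.
    Includes confusion-matrix metrics, ROC/AUC, predictor overlap and
    coverage statistics, and a seeded synthetic-data generator so every
    stage is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
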