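Package: soluq
Title: Quality-Oriented Data Selection and Consensus Modelling for
    Aqueous Solubility Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for curating multi-source aqueous solubility (LogS)
    tables and building consensus machine-learning predictors on them.
    Estimates per-source data quality as the pooled standard deviation of
    multi-lab measurements matched by InChIKey, collapses duplicates
    within a LogS tolerance, flags misprint-style outliers, and selects
    test and training data by quality rather than volume. Fits an
    ensemble of a neural network, a random forest and gradient boosted
    trees over LASSO- or correlation-selected 2D molecular descriptors,
    reporting per-compound prediction uncertainty as the spread of the
    member models. Includes chemical-space coverage diagnostics, a
    synthetic multi-source data generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    nnet,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
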