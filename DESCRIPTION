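Package: scmalig
Title: Malignant-Cell Discrimination and Scoring for Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Screens genes that separate malignant from normal single cells by
    Wilcoxon differential expression and per-gene ROC AUC, selects a sparse
    predictor set by ten-fold cross-validated L1-penalized logistic regression,
    and fits a single-cell malignant score (scMS) -- a logistic probability of
    malignancy with a Youden-optimal classification cut-point. Ships a
    seven-gene lung adenocarcinoma reference signature, cell-level quality
    control and normalization, a calibrated synthetic single-cell generator for
    validation, readers and writers for 10x-style Matrix Market and dense TSV
    matrices, broom-style tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    withr
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
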