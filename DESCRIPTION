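Package: plcpredict
Title: Predicting Drug-Phospholipid Complex Formation from Molecular
    Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A deep-learning pipeline for predicting whether an active
    pharmaceutical ingredient and a phospholipid will form a complex
    (complexation rate >= 80%) from tabular molecular descriptors.
    Implements leakage-safe min-max normalization, minority-class
    augmentation with a variational autoencoder trained by
    reparameterized gradients, principal-component dimensionality
    reduction with scree-based component selection, and a multi-layer
    one-dimensional convolutional network with a skip connection, all
    written in base matrix algebra with a hand-derived Adam optimizer.
    Classic resampling baselines (SMOTE, edited nearest neighbours and
    their composition), a confusion-matrix metric suite with
    rank-statistic ROC-AUC, permutation feature importance, and a
    seedable synthetic descriptor-table generator with a closed-form
    Bayes-accuracy oracle round out the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
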