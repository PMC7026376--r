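Package: hdbench
Title: Simulation Benchmarking of Penalized Regression in High Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A benchmarking framework for sparse linear regression with
    p >> n. Generates Gaussian covariate designs (independence,
    pairwise-block, Toeplitz-block) and semisynthetic-style covariate
    pools with signal-to-noise-calibrated responses; fits lasso, ridge,
    elastic net, SCAD, adaptive lasso and the Dantzig selector along
    regularization paths with ten-fold cross-validation; runs stability
    selection with expected-false-positive control; and scores methods
    on prediction (RMSE), variable selection (TPR/PPV) and variable
    ranking (partial AUC) over factorial scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    pracma,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    boot,
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
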