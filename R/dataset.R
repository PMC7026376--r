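#' Noise standard deviation attaining a target signal-to-noise ratio
#'
#' Solves `snr = sqrt(beta' X'X beta / (n sigma^2))` for `sigma` on the
#' realized training design, so the realized SNR identity holds exactly
#' for every generated dataset.
#'
#' @param X_train `n x p` training design matrix.
#' @param beta true coefficient vector.
#' @param snr target signal-to-noise ratio, positive.
#' @return the scalar `sigma`.
#' @export
sigma_for_snr <- function(X_train, beta, snr) {
  stopifnot(snr > 0)
  xb <- as.vector(X_train %*% beta)
  energy <- sum(xb^2)
  if (energy <= 0) stop("zero signal energy: beta' X'X beta = 0")
  sqrt(energy / (nrow(X_train) * snr^2))
}

#' Generate a complete training/test dataset for a scenario
#'
#' Draws training and test covariates from the scenario's design, builds
#' the true sparse coefficient vector, calibrates the noise standard
#' deviation to the target SNR on the realized training design, and
#' draws Gaussian responses `y = X beta + eps` for both splits with the
#' same `beta` and `sigma`. Synthetic designs use `n_test` fresh rows;
#' semisynthetic designs subsample `n` rows and `p` columns from the
#' pool, with all held-out pool rows forming the test set.
#'
#' @param config a [scenario_config()]; its `seed` makes the dataset
#'   bit-reproducible.
#' @param pool a `"covariate_pool"` (required for the semisynthetic
#'   designs; ignored otherwise).
#' @param noise_fun optional error-distribution hook: a
#'   `function(n, sigma)` returning the noise vector. Defaults to i.i.d.
#'   Gaussian `rnorm(n, 0, sigma)`.
#' @return an object of class `"hd_dataset"`: list with `X_train`,
#'   `y_train`, `X_test`, `y_test`, `beta`, `sigma`, `active_set`,
#'   `config`, and for the semisynthetic high design also `signal_blocks`.
#' @export
gen_dataset <- function(config, pool = NULL, noise_fun = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  design <- config$design
  n <- config$n; p <- config$p; s0 <- config$s0
  blocks <- NULL
  if (design %in% c("semisyn_low", "semisyn_high")) {
    if (is.null(pool) || !inherits(pool, "covariate_pool"))
      stop("semisynthetic designs require a covariate_pool")
    if (n >= pool$n_pool)
      stop("semisynthetic designs require n < n_pool")
    if (p > pool$p_pool) stop("pool has fewer than p columns")
    rows <- sample.int(pool$n_pool, n)
    cols <- sort(sample.int(pool$p_pool, p))
    X_train <- pool$X[rows, cols, drop = FALSE]
    X_test <- pool$X[-rows, cols, drop = FALSE]
    if (design == "semisyn_low") {
      active <- allocate_signals_low(p, s0)
    } else {
      alloc <- allocate_signals_high(X_train, s0, config$s0_B, config$p_B)
      active <- alloc$active
      blocks <- alloc$blocks
    }
  } else {
    gen <- switch(design,
      independence = function(m) gen_independence(m, p),
      pairwise = function(m) gen_pairwise_blocks(m, p, config$p_B,
                                                 config$rho),
      toeplitz = function(m) gen_toeplitz_blocks(m, p, config$p_B,
                                                 config$decay))
    X_train <- gen(n)
    X_test <- gen(config$n_test)
    active <- switch(design,
      independence = seq_len(s0),
      pairwise = allocate_signals_synthetic(p, config$p_B, s0,
                                            config$s0_B, "pairwise"),
      toeplitz = allocate_signals_synthetic(p, config$p_B, s0,
                                            config$s0_B, "toeplitz"))
  }
  beta <- make_coefficients(p, active, config$c_beta)
  sigma <- sigma_for_snr(X_train, beta, config$snr)
  if (is.null(noise_fun)) noise_fun <- function(m, s) rnorm(m, 0, s)
  y_train <- as.vector(X_train %*% beta) + noise_fun(nrow(X_train), sigma)
  y_test <- as.vector(X_test %*% beta) + noise_fun(nrow(X_test), sigma)
  structure(list(X_train = X_train, y_train = y_train,
                 X_test = X_test, y_test = y_test,
                 beta = beta, sigma = sigma, active_set = active,
                 signal_blocks = blocks, config = config),
            class = "hd_dataset")
}

#' @export
print.hd_dataset <- function(x, ...) {
  cat("<hd_dataset> ", scenario_id(x$config),
      ": train ", nrow(x$X_train), "x", ncol(x$X_train),
      ", test ", nrow(x$X_test), " rows, sigma = ",
      signif(x$sigma, 4), "\n", sep = "")
  invisible(x)
}

#' Export a dataset to plain CSV files
#'
#' Writes `X_train.csv`, `y_train.csv`, `X_test.csv`, `y_test.csv`,
#' `beta.csv` and `active_set.csv` (1-based indices) under `dir`, for
#' cross-language checks.
#'
#' @param dataset an `"hd_dataset"`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
export_dataset_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "hd_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(obj, name)
    write.csv(obj, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  wr(as.data.frame(dataset$X_train), "X_train")
  wr(data.frame(y = dataset$y_train), "y_train")
  wr(as.data.frame(dataset$X_test), "X_test")
  wr(data.frame(y = dataset$y_test), "y_test")
  wr(data.frame(beta = dataset$beta), "beta")
  wr(data.frame(index = dataset$active_set), "active_set")
  invisible(dir)
}
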