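#' Independence design: i.i.d. standard normal covariates
#'
#' @param n number of rows.
#' @param p number of columns.
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible.
#' @return an `n x p` numeric matrix.
#' @export
gen_independence <- function(n, p, seed = NULL) {
  stopifnot(n >= 1, p >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * p), nrow = n, ncol = p)
}

#' Pairwise-block correlation design
#'
#' Covariates are standard normal, partitioned into blocks of size `p_B`;
#' any two covariates within the same block have population correlation
#' `rho`, and covariates in different blocks are independent. The
#' construction shares a latent block factor:
#' `x = sqrt(rho) z_block + sqrt(1 - rho) e`, whose population covariance
#' is exactly block-equicorrelated.
#'
#' @param n number of rows.
#' @param p number of columns; `p_B` must divide `p`.
#' @param p_B block size.
#' @param rho within-block correlation in `[0, 1)`; `rho = 0` reduces to
#'   the independence design.
#' @param seed optional integer seed.
#' @return an `n x p` numeric matrix.
#' @export
gen_pairwise_blocks <- function(n, p, p_B, rho, seed = NULL) {
  stopifnot(n >= 1, p >= 1, p %% p_B == 0, rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  B <- p / p_B
  Z <- matrix(rnorm(n * B), nrow = n)            # one factor per block
  E <- matrix(rnorm(n * p), nrow = n)
  sqrt(rho) * Z[, rep(seq_len(B), each = p_B), drop = FALSE] +
    sqrt(1 - rho) * E
}

#' Toeplitz-block correlation design
#'
#' Covariates are standard normal in independent blocks of size `p_B`;
#' within a block, covariates at positions `j1` and `j2` have population
#' correlation `decay^|j1 - j2|` (an AR(1)-type structure, default decay
#' 0.95, so lag 7 gives `0.95^7 ~ 0.70`). Each block is drawn through the
#' Cholesky factor of the block covariance.
#'
#' @inheritParams gen_pairwise_blocks
#' @param decay base correlation in `(0, 1)`.
#' @return an `n x p` numeric matrix.
#' @export
gen_toeplitz_blocks <- function(n, p, p_B = 100, decay = 0.95, seed = NULL) {
  stopifnot(n >= 1, p >= 1, p %% p_B == 0, decay > 0, decay < 1)
  if (!is.null(seed)) set.seed(seed)
  S <- decay^abs(outer(seq_len(p_B), seq_len(p_B), "-"))
  R <- chol(S)  # failure signals an invalid decay
  B <- p / p_B
  X <- matrix(rnorm(n * p), nrow = n)
  for (b in seq_len(B)) {
    idx <- ((b - 1) * p_B + 1):(b * p_B)
    X[, idx] <- X[, idx, drop = FALSE] %*% R
  }
  X
}
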