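#' Dantzig selector at a single constraint level
#'
#' Solves `min ||b||_1 subject to ||X'(y - X b)||_inf <= lambda` as a
#' linear program in the split `b = b+ - b-` with `2p` nonnegative
#' variables and `2p` constraint rows. The constraint uses the raw
#' (unscaled) correlation `X'(y - Xb)`, so lambda lives on the
#' `||X'y||_inf` scale. Data are standardized internally by default and
#' the solution mapped back to the original scale.
#'
#' @param X design matrix.
#' @param y response vector.
#' @param lambda nonnegative constraint level.
#' @param standardize standardize columns / center y first (default
#'   TRUE); set FALSE to solve on the data as given (no intercept).
#' @return list with `beta` (length-`p` coefficient vector), `a0`
#'   (intercept, 0 when `standardize = FALSE`) and `status` (0 for
#'   success, from the LP solver).
#' @export
fit_dantzig <- function(X, y, lambda, standardize = TRUE) {
  stopifnot(lambda >= 0)
  if (standardize) {
    std <- standardize(X, y)
    Xs <- std$X; ys <- std$y
  } else {
    Xs <- X; ys <- y
  }
  p <- ncol(Xs)
  G <- crossprod(Xs)                  # p x p
  d <- as.vector(crossprod(Xs, ys))   # p
  # constraints: -lambda <= d - G(b+ - b-) <= lambda
  #   =>  [ G  -G] [b+; b-] <= lambda + d
  #       [-G   G] [b+; b-] <= lambda - d
  A <- rbind(cbind(G, -G), cbind(-G, G))
  b <- c(lambda + d, lambda - d)
  cc <- rep(1, 2 * p)
  sol <- pracma::linprog(cc, A = A, b = b, maxiter = 200 * p)
  if (is.null(sol$x) || anyNA(sol$x))
    stop("Dantzig LP solver failed (errno ", sol$errno, ")")
  bvec <- sol$x[seq_len(p)] - sol$x[p + seq_len(p)]
  bvec[abs(bvec) < 1e-10] <- 0
  if (standardize) {
    ds <- destandardize_coefs(bvec, std)
    list(beta = ds$beta, a0 = ds$a0, status = 0)
  } else {
    list(beta = bvec, a0 = 0, status = 0)
  }
}

#' Dantzig selector solution path
#'
#' Fits [fit_dantzig()] along a descending geometric grid built on the
#' `||X'y||_inf` scale (from the smallest lambda with an all-zero
#' solution down to `min_ratio` times it).
#'
#' @inheritParams fit_dantzig
#' @param lambda optional user grid.
#' @param n_lambda,min_ratio grid parameters when `lambda` is absent.
#' @return a `"path_fit"` with `family = "dantzig"`.
#' @export
fit_dantzig_path <- function(X, y, lambda = NULL, n_lambda = 20,
                             min_ratio = 0.01) {
  std <- standardize(X, y)
  if (is.null(lambda)) {
    lmax <- max(abs(crossprod(std$X, std$y)))
    lambda <- exp(seq(log(lmax), log(min_ratio * lmax),
                      length.out = n_lambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  p <- ncol(X)
  B <- matrix(0, p, length(lambda))
  for (l in seq_along(lambda)) {
    f <- fit_dantzig(std$X, std$y, lambda[l], standardize = FALSE)
    B[, l] <- f$beta
  }
  ds <- destandardize_coefs(B, std)
  new_path_fit(lambda, ds$beta, ds$a0, std, "dantzig",
               converged = rep(1L, length(lambda)))
}
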