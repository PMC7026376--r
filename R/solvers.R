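#' Standardize covariates and center the response
#'
#' Columns of `X` are centered and scaled to unit variance under the
#' `1/n` convention; `y` is centered. The returned record suffices to
#' map standardized-scale coefficients back to the original scale.
#'
#' @param X design matrix.
#' @param y response vector.
#' @return list with `X` (standardized), `y` (centered), `center`,
#'   `scale` (per column) and `y_center`.
#' @export
standardize <- function(X, y) {
  n <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(colSums(Xc^2) / n)
  if (any(scale == 0)) stop("zero-variance column in X")
  list(X = sweep(Xc, 2, scale, "/"), y = y - mean(y),
       center = center, scale = scale, y_center = mean(y))
}

destandardize_coefs <- function(b_std, record) {
  beta <- b_std / record$scale
  a0 <- record$y_center - as.vector(crossprod(record$center, beta))
  list(beta = beta, a0 = a0)
}

#' Regularization grid for a penalized path
#'
#' Geometric grid of `n_lambda` values descending from `lambda_max` to
#' `min_ratio * lambda_max`, where `lambda_max` is the smallest value at
#' which all penalized coefficients are zero:
#' `max_j |x_j' y| / (n * max(alpha, 0.001) * w_j)` on standardized data
#' (the `alpha` floor keeps ridge grids finite; per-variable penalty
#' factors `w_j` rescale the entry point, with infinite factors meaning
#' exclusion).
#'
#' @param X_std standardized design matrix.
#' @param y_c centered response.
#' @param alpha elastic-net mixing weight (1 for lasso-type penalties).
#' @param n_lambda grid length (default 100).
#' @param min_ratio ratio of smallest to largest value (default 0.01).
#' @param penalty_factor optional per-variable penalty multipliers.
#' @return a strictly decreasing numeric vector.
#' @export
lambda_grid <- function(X_std, y_c, alpha = 1, n_lambda = 100,
                        min_ratio = 0.01, penalty_factor = NULL) {
  if (n_lambda < 2) stop("n_lambda must be at least 2")
  n <- nrow(X_std)
  z <- abs(as.vector(crossprod(X_std, y_c))) / n
  if (!is.null(penalty_factor)) {
    z <- z / penalty_factor           # Inf factors drop out (z -> 0)
    z[!is.finite(penalty_factor)] <- 0
  }
  lmax <- max(z) / max(alpha, 0.001)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(min_ratio * lmax), length.out = n_lambda))
}

new_path_fit <- function(lambda, beta, a0, record, family, alpha = NA,
                         a = NA, penalty_factor = NULL, converged = NULL) {
  structure(list(lambda = lambda, beta = beta, a0 = a0,
                 center = record$center, scale = record$scale,
                 y_center = record$y_center, family = family,
                 alpha = alpha, a = a, penalty_factor = penalty_factor,
                 converged = converged),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("<path_fit> ", x$family,
      if (!is.na(x$alpha)) paste0(" (alpha = ", x$alpha, ")"),
      ": ", length(x$lambda), " lambda values, p = ", nrow(x$beta),
      "\n", sep = "")
  invisible(x)
}

ridge_path_std <- function(Xs, yc, lambda) {
  # closed form on standardized data: b = (X'X/n + lambda I)^{-1} X'y/n,
  # computed in the dual when p > n via the eigendecomposition of XX'.
  n <- nrow(Xs); p <- ncol(Xs)
  L <- length(lambda)
  B <- matrix(0, p, L)
  if (p > n) {
    K <- tcrossprod(Xs)                 # n x n
    eig <- eigen(K, symmetric = TRUE)
    Uty <- crossprod(eig$vectors, yc)
    for (l in seq_len(L)) {
      alpha_dual <- eig$vectors %*% (Uty / (eig$values + n * lambda[l]))
      B[, l] <- crossprod(Xs, alpha_dual)
    }
  } else {
    G <- crossprod(Xs)                  # p x p
    eig <- eigen(G, symmetric = TRUE)
    Vty <- crossprod(eig$vectors, crossprod(Xs, yc))
    for (l in seq_len(L))
      B[, l] <- eig$vectors %*% (Vty / (eig$values + n * lambda[l]))
  }
  B
}

#' Elastic-net solution path by coordinate descent
#'
#' Minimizes `(1/2n) ||y - X b||^2 + lambda * sum_j w_j (alpha |b_j| +
#' (1 - alpha) b_j^2 / 2)` along a descending lambda grid with warm
#' starts (the standard elastic-net parameterization, so the mixing
#' weights 0.3/0.6 carry their conventional meaning). `alpha = 0` is
#' solved exactly by the ridge closed form; `alpha > 0` by cyclic
#' coordinate descent with soft thresholding, strong-rule screening and
#' full KKT verification. Covariates *and response* are standardized
#' internally (the convention of standard elastic-net software, making
#' the fit equivariant to rescaling of `y`); coefficients are returned
#' on the original scale and `lambda` is reported in original-response
#' units.
#'
#' @param X design matrix.
#' @param y response vector.
#' @param alpha mixing weight in `[0, 1]`: 1 lasso, 0 ridge, 0.3 heavy
#'   elastic net, 0.6 light elastic net.
#' @param lambda optional user grid (descending); computed by
#'   [lambda_grid()] when absent.
#' @param n_lambda,min_ratio grid parameters when `lambda` is absent.
#' @param penalty_factor optional positive per-variable penalty
#'   multipliers; `Inf` excludes a variable.
#' @param tol convergence tolerance on the max absolute standardized
#'   coefficient change (default 1e-7).
#' @param max_sweeps per-lambda sweep budget; non-convergence is
#'   recorded per lambda, not fatal.
#' @return a `"path_fit"`: descending `lambda`, `p x L` coefficient
#'   matrix `beta` on the original scale, per-lambda intercepts `a0`,
#'   standardization record and convergence flags.
#' @export
fit_enet_path <- function(X, y, alpha = 1, lambda = NULL, n_lambda = 100,
                          min_ratio = 0.01, penalty_factor = NULL,
                          tol = 1e-7, max_sweeps = 5000) {
  stopifnot(alpha >= 0, alpha <= 1)
  std <- standardize(X, y)
  if (is.null(lambda))
    lambda <- lambda_grid(std$X, std$y, alpha, n_lambda, min_ratio,
                          penalty_factor)
  lambda <- sort(lambda, decreasing = TRUE)
  if (is.null(penalty_factor)) penalty_factor <- rep(1, ncol(X))
  # the response is standardized too (unit 1/n-variance), making the fit
  # scale-equivariant; lambda is kept in original-response units
  sdy <- sqrt(mean(std$y^2))
  if (sdy == 0) sdy <- 1                # y identically centered: beta = 0
  if (alpha == 0 && all(penalty_factor == 1)) {
    B <- ridge_path_std(std$X, std$y / sdy, lambda / sdy) * sdy
    conv <- rep(1L, length(lambda))
  } else {
    fit <- .cd_path(std$X, std$y / sdy, lambda / sdy, alpha, 3.7, FALSE,
                    penalty_factor, tol, as.integer(max_sweeps))
    B <- fit$beta * sdy
    conv <- as.integer(fit$converged)
    if (any(conv == 0))
      warning("coordinate descent did not converge at ",
              sum(conv == 0), " lambda value(s)")
  }
  ds <- destandardize_coefs(B, std)
  new_path_fit(lambda, ds$beta, ds$a0, std, "enet", alpha = alpha,
               penalty_factor = penalty_factor, converged = conv)
}

#' SCAD solution path by coordinate descent
#'
#' Minimizes the penalized least-squares objective with the smoothly
#' clipped absolute deviation penalty (shape `a > 2`, default 3.7):
#' small coefficients are soft-thresholded like the lasso and large ones
#' left unpenalized. The penalty is non-convex; the fitted path is the
#' local solution reached by warm-started coordinate descent from the
#' largest lambda, using the exact univariate SCAD thresholding update,
#' and is deterministic given the data and grid.
#'
#' @inheritParams fit_enet_path
#' @param a SCAD shape parameter, `> 2`.
#' @return a `"path_fit"` with `family = "scad"`.
#' @export
fit_scad_path <- function(X, y, a = 3.7, lambda = NULL, n_lambda = 100,
                          min_ratio = 0.01, tol = 1e-7,
                          max_sweeps = 5000) {
  stopifnot(a > 2)
  std <- standardize(X, y)
  if (is.null(lambda)) lambda <- lambda_grid(std$X, std$y, 1, n_lambda,
                                             min_ratio)
  lambda <- sort(lambda, decreasing = TRUE)
  fit <- .cd_path(std$X, std$y, lambda, 1, a, TRUE, rep(1, ncol(X)),
                  tol, as.integer(max_sweeps))
  conv <- as.integer(fit$converged)
  if (any(conv == 0))
    warning("SCAD coordinate descent did not converge at ",
            sum(conv == 0), " lambda value(s)")
  ds <- destandardize_coefs(fit$beta, std)
  new_path_fit(lambda, ds$beta, ds$a0, std, "scad", a = a,
               converged = conv)
}

#' Adaptive lasso path (ridge-weighted two-stage fit)
#'
#' Stage 1 fits a cross-validated ridge regression to obtain initial
#' estimates `beta~`; stage 2 solves the weighted lasso with penalty
#' weights `w_j = 1 / |beta~_j|^gamma_w`, so variables with larger
#' initial estimates are shrunk less. Variables whose initial estimate
#' is exactly zero receive infinite weight and are excluded at every
#' lambda (set `zero_eps > 0` to instead floor `|beta~|` at `zero_eps`).
#'
#' @inheritParams fit_enet_path
#' @param gamma_w weight exponent (default 1).
#' @param cv_seed seed for the stage-1 ridge cross-validation folds.
#' @param K folds for the stage-1 ridge CV.
#' @param zero_eps optional floor for `|beta~|`; 0 means exclusion.
#' @return a `"path_fit"` with `family = "adalasso"`, carrying the
#'   weights in `penalty_factor`.
#' @export
fit_adaptive_lasso <- function(X, y, gamma_w = 1, cv_seed = 1L, K = 10,
                               lambda = NULL, n_lambda = 100,
                               min_ratio = 0.01, zero_eps = 0,
                               tol = 1e-7, max_sweeps = 5000) {
  ridge_cv <- cv_select(X, y, family = "enet", alpha = 0, K = K,
                        seed = cv_seed)
  bt <- abs(ridge_cv$beta)
  if (zero_eps > 0) bt <- pmax(bt, zero_eps)
  if (all(bt == 0)) stop("all initial estimates are zero; cannot weight")
  w <- 1 / bt^gamma_w                   # bt = 0 -> Inf -> excluded
  fit <- fit_enet_path(X, y, alpha = 1, lambda = lambda,
                       n_lambda = n_lambda, min_ratio = min_ratio,
                       penalty_factor = w, tol = tol,
                       max_sweeps = max_sweeps)
  fit$family <- "adalasso"
  fit$gamma_w <- gamma_w
  fit
}

#' Predict from a solution path
#'
#' @param object a `"path_fit"`.
#' @param newx matrix of new observations (original covariate scale).
#' @param s optional lambda index (or vector of indices) selecting path
#'   columns; all columns when absent.
#' @param ... unused.
#' @return an `nrow(newx) x length(s)` matrix of predictions (dropped to
#'   a vector for a single `s`).
#' @export
predict.path_fit <- function(object, newx, s = NULL, ...) {
  if (ncol(newx) != nrow(object$beta))
    stop("newx has ", ncol(newx), " columns; fit expects ",
         nrow(object$beta))
  B <- object$beta
  a0 <- object$a0
  if (!is.null(s)) { B <- B[, s, drop = FALSE]; a0 <- a0[s] }
  out <- sweep(newx %*% B, 2, a0, "+")
  if (ncol(out) == 1) as.vector(out) else out
}

#' Extract path coefficients
#'
#' @param object a `"path_fit"`.
#' @param s optional lambda index.
#' @param ... unused.
#' @return coefficient matrix (or vector for a single `s`), original scale.
#' @export
coef.path_fit <- function(object, s = NULL, ...) {
  if (is.null(s)) object$beta else object$beta[, s]
}

#' Serialize a solution path to CSV
#'
#' Writes one row per lambda: the lambda value, then the coefficients
#' of every variable on the original scale (columns `x1..xp`).
#'
#' @param fit a `"path_fit"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_path_csv <- function(fit, path) {
  stopifnot(inherits(fit, "path_fit"))
  df <- data.frame(lambda = fit$lambda, t(fit$beta))
  names(df) <- c("lambda", paste0("x", seq_len(nrow(fit$beta))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
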