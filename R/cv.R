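#' K-fold cross-validated fit
#'
#' Assigns folds by a seeded random permutation into near-equal sizes,
#' computes a common lambda grid on the full data, accumulates held-out
#' squared error per lambda, selects the lambda minimizing the mean CV
#' error (or the 1-SE rule), and refits on all data at the common grid.
#'
#' @param X design matrix.
#' @param y response vector.
#' @param family `"enet"` (any `alpha`, including ridge at 0),
#'   `"scad"`, `"adalasso"` or `"dantzig"`.
#' @param alpha elastic-net mixing weight (family `"enet"`).
#' @param a SCAD shape parameter.
#' @param gamma_w adaptive-lasso weight exponent; the ridge-based
#'   weights are computed once on the full training data and held fixed
#'   across folds.
#' @param K number of folds (default 10); requires `n >= K`.
#' @param seed fold-assignment seed.
#' @param rule `"min"` (lambda minimizing mean CV error, default) or
#'   `"1se"` (largest lambda within one standard error of the minimum).
#' @param n_lambda,min_ratio grid parameters; ridge (`alpha = 0`)
#'   defaults to a deeper grid (`min_ratio = 1e-5`) since its penalty
#'   scale enters through the 0.001 alpha floor.
#' @param ... further arguments passed to the underlying path fitter.
#' @return an object of class `"cv_fit"`: `lambda` (grid), `cvm`,
#'   `cvse` (mean CV error and its standard error per lambda),
#'   `lambda_index`, `lambda_min` (selected value), `beta`, `a0`
#'   (coefficients at the selected lambda, original scale), and `path`
#'   (the full-data `"path_fit"`).
#' @export
cv_select <- function(X, y, family = c("enet", "scad", "adalasso",
                                       "dantzig"),
                      alpha = 1, a = 3.7, gamma_w = 1, K = 10,
                      seed = 1L, rule = c("min", "1se"),
                      n_lambda = 100, min_ratio = NULL, ...) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  n <- nrow(X)
  if (n < K) stop("need at least K observations for K-fold CV")
  if (is.null(min_ratio))
    min_ratio <- if (family == "enet" && alpha == 0) 1e-5 else 0.01
  pf <- NULL
  if (family == "adalasso") {
    ridge_cv <- cv_select(X, y, family = "enet", alpha = 0, K = K,
                          seed = seed)
    bt <- abs(ridge_cv$beta)
    if (all(bt == 0)) stop("all initial estimates are zero; cannot weight")
    pf <- 1 / bt^gamma_w
  }
  fit_fun <- function(X., y., lam) {
    switch(family,
      enet = fit_enet_path(X., y., alpha = alpha, lambda = lam,
                           n_lambda = n_lambda, min_ratio = min_ratio,
                           ...),
      adalasso = fit_enet_path(X., y., alpha = 1, lambda = lam,
                               n_lambda = n_lambda,
                               min_ratio = min_ratio,
                               penalty_factor = pf, ...),
      scad = fit_scad_path(X., y., a = a, lambda = lam,
                           n_lambda = n_lambda, min_ratio = min_ratio,
                           ...),
      dantzig = fit_dantzig_path(X., y., lambda = lam,
                                 n_lambda = n_lambda,
                                 min_ratio = min_ratio))
  }
  full <- fit_fun(X, y, NULL)
  lambda <- full$lambda
  set.seed(seed)
  folds <- sample(rep_len(seq_len(K), n))
  errs <- matrix(NA_real_, K, length(lambda))
  for (k in seq_len(K)) {
    te <- folds == k
    fit_k <- fit_fun(X[!te, , drop = FALSE], y[!te], lambda)
    pred <- predict(fit_k, X[te, , drop = FALSE])
    errs[k, ] <- colMeans((y[te] - pred)^2)
  }
  cvm <- colMeans(errs)
  cvse <- apply(errs, 2, sd) / sqrt(K)
  idx <- which.min(cvm)
  if (rule == "1se") {
    ok <- which(cvm <= cvm[idx] + cvse[idx])
    idx <- min(ok)   # largest lambda within one SE (grid is descending)
  }
  structure(list(lambda = lambda, cvm = cvm, cvse = cvse,
                 lambda_index = idx, lambda_min = lambda[idx],
                 beta = full$beta[, idx], a0 = full$a0[idx],
                 family = family, alpha = alpha, rule = rule,
                 path = full),
            class = "cv_fit")
}

#' @export
print.cv_fit <- function(x, ...) {
  cat("<cv_fit> ", x$family,
      if (x$family == "enet") paste0(" (alpha = ", x$alpha, ")"),
      ": selected lambda = ", signif(x$lambda_min, 4),
      " (index ", x$lambda_index, "/", length(x$lambda), "), ",
      sum(x$beta != 0), " nonzero coefficients\n", sep = "")
  invisible(x)
}

#' Predict from a cross-validated fit
#'
#' @param object a `"cv_fit"`.
#' @param newx matrix of new observations.
#' @param ... unused.
#' @return a numeric vector of predictions at the selected lambda.
#' @export
predict.cv_fit <- function(object, newx, ...) {
  if (ncol(newx) != length(object$beta))
    stop("newx has ", ncol(newx), " columns; fit expects ",
         length(object$beta))
  as.vector(newx %*% object$beta) + object$a0
}

#' Selected variables of a cross-validated fit
#'
#' @param fit a `"cv_fit"`.
#' @return integer indices of nonzero coefficients at the selected
#'   lambda (exact zeros define exclusion).
#' @export
selected_set <- function(fit) {
  stopifnot(inherits(fit, "cv_fit"))
  which(fit$beta != 0)
}
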