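#' Stability selection path with the lasso base learner
#'
#' Draws `M` random subsamples of size `n_sub` without replacement,
#' fits the lasso path on each over a common lambda grid (computed on
#' the full data), and records the selection frequency
#' `Pi[lambda, j]` = fraction of subsamples in which variable `j` has a
#' nonzero coefficient at that lambda. Frequencies are exact multiples
#' of `1/M` and the whole procedure is deterministic given the seed.
#'
#' @param X design matrix.
#' @param y response vector.
#' @param M number of subsamples (default 100).
#' @param n_sub subsample size; default `floor(0.632 * n)`. Must be
#'   smaller than `n`.
#' @param lambda optional common grid; computed on the full data when
#'   absent.
#' @param n_lambda,min_ratio grid parameters when `lambda` is absent.
#' @param seed integer seed for the subsample draws.
#' @return an object of class `"stability_result"`: `lambda`, `freq`
#'   (`L x p` selection-frequency matrix), `scores` (per-variable
#'   `max_lambda` frequency), `q_avg` (average selected-set size per
#'   lambda across subsamples, the q-diagnostic used by the error
#'   bound), `M`, `n_sub`.
#' @export
stability_path <- function(X, y, M = 100, n_sub = floor(0.632 * nrow(X)),
                           lambda = NULL, n_lambda = 100,
                           min_ratio = 0.01, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  if (n_sub >= n) stop("n_sub must be smaller than n")
  stopifnot(M >= 1)
  std <- standardize(X, y)
  if (is.null(lambda))
    lambda <- lambda_grid(std$X, std$y, 1, n_lambda, min_ratio)
  lambda <- sort(lambda, decreasing = TRUE)
  L <- length(lambda)
  count <- matrix(0L, L, p)
  qsum <- numeric(L)
  set.seed(seed)
  for (m in seq_len(M)) {
    rows <- sample.int(n, n_sub)
    fit <- fit_enet_path(X[rows, , drop = FALSE], y[rows], alpha = 1,
                         lambda = lambda)
    nz <- t(fit$beta != 0)             # L x p
    count <- count + nz
    qsum <- qsum + rowSums(nz)
  }
  freq <- count / M
  structure(list(lambda = lambda, freq = freq,
                 scores = apply(freq, 2, max),
                 q_avg = qsum / M, M = M, n_sub = n_sub),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result> M = ", x$M, ", n_sub = ", x$n_sub, ", ",
      length(x$lambda), " lambda values, ", ncol(x$freq),
      " variables (max score ", max(x$scores), ")\n", sep = "")
  invisible(x)
}

#' Restrict the lambda grid for expected-false-positive control
#'
#' Under the stability-selection error bound
#' `E[V] <= q^2 / ((2 pi_thr - 1) p)`, a bound `V_bound` on the expected
#' number of falsely selected variables is attained by keeping only the
#' lambda sub-grid (largest lambda downward) whose running average
#' selected-set size satisfies `q <= sqrt(V_bound (2 pi_thr - 1) p)`.
#' The running `q` is the cumulative maximum of the per-lambda average
#' selected-set size across subsamples.
#'
#' @param result a `"stability_result"`.
#' @param V_bound positive bound on `E[V]`.
#' @param pi_thr selection-frequency threshold in `(0.5, 1)`.
#' @param p number of variables (defaults to the result's).
#' @return integer indices into `result$lambda` forming the retained
#'   sub-grid (possibly empty, with a warning).
#' @export
restrict_lambda <- function(result, V_bound, pi_thr = 0.6,
                            p = ncol(result$freq)) {
  stopifnot(V_bound > 0, pi_thr > 0.5, pi_thr < 1)
  cap <- sqrt(V_bound * (2 * pi_thr - 1) * p)
  qrun <- cummax(result$q_avg)
  keep <- which(qrun <= cap)
  if (length(keep) == 0)
    warning("no lambda value satisfies the q cap ", signif(cap, 4))
  keep
}

#' Stable set of selected variables
#'
#' Thresholds the per-variable maximum selection frequency at `pi_thr`.
#' Without `V_bound` the maximum is taken over the full lambda grid (no
#' explicit false-positive control); with `V_bound` the grid is first
#' restricted by [restrict_lambda()] so that `E[V] <= V_bound`.
#'
#' @param result a `"stability_result"`.
#' @param pi_thr selection-frequency cutoff in `(0.5, 1)`, default 0.6.
#' @param V_bound optional bound on the expected number of false
#'   positives.
#' @return integer indices of the stable variables (empty when nothing
#'   passes the cutoff or no lambda survives the restriction).
#' @export
stable_set <- function(result, pi_thr = 0.6, V_bound = NULL) {
  stopifnot(pi_thr > 0.5, pi_thr < 1)
  if (is.null(V_bound)) {
    scores <- result$scores
  } else {
    keep <- restrict_lambda(result, V_bound, pi_thr)
    if (length(keep) == 0) return(integer(0))
    scores <- apply(result$freq[keep, , drop = FALSE], 2, max)
  }
  which(scores >= pi_thr)
}

#' Serialize a stability result to CSV
#'
#' Writes the lambda-by-variable selection-frequency table with a
#' `lambda` column header.
#'
#' @param result a `"stability_result"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stability_csv <- function(result, path) {
  df <- data.frame(lambda = result$lambda, result$freq)
  names(df) <- c("lambda", paste0("x", seq_len(ncol(result$freq))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
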