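#' Root-mean-squared prediction error
#'
#' `||y - yhat||_2 / sqrt(n_test)`.
#'
#' @param y_test observed test responses.
#' @param y_pred predictions.
#' @return nonnegative scalar.
#' @export
rmse <- function(y_test, y_pred) {
  if (length(y_test) != length(y_pred)) stop("length mismatch")
  sqrt(mean((y_test - y_pred)^2))
}

#' Confusion counts of a selected variable set
#'
#' @param selected integer indices of selected variables.
#' @param active_set integer indices of truly active variables.
#' @param p total number of variables.
#' @return named vector `c(tp, fp, fn, tn)`.
#' @export
confusion <- function(selected, active_set, p) {
  if (length(selected) && (min(selected) < 1 || max(selected) > p))
    stop("selected indices out of range")
  if (length(active_set) && (min(active_set) < 1 || max(active_set) > p))
    stop("active indices out of range")
  tp <- length(intersect(selected, active_set))
  fp <- length(setdiff(selected, active_set))
  fn <- length(setdiff(active_set, selected))
  c(tp = tp, fp = fp, fn = fn, tn = p - tp - fp - fn)
}

#' True positive rate and positive predictive value
#'
#' `TPR = TP / (TP + FN)`, `PPV = TP / (TP + FP)`. The PPV of an empty
#' selection (TP + FP = 0) is undefined and returned as `NA`; scenario
#' aggregation excludes these and reports their count.
#'
#' @param tp,fp,fn nonnegative counts.
#' @return named vector `c(tpr, ppv)` (ppv possibly `NA`).
#' @export
tpr_ppv <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  tpr <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  c(tpr = tpr, ppv = ppv)
}

#' Path-persistence ranking scores
#'
#' A variable is scored by how long it remains continuously in the
#' estimated active set as the penalty grows: `s_j` is the largest grid
#' lambda such that `j` has a nonzero coefficient at every grid lambda
#' below it, and 0 if `j` is not active at the smallest lambda. Active
#' membership uses exact zeros (coordinate descent produces exact zeros
#' for L1-type penalties).
#'
#' @param path a `"path_fit"` (descending lambda grid).
#' @return a nonnegative numeric vector of length `p`.
#' @export
path_ranking_scores <- function(path) {
  stopifnot(inherits(path, "path_fit"), length(path$lambda) >= 1)
  nz <- path$beta != 0                 # p x L, columns descending lambda
  L <- ncol(nz)
  # length of the run of consecutive TRUEs ending at the smallest lambda
  run <- integer(nrow(nz))
  alive <- nz[, L]
  run[alive] <- 1L
  k <- L - 1L
  while (k >= 1L && any(alive)) {
    alive <- alive & nz[, k]
    run[alive] <- run[alive] + 1L
    k <- k - 1L
  }
  ifelse(run == 0L, 0, path$lambda[L - run + 1L])
}

#' Ranking scores for any fitted method
#'
#' Dispatches on the method: ridge ranks by the absolute
#' cross-validated coefficients, stability selection by the
#' maximum selection frequency over the grid, and sparse path methods
#' (lasso, elastic net, SCAD, adaptive lasso, Dantzig) by
#' [path_ranking_scores()].
#'
#' @param fit a `"cv_fit"` (ridge), `"stability_result"`, or
#'   `"path_fit"`.
#' @param method method tag, used to disambiguate `"cv_fit"` objects:
#'   `"ridge"` means rank by `|beta_cv|`.
#' @return a nonnegative numeric score vector of length `p`.
#' @export
method_scores <- function(fit, method = NULL) {
  if (inherits(fit, "stability_result")) return(fit$scores)
  if (inherits(fit, "cv_fit")) {
    is_ridge <- identical(method, "ridge") ||
      (is.null(method) && fit$family == "enet" && fit$alpha == 0)
    if (is_ridge) return(abs(fit$beta))
    return(path_ranking_scores(fit$path))
  }
  if (inherits(fit, "path_fit")) return(path_ranking_scores(fit))
  stop("unsupported fit object of class ", paste(class(fit),
                                                 collapse = "/"))
}

#' Partial area under the ROC curve for variable ranking
#'
#' Builds the ROC curve of the scores against the true active set by
#' descending score threshold, traversing tie blocks as single diagonal
#' segments (threshold averaging), and integrates the curve over the
#' false-positive-rate window `[0, max_fp / (p - s0)]` with linear
#' interpolation at the right boundary. The area is normalized by the
#' window width so the result lies in `[0, 1]` (1 when every signal
#' outranks every non-signal; ~window/2 behavior maps to 0.5 under
#' random scores).
#'
#' @param scores numeric score vector of length `p` (higher = more
#'   important).
#' @param active_set indices of the truly active variables.
#' @param p number of variables.
#' @param max_fp maximum number of false positives defining the window
#'   (default 50); requires `p - s0 >= max_fp`.
#' @return the normalized partial AUC in `[0, 1]`.
#' @export
pauc <- function(scores, active_set, p, max_fp = 50) {
  stopifnot(length(scores) == p, max_fp >= 1)
  s0 <- length(active_set)
  n_neg <- p - s0
  if (n_neg < max_fp) stop("max_fp exceeds the number of non-signals")
  lab <- logical(p); lab[active_set] <- TRUE
  o <- order(scores, decreasing = TRUE)
  sc <- scores[o]; lb <- lab[o]
  grp <- cumsum(!duplicated(sc))       # tie blocks of equal score
  tp <- cumsum(lb); fp <- cumsum(!lb)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / s0)
  fpr <- c(0, fp[last] / n_neg)
  fmax <- max_fp / n_neg
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]
    y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x0 >= fmax) break
    if (x1 > fmax) {                   # clip the segment at the boundary
      y1 <- y0 + (y1 - y0) * (fmax - x0) / (x1 - x0)
      x1 <- fmax
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area / fmax
}
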