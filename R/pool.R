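#' Synthetic covariate pool emulating a gene-expression matrix
#'
#' Builds a latent-factor Gaussian pool to stand in for a real
#' high-dimensional expression matrix: a minority of columns load on
#' shared cluster factors (creating pockets of strongly correlated
#' columns for the greedy high-correlation signal allocation), while all
#' columns load weakly on a global factor so that the mean absolute
#' pairwise column correlation matches a target (default 0.08). The pool
#' is synthetic; it reproduces the correlation summary of real
#' expression data, not expression-specific marginal distributions.
#'
#' @param n_pool number of rows (samples), default 594.
#' @param p_pool number of columns (features).
#' @param target_mean_abs_corr target mean absolute pairwise column
#'   correlation, reported within about 0.02.
#' @param n_clusters number of planted 10-column clusters.
#' @param cluster_size columns per cluster.
#' @param within_cluster_corr approximate population correlation inside
#'   a cluster (must exceed the global level).
#' @param seed optional integer seed.
#' @param report_columns number of randomly chosen columns over which the
#'   mean absolute correlation report is computed (exhaustive for small
#'   pools); keeps the summary cheap for wide pools.
#' @return an object of class `"covariate_pool"`: list with `X`
#'   (`n_pool x p_pool` matrix), `clusters` (list of planted column
#'   index sets, for testing), and `mean_abs_corr` (reported summary).
#' @export
build_pool <- function(n_pool = 594, p_pool = 2000,
                       target_mean_abs_corr = 0.08,
                       n_clusters = 40, cluster_size = 10,
                       within_cluster_corr = 0.6, seed = NULL,
                       report_columns = 300) {
  stopifnot(n_pool >= 2, p_pool >= 2,
            n_clusters * cluster_size <= p_pool,
            within_cluster_corr > target_mean_abs_corr,
            within_cluster_corr < 1)
  if (!is.null(seed)) set.seed(seed)
  # Global factor loading g: between-column population correlation ~ g^2.
  # The sampling noise floor of |r| at n_pool rows is ~sqrt(2/(pi n));
  # aiming the population level slightly under the target compensates.
  g2 <- max(target_mean_abs_corr - 0.5 * sqrt(2 / (pi * n_pool)), 0)
  g <- sqrt(g2)
  # Cluster loading c: within-cluster correlation ~ (c^2 + g^2).
  cl <- sqrt(max(within_cluster_corr - g2, 0))
  noise_sd <- sqrt(1 - g2 - cl^2)
  global <- rnorm(n_pool)
  X <- g * matrix(global, n_pool, p_pool) +
    matrix(rnorm(n_pool * p_pool), n_pool) *
      sqrt(1 - g2)  # provisional: cluster columns rescaled below
  clusters <- vector("list", n_clusters)
  if (n_clusters > 0) {
    cols <- seq_len(n_clusters * cluster_size)
    for (k in seq_len(n_clusters)) {
      idx <- cols[((k - 1) * cluster_size + 1):(k * cluster_size)]
      f <- rnorm(n_pool)
      X[, idx] <- g * global + cl * f +
        noise_sd * matrix(rnorm(n_pool * cluster_size), n_pool)
      clusters[[k]] <- idx
    }
  }
  rep_idx <- if (p_pool <= report_columns) seq_len(p_pool) else
    sort(sample.int(p_pool, report_columns))
  Cr <- abs(cor(X[, rep_idx, drop = FALSE]))
  mac <- mean(Cr[upper.tri(Cr)])
  structure(list(X = X, n_pool = n_pool, p_pool = p_pool,
                 clusters = clusters, mean_abs_corr = mac),
            class = "covariate_pool")
}

#' Read a real covariate pool from CSV/TSV
#'
#' Accepts a numeric matrix with samples as rows and features as
#' columns, with a header row of feature names; use this to substitute a
#' real expression matrix for the synthetic pool in the semisynthetic
#' designs.
#'
#' @param path file path; tab- or comma-separated inferred from the
#'   extension (`.tsv`/`.txt` vs `.csv`).
#' @return a `"covariate_pool"` object (no planted clusters).
#' @export
read_pool <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  X <- as.matrix(read.csv(path, sep = sep, check.names = FALSE))
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("pool matrix contains non-finite values")
  rep_idx <- if (ncol(X) <= 300) seq_len(ncol(X)) else
    sort(sample.int(ncol(X), 300))
  Cr <- abs(cor(X[, rep_idx, drop = FALSE]))
  structure(list(X = X, n_pool = nrow(X), p_pool = ncol(X),
                 clusters = list(),
                 mean_abs_corr = mean(Cr[upper.tri(Cr)])),
            class = "covariate_pool")
}

#' @export
print.covariate_pool <- function(x, ...) {
  cat("<covariate_pool> ", x$n_pool, " x ", x$p_pool,
      " (mean |corr| = ", round(x$mean_abs_corr, 3), ")\n", sep = "")
  invisible(x)
}
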