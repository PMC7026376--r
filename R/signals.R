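#' Deterministic signal positions for synthetic block designs
#'
#' For the pairwise design the first `s0 / s0_B` blocks each contribute
#' their first `s0_B` positions (positions within an equicorrelated block
#' are exchangeable, so the choice is statistically irrelevant; a fixed
#' rule keeps datasets reproducible). For the Toeplitz design each signal
#' block contributes a pair of positions spaced exactly 7 apart
#' (positions 1 and 8 of the block), giving the two signals within a
#' block a correlation of `decay^7`.
#'
#' @param p number of covariates.
#' @param p_B block size (`p_B` divides `p`).
#' @param s0 total number of signals.
#' @param s0_B signals per block (`s0_B` divides `s0`; 2 for toeplitz).
#' @param design `"pairwise"` or `"toeplitz"`.
#' @param spacing within-block distance of the toeplitz signal pair.
#' @return an integer vector of 1-based active indices, ordered.
#' @export
allocate_signals_synthetic <- function(p, p_B, s0, s0_B,
                                       design = c("pairwise", "toeplitz"),
                                       spacing = 7) {
  design <- match.arg(design)
  stopifnot(p %% p_B == 0, s0 %% s0_B == 0, s0 / s0_B <= p / p_B)
  n_blocks <- s0 / s0_B
  starts <- (seq_len(n_blocks) - 1) * p_B
  if (design == "toeplitz") {
    if (s0_B != 2) stop("toeplitz signal allocation requires s0_B = 2")
    if (spacing + 1 > p_B) stop("spacing exceeds block size")
    sort(c(starts + 1, starts + 1 + spacing))
  } else {
    sort(as.vector(outer(seq_len(s0_B), starts, "+")))
  }
}

#' Random signal allocation (low-correlation design)
#'
#' Signals are a uniform random subset of the `p` covariates, drawn
#' without replacement.
#'
#' @param p number of covariates.
#' @param s0 number of signals, `s0 <= p`.
#' @param seed optional integer seed.
#' @return an integer vector of `s0` ordered 1-based indices.
#' @export
allocate_signals_low <- function(p, s0, seed = NULL) {
  stopifnot(s0 <= p)
  if (!is.null(seed)) set.seed(seed)
  sort(sample.int(p, s0))
}

#' Greedy correlated-block signal allocation (high-correlation design)
#'
#' Builds signal blocks of 10 covariates from the empirical column
#' correlations: (i) find the most correlated pair of unallocated
#' columns, anchor the block at the first of the pair, and complete the
#' block with the 8 further columns most correlated with the anchor;
#' (ii) designate the anchor and the `s0_B - 1` columns most correlated
#' with it as signals; (iii) remove the block's columns from candidacy
#' and repeat until `s0` signals are placed. "Most correlated" uses
#' absolute Pearson correlation (sign-agnostic), with ties broken by the
#' lowest column index.
#'
#' @param X numeric matrix whose columns are the candidate covariates.
#' @param s0 total number of signals.
#' @param s0_B signals per block, in `{1, 2, 5}`; divides `s0`.
#' @param p_B block size (default 10).
#' @return a list with `active` (ordered 1-based signal indices) and
#'   `blocks` (a list of the 10-member index sets, one per signal block).
#' @export
allocate_signals_high <- function(X, s0, s0_B, p_B = 10) {
  stopifnot(s0_B %in% c(1, 2, 5), s0 %% s0_B == 0)
  p <- ncol(X)
  n_blocks <- s0 / s0_B
  if (n_blocks * p_B > p)
    stop("not enough columns to form ", n_blocks, " blocks of ", p_B)
  C <- abs(cor(X))
  diag(C) <- 0
  avail <- rep(TRUE, p)
  active <- integer(0)
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    if (sum(avail) < p_B) stop("fewer than ", p_B, " unallocated columns left")
    idx <- which(avail)
    Csub <- C[idx, idx, drop = FALSE]
    # most correlated pair; ties -> lowest (row, col) indices
    m <- which(Csub == max(Csub), arr.ind = TRUE)
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    anchor <- idx[min(m[1, ])]
    partner <- idx[max(m[1, ])]
    others <- setdiff(idx, c(anchor, partner))
    fill <- others[order(-C[anchor, others], others)][seq_len(p_B - 2)]
    block <- c(anchor, partner, fill)
    members <- setdiff(block, anchor)
    sig <- anchor
    if (s0_B > 1)
      sig <- c(sig, members[order(-C[anchor, members], members)][seq_len(s0_B - 1)])
    blocks[[b]] <- sort(block)
    active <- c(active, sig)
    avail[block] <- FALSE
  }
  list(active = sort(active), blocks = blocks)
}

#' True coefficient vector
#'
#' With `c_beta = 1` every active coefficient equals 3. With
#' `c_beta < 1` the first half of the active set gets
#' `beta' = sqrt(18 / (1 + c_beta^2))` and the second half `c_beta *
#' beta'`, which keeps the total signal energy `sum(beta^2) = 9 * s0`
#' constant across `c_beta` (so the calibrated noise level is unchanged
#' in expectation).
#'
#' @param p number of covariates.
#' @param active_set ordered active indices.
#' @param c_beta heterogeneity factor in `[0, 1]`; values below 1
#'   require an even number of signals.
#' @return a length-`p` numeric vector, nonzero exactly on `active_set`.
#' @export
make_coefficients <- function(p, active_set, c_beta = 1) {
  stopifnot(c_beta >= 0, c_beta <= 1, all(active_set >= 1), all(active_set <= p))
  s0 <- length(active_set)
  beta <- numeric(p)
  if (c_beta == 1) {
    beta[active_set] <- 3
  } else {
    if (s0 %% 2 != 0) stop("c_beta < 1 requires an even number of signals")
    bp <- sqrt(18 / (1 + c_beta^2))
    half <- s0 / 2
    beta[active_set[seq_len(half)]] <- bp
    beta[active_set[(half + 1):s0]] <- c_beta * bp
  }
  beta
}
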