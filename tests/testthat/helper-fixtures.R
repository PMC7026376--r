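# Small fixtures shared across test files; everything is generated in
# code under fixed seeds.

# a well-conditioned low-dimensional regression instance
small_instance <- function(n = 60, p = 8, s0 = 3, sigma = 0.5,
                           seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p)
  beta[seq_len(s0)] <- c(3, -2, 1.5)[seq_len(s0)]
  y <- as.vector(X %*% beta) + rnorm(n, 0, sigma)
  list(X = X, y = y, beta = beta, active = which(beta != 0))
}

# an exactly orthonormal design with prescribed correlations X'y
orthonormal_instance <- function(xty, n = NULL) {
  p <- length(xty)
  if (is.null(n)) n <- p
  stopifnot(n >= p)
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))   # Q'Q = I
  y <- as.vector(Q %*% xty)                   # then Q'y = xty exactly
  list(X = Q, y = y)
}

# brute-force 1-D SCAD minimizer on a fine grid
scad_brute <- function(z, lam, a, grid_n = 1e4, span = NULL) {
  if (is.null(span)) span <- max(2 * abs(z), 4 * lam * a)
  b <- seq(-span, span, length.out = grid_n)
  pen <- ifelse(abs(b) <= lam, lam * abs(b),
         ifelse(abs(b) <= a * lam,
                -(b^2 - 2 * a * lam * abs(b) + lam^2) / (2 * (a - 1)),
                (a + 1) * lam^2 / 2))
  b[which.min(0.5 * (z - b)^2 + pen)]
}

# pairwise-comparison AUC with ties counted 1/2
auc_pairwise <- function(scores, active, p) {
  pos <- scores[active]
  neg <- scores[setdiff(seq_len(p), active)]
  cmp <- outer(pos, neg, function(a, b)
    ifelse(a > b, 1, ifelse(a == b, 0.5, 0)))
  mean(cmp)
}

# a path_fit built directly from a membership/value matrix, for metric
# tests that need full control of the active sets along the path
fake_path <- function(beta, lambda) {
  structure(list(lambda = lambda, beta = beta,
                 a0 = rep(0, length(lambda)),
                 center = rep(0, nrow(beta)), scale = rep(1, nrow(beta)),
                 y_center = 0, family = "enet", alpha = 1,
                 converged = rep(1L, length(lambda))),
            class = "path_fit")
}
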