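test_that("standardization centers, scales and round-trips", {
  X <- cbind(c(1, 2, 3), c(10, 0, -4))
  y <- c(3, 1, 2)
  std <- standardize(X, y)
  expect_equal(colMeans(std$X), c(0, 0))
  expect_equal(colSums(std$X^2) / 3, c(1, 1))
  expect_equal(mean(std$y), 0)
  expect_error(standardize(cbind(X, 5), y), "zero-variance")
  # round trip: destandardized coefficients reproduce fitted values
  inst <- small_instance()
  fit <- fit_enet_path(inst$X, inst$y, alpha = 1)
  s <- 70
  expect_equal(predict(fit, inst$X, s = s),
               as.vector(inst$X %*% fit$beta[, s]) + fit$a0[s])
  # CSV serialization round-trips the lambda grid and coefficients
  tf <- withr::local_tempfile(fileext = ".csv")
  write_path_csv(fit, tf)
  back <- read.csv(tf)
  expect_equal(back$lambda, fit$lambda)
  expect_equal(unname(as.matrix(back[, -1])), unname(t(fit$beta)),
               tolerance = 1e-12)
})

test_that("the lasso entry point and univariate solution are exact", {
  # at lambda_max the solution is exactly zero (KKT)
  inst <- small_instance()
  fit <- fit_enet_path(inst$X, inst$y, alpha = 1)
  expect_true(all(fit$beta[, 1] == 0))
  expect_true(any(fit$beta[, 2] != 0))
  # univariate standardized lasso: z = 1, lambda 0.4 -> 0.6 (times sd(y))
  n <- 400
  set.seed(8)
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- x        # unit response: x'y/n = 1 exactly, sd(y) = 1
  X2 <- cbind(x, rnorm(n) * 1e-8 + rnorm(n))  # second inert column
  X2[, 2] <- X2[, 2] - mean(X2[, 2])
  f <- fit_enet_path(cbind(x, X2[, 2]), y, lambda = c(0.5, 0.4))
  expect_equal(unname(f$beta[1, 2]), 0.6, tolerance = 1e-5)
})

test_that("elastic-net paths satisfy the KKT certificate", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 40; p <- 25
    X <- matrix(rnorm(n * p), n, p)
    y <- as.vector(X[, 1:3] %*% c(2, -1, 1)) + rnorm(n)
    fit <- fit_enet_path(X, y, alpha = 1, n_lambda = 30)
    std <- standardize(X, y)
    sdy <- sqrt(mean(std$y^2))
    for (s in c(5, 15, 30)) {
      b <- fit$beta[, s] * std$scale / sdy     # standardized-unit coefs
      r <- std$y / sdy - std$X %*% b
      g <- abs(as.vector(crossprod(std$X, r))) / n
      lam <- fit$lambda[s] / sdy
      expect_true(all(g[b == 0] <= lam + 1e-6))
      nz <- which(b != 0)
      expect_true(all(abs(g[nz] - lam) <= 1e-6))
    }
  }
})

test_that("alpha = 0 matches the ridge closed form and alpha extremes cohere", {
  inst <- small_instance(n = 50, p = 12)
  fit <- fit_enet_path(inst$X, inst$y, alpha = 0, n_lambda = 20)
  std <- standardize(inst$X, inst$y)
  sdy <- sqrt(mean(std$y^2))
  p <- ncol(inst$X)
  for (s in c(1, 10, 20)) {
    lam_std <- fit$lambda[s] / sdy
    b_oracle <- solve(crossprod(std$X) / 50 + lam_std * diag(p),
                      crossprod(std$X, std$y) / 50)
    expect_equal(unname(fit$beta[, s]),
                 unname(as.vector(b_oracle) / std$scale),
                 tolerance = 1e-6)
  }
  # y = 0 gives the zero path
  f0 <- fit_enet_path(inst$X, rep(2, 50), alpha = 1)
  expect_true(all(f0$beta == 0))
})

test_that("elastic-net solutions agree with an independent reference solver", {
  skip_if_not_installed("glmnet")
  inst <- small_instance(n = 80, p = 15, sigma = 1)
  for (al in c(1, 0.6, 0.3)) {
    fit <- fit_enet_path(inst$X, inst$y, alpha = al)
    g <- glmnet::glmnet(inst$X, inst$y, alpha = al, lambda = fit$lambda,
                        standardize = TRUE, thresh = 1e-13, maxit = 1e7)
    expect_lt(max(abs(as.matrix(g$beta) - fit$beta)), 1e-5)
    expect_lt(max(abs(g$a0 - fit$a0)), 1e-5)
  }
})

test_that("SCAD univariate updates match brute-force minimization", {
  # soft-threshold regime, interpolation regime, no-shrinkage regime
  cases <- list(c(z = 1.5, lam = 1), c(z = 2.5, lam = 1), c(z = 5, lam = 1),
                c(z = -2.5, lam = 1), c(z = 0.8, lam = 0.5),
                c(z = 3.3, lam = 1.2))
  n <- 500
  set.seed(9)
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  for (cs in cases) {
    y <- cs["z"] * x                      # x'y/n = z exactly
    f <- fit_scad_path(cbind(x, rnorm(n)), y,
                       lambda = c(cs[["lam"]] * 2.5, cs[["lam"]]))
    oracle <- scad_brute(cs[["z"]], cs[["lam"]], 3.7)
    expect_equal(unname(f$beta[1, 2]), oracle, tolerance = 3e-3)
  }
  # printed anchor values of the three regimes
  expect_equal(scad_brute(1.5, 1, 3.7), 0.5, tolerance = 3e-3)
  expect_equal(scad_brute(2.5, 1, 3.7), (2.7 * 2.5 - 3.7) / 1.7,
               tolerance = 3e-3)
  expect_equal(scad_brute(5, 1, 3.7), 5, tolerance = 3e-3)
})

test_that("adaptive weights rescale the penalty and exclude zero-initialized variables", {
  inst <- small_instance(n = 70, p = 10)
  # uniform weights: identical to plain lasso at a rescaled lambda grid
  f1 <- fit_enet_path(inst$X, inst$y, alpha = 1, n_lambda = 40)
  f2 <- fit_enet_path(inst$X, inst$y, alpha = 1, lambda = f1$lambda / 2,
                      penalty_factor = rep(2, 10))
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  # infinite weight: the variable never enters
  f3 <- fit_enet_path(inst$X, inst$y, alpha = 1,
                      penalty_factor = c(Inf, rep(1, 9)))
  expect_true(all(f3$beta[1, ] == 0))
  # two-stage fit produces a path and larger initial estimates get
  # smaller weights
  ada <- fit_adaptive_lasso(inst$X, inst$y, cv_seed = 4)
  expect_s3_class(ada, "path_fit")
  expect_equal(ada$family, "adalasso")
  w <- ada$penalty_factor
  expect_true(w[which.max(abs(inst$beta))] < median(w))
})

test_that("paths are continuous in lambda for convex penalties", {
  inst <- small_instance(n = 60, p = 20)
  fit <- fit_enet_path(inst$X, inst$y, alpha = 0.6, n_lambda = 200)
  jumps <- apply(abs(diff(t(fit$beta))), 1, max)
  expect_lt(max(jumps), 0.15)
})

test_that("predictions are equivariant to affine rescaling of the inputs", {
  inst <- small_instance(n = 60, p = 6)
  scales <- c(2, 0.5, 10, 1, 0.1, 3)
  shifts <- c(1, -2, 0, 5, 0.3, -1)
  Xr <- sweep(sweep(inst$X, 2, scales, "*"), 2, shifts, "+")
  f1 <- fit_enet_path(inst$X, inst$y, alpha = 1)
  f2 <- fit_enet_path(Xr, inst$y, alpha = 1, lambda = f1$lambda)
  expect_equal(predict(f1, inst$X, s = 50), predict(f2, Xr, s = 50),
               tolerance = 1e-6)
})
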