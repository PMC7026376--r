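test_that("rmse matches its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(rep(0, 5), rep(2, 5)), 2)   # constant residual c -> |c|
  set.seed(1)
  y <- rnorm(200)
  # predicting the (zero) training mean on centered data ~ sd of y
  expect_equal(rmse(y, rep(0, 200)), sqrt(mean(y^2)))
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("confusion counts and rates match exhaustive enumeration", {
  expect_equal(confusion(1:10, 1:10, 50),
               c(tp = 10, fp = 0, fn = 0, tn = 40))
  expect_equal(confusion(integer(0), 1:10, 50),
               c(tp = 0, fp = 0, fn = 10, tn = 40))
  expect_equal(confusion(c(1:8, 11, 12), 1:10, 100),
               c(tp = 8, fp = 2, fn = 2, tn = 88))
  expect_equal(tpr_ppv(8, 2, 2), c(tpr = 0.8, ppv = 0.8))
  expect_equal(tpr_ppv(10, 0, 0), c(tpr = 1, ppv = 1))
  expect_true(is.na(tpr_ppv(0, 0, 10)["ppv"]))
  expect_equal(tpr_ppv(0, 0, 10)[["tpr"]], 0)
  # random small instances against direct set logic
  set.seed(33)
  for (r in 1:20) {
    p <- sample(5:20, 1)
    act <- sort(sample.int(p, sample.int(p - 1, 1)))
    sel <- sort(sample.int(p, sample.int(p, 1)))
    cm <- confusion(sel, act, p)
    expect_equal(unname(cm["tp"]), sum(sel %in% act))
    expect_equal(unname(cm["fp"]), sum(!sel %in% act))
    expect_equal(unname(cm["fn"]), sum(!act %in% sel))
    expect_equal(sum(cm), p)
  }
  expect_error(confusion(c(0, 3), 1:2, 5), "out of range")
})

test_that("path-persistence scores implement the dropout-truncation rule", {
  # grid descending: lambda = 0.4, 0.3, 0.2, 0.1
  lam <- c(0.4, 0.3, 0.2, 0.1)
  B <- rbind(c(0, 1, 1, 1),   # drops out at 0.4 -> score 0.3
             c(0, 1, 0, 1),   # gap at 0.2 -> truncated to 0.1
             c(0, 0, 0, 0),   # never active -> 0
             c(1, 1, 1, 1),   # full path -> 0.4
             c(1, 1, 1, 0))   # inactive at lambda_min -> 0
  sc <- path_ranking_scores(fake_path(B, lam))
  expect_equal(sc, c(0.3, 0.1, 0, 0.4, 0))
})

test_that("ranking scores never invert the dropout order", {
  inst <- small_instance(n = 60, p = 15, sigma = 1)
  fit <- fit_enet_path(inst$X, inst$y, alpha = 1, n_lambda = 50)
  sc <- path_ranking_scores(fit)
  nz <- fit$beta != 0
  # survival depth: smallest grid index from which a variable stays active
  depth <- apply(nz, 1, function(z) {
    L <- length(z)
    if (!z[L]) return(Inf)
    k <- L
    while (k >= 2 && z[k - 1]) k <- k - 1
    k
  })
  ord <- order(depth)
  expect_true(all(diff(sc[ord]) <= 1e-12))
})

test_that("method score dispatch matches the per-method definitions", {
  cvr <- structure(list(beta = c(-2, 0.5, 0), family = "enet", alpha = 0,
                        path = NULL),
                   class = "cv_fit")
  expect_equal(method_scores(cvr, "ridge"), c(2, 0.5, 0))
  sr <- structure(list(freq = rbind(c(0.9, 0.2), c(0.4, 0.1)),
                       scores = c(0.9, 0.2)),
                  class = "stability_result")
  expect_equal(method_scores(sr), c(0.9, 0.2))
  inst <- small_instance()
  fit <- fit_enet_path(inst$X, inst$y, alpha = 1)
  expect_equal(method_scores(fit), path_ranking_scores(fit))
})

test_that("pauc handles perfect, random-tie and adversarial rankings", {
  p <- 500; act <- 1:10
  sc_perfect <- c(rep(2, 10), rep(1, 490))
  expect_equal(pauc(sc_perfect, act, p), 1)
  # one global tie block traverses the diagonal: normalized area is
  # half the window width
  expect_equal(pauc(rep(1, p), act, p), (50 / 490) / 2)
  expect_equal(round(pauc(rep(1, p), act, p), 3), 0.051)
  # all signals below > 50 non-signals
  sc_bad <- c(rep(0, 10), rep(3, 490))
  expect_equal(pauc(sc_bad, act, p), 0)
  expect_error(pauc(rep(1, 20), 1:15, 20, max_fp = 10), "max_fp")
})

test_that("pauc is invariant to monotone transforms and matches pairwise AUC", {
  set.seed(35)
  for (r in 1:10) {
    p <- sample(20:50, 1)
    s0 <- sample(3:8, 1)
    act <- sort(sample.int(p, s0))
    sc <- sample(0:5, p, replace = TRUE) + rnorm(p, 0, 0.01) *
      rbinom(p, 1, 0.5)                  # many exact ties, some unique
    full <- pauc(sc, act, p, max_fp = p - s0)
    expect_equal(full, auc_pairwise(sc, act, p), tolerance = 1e-9)
    expect_equal(pauc(exp(2 * sc), act, p, max_fp = p - s0), full,
                 tolerance = 1e-9)
    windowed <- pauc(sc, act, p, max_fp = min(10, p - s0))
    expect_equal(pauc(sc^3 + 1, act, p, max_fp = min(10, p - s0)),
                 windowed, tolerance = 1e-9)
  }
})
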