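test_that("applicability encodes the method restrictions", {
  pw2000 <- scenario_config("pairwise", 100, 2000, 10, 1, p_B = 10,
                            s0_B = 1, rho = 0.5)
  pw1000 <- scenario_config("pairwise", 100, 1000, 10, 1, p_B = 10,
                            s0_B = 1, rho = 0.5)
  ind <- scenario_config("independence", 100, 2000, 10, 1)
  ssl <- scenario_config("semisyn_low", 100, 2000, 10, 1)
  expect_false(applicable("dantzig", pw2000, "selection"))
  expect_true(applicable("dantzig", pw1000, "selection"))
  expect_true(applicable("dantzig", ind, "selection"))
  expect_false(applicable("dantzig", ssl, "selection"))
  expect_false(applicable("adalasso", pw1000, "ranking"))
  expect_true(applicable("adalasso", ssl, "ranking"))
  expect_false(applicable("ridge", ind, "selection"))
  expect_true(applicable("ridge", ind, "ranking"))
  expect_false(applicable("stabsel", ind, "prediction"))
  for (m in names(method_registry()))
    expect_true(applicable("lasso", ind, "ranking"))
})

test_that("child seeds are deterministic, in range and replicate-distinct", {
  s1 <- child_seed(1, "abc", 1)
  expect_identical(s1, child_seed(1, "abc", 1))
  expect_true(s1 >= 0 && s1 < 2^31)
  seeds <- vapply(1:200, function(r) child_seed(7, "scen_x", r),
                  integer(1))
  expect_equal(anyDuplicated(seeds), 0)
  expect_false(child_seed(1, "abc", 1) == child_seed(2, "abc", 1))
  expect_false(child_seed(1, "abc", 1) == child_seed(1, "abd", 1))
})

test_that("run_scenario emits one record per method, task and metric and reruns identically", {
  cfg <- scenario_config("independence", 40, 60, 4, 3, n_test = 30)
  rec <- run_scenario(cfg, methods = c("lasso", "ridge"),
                      n_reps = 2, root_seed = 5)
  # lasso: rmse + tpr + ppv + pauc; ridge: rmse + pauc (no selection)
  expect_equal(nrow(rec), 2 * (4 + 2))
  expect_setequal(unique(rec$metric), c("rmse", "tpr", "ppv", "pauc"))
  expect_true(all(rec$value[rec$metric %in% c("tpr", "ppv", "pauc")] >= 0,
                  na.rm = TRUE))
  rec2 <- run_scenario(cfg, methods = c("lasso", "ridge"),
                       n_reps = 2, root_seed = 5)
  expect_identical(rec, rec2)
  # an easy scenario is solved: lasso finds every signal
  expect_true(all(rec$value[rec$method == "lasso" &
                              rec$metric == "tpr"] == 1))
})

test_that("stability selection runs inside the scenario loop with V control on semisynthetic data", {
  pool <- build_pool(n_pool = 70, p_pool = 50, n_clusters = 2,
                     within_cluster_corr = 0.7, seed = 8)
  cfg <- scenario_config("semisyn_low", 40, 30, 3, 3)
  rec <- run_scenario(cfg, methods = "stabsel",
                      tasks = c("selection", "ranking"), n_reps = 1,
                      root_seed = 3, pool = pool, max_fp = 10)
  expect_setequal(unique(rec$metric), c("tpr", "ppv", "pauc"))
  expect_equal(unique(rec$method), "stabsel")
})

test_that("aggregation reports means, standard errors and missing counts", {
  cfg <- scenario_config("independence", 40, 60, 4, 3, n_test = 30)
  rec <- run_scenario(cfg, methods = "lasso", n_reps = 3, root_seed = 2)
  agg <- aggregate_records(rec)
  one <- agg[agg$metric == "rmse", ]
  vals <- rec$value[rec$metric == "rmse"]
  expect_equal(one$mean, mean(vals))
  expect_equal(one$se, sd(vals) / sqrt(3))
  expect_equal(one$n_used, 3)
  # hand-built records with an NA PPV
  fake <- rec[rec$metric == "ppv", ]
  fake$value[1] <- NA
  agg2 <- aggregate_records(fake)
  expect_equal(agg2$n_missing, 1)
  expect_equal(agg2$mean, mean(fake$value, na.rm = TRUE))
})

test_that("experiment presets honor their factor grids at desk scale", {
  rec <- experiment_heterogeneous(c_beta_levels = c(0.5, 1),
                                  snr_levels = 4, methods = "lasso",
                                  n = 40, p = 60, s0 = 4, n_reps = 2,
                                  root_seed = 2)
  expect_setequal(unique(rec$c_beta), c(0.5, 1))
  expect_true(all(c("tpr_strong", "tpr_weak") %in% names(rec)))
  st <- experiment_stability_tuning(V_levels = c(1, 20),
                                    pi_levels = 0.6,
                                    gamma_levels = c(0.5, 0.7),
                                    s0_levels = 4,
                                    designs = "independence",
                                    n = 40, p = 60, snr = 3, M = 10,
                                    n_reps = 2, root_seed = 2)
  expect_equal(nrow(st), 2 * 2 * 2)      # gamma x V x replicate
  expect_setequal(unique(st$gamma), c(0.5, 0.7))
  # selected-set size grows (weakly) with the error bound
  wide <- tapply(st$n_selected, st$V_bound, mean)
  expect_lte(wide[["1"]], wide[["20"]])
})

test_that("the toeplitz preset pairs designs and skips infeasible combos", {
  expect_message(
    rec <- experiment_toeplitz(n_levels = 40, p_levels = c(200, 400),
                               s0_levels = c(4, 10), snr_levels = 3,
                               methods = "lasso", n_reps = 1,
                               root_seed = 4, tasks = "selection"),
    "skipping")
  # s0=10 needs 5 blocks of 100: infeasible at p=200 and p=400, so only
  # the two s0=4 combinations run, each under both designs
  expect_setequal(unique(rec$design), c("toeplitz", "pairwise"))
  combos <- unique(rec[, c("design", "p", "s0")])
  expect_equal(nrow(combos), 2 * 2)
})
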