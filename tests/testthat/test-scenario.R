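test_that("default grid enumerates 2394 scenarios with the expected family subtotals", {
  grid <- enumerate_scenarios()
  expect_equal(nrow(grid), 2394)
  counts <- table(grid$design)
  expect_equal(unname(counts[["independence"]]), 144)
  expect_equal(unname(counts[["semisyn_low"]]), 144)
  expect_equal(unname(counts[["semisyn_high"]]), 432)
  expect_equal(unname(counts[["pairwise"]]), 1674)
  # no duplicated scenarios
  expect_equal(anyDuplicated(grid$scenario), 0)
})

test_that("independence family is the plain factorial cross-product", {
  ind <- enumerate_scenarios(designs = "independence")
  # brute-force oracle: cross product of the factor levels
  oracle <- expand.grid(n = c(100, 200, 300), p = c(500, 1000, 2000, 4000),
                        s0 = c(10, 20, 40), snr = c(0.5, 1, 2, 4))
  expect_equal(nrow(ind), nrow(oracle))
  expect_equal(sort(unique(ind$n)), c(100, 200, 300))
  expect_true(all(is.na(ind$p_B)))
})

test_that("pairwise big-block inclusion matches the published inclusion table", {
  # hard-coded inclusion matrix for block size 100: admitted s0_B values
  incl <- list("500" = list("10" = c(2, 5), "20" = 5, "40" = numeric(0)),
               "1000" = list("10" = c(1, 2, 5), "20" = c(2, 5), "40" = 5),
               "2000" = list("10" = c(1, 2, 5), "20" = c(1, 2, 5),
                             "40" = c(2, 5)),
               "4000" = list("10" = c(1, 2, 5), "20" = c(1, 2, 5),
                             "40" = c(1, 2, 5)))
  pw <- enumerate_scenarios(designs = "pairwise")
  pw100 <- unique(pw[pw$p_B == 100, c("p", "s0", "s0_B")])
  expect_equal(nrow(pw100), 26)   # count of admitted combinations
  for (i in seq_len(nrow(pw100)))
    expect_true(pw100$s0_B[i] %in%
                  incl[[as.character(pw100$p[i])]][[as.character(pw100$s0[i])]])
  # small blocks admit every combination
  pw10 <- unique(pw[pw$p_B == 10, c("p", "s0", "s0_B")])
  expect_equal(nrow(pw10), 4 * 3 * 3)
  # excluded SNR level never appears in the pairwise family
  expect_false(any(pw$snr == 0.5))
})

test_that("rescaled sample size uses the natural logarithm", {
  expect_equal(round(rescaled_n(200, 1000, 10), 2), 2.90)
  expect_equal(round(rescaled_n(200, 4000, 40), 2), 0.60)
  expect_equal(round(rescaled_n(200, 1000, 20), 2), 1.45)
  expect_error(rescaled_n(100, 10, 10), "p > s0")
})

test_that("scenario validation rejects inconsistent block structure", {
  expect_error(scenario_config("pairwise", 100, 500, 40, 1, p_B = 100,
                               s0_B = 1, rho = 0.5), "s0_B")
  expect_error(scenario_config("pairwise", 100, 500, 10, 1, p_B = 3,
                               s0_B = 1, rho = 0.5), "divide")
  expect_error(scenario_config("pairwise", 100, 500, 10, 1, p_B = 10,
                               s0_B = 1, rho = 1.2), "rho")
  expect_error(scenario_config("toeplitz", 100, 500, 10, 1, p_B = 100,
                               s0_B = 5), "s0_B = 2")
  expect_error(scenario_config("unknown", 100, 500, 10, 1))
})

test_that("a YAML grid spec overrides defaults and reproduces subsets", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n: [100, 200]", "p: [500]", "s0: [10]",
               "snr: [1, 2]"), tf)
  grid <- read_grid(tf)
  ind <- enumerate_scenarios(grid, designs = "independence")
  expect_equal(nrow(ind), 2 * 1 * 1 * 2)
})
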