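#' Toeplitz versus pairwise correlation comparison
#'
#' Paired runs of the Toeplitz block design (block size 100, two
#' signals per block spaced 7 apart, base correlation 0.95, so the
#' signal pair has correlation `0.95^7 ~ 0.7`) against the matched
#' pairwise design (`rho = 0.7`, `s0_B = 2`, `p_B = 100`) over all
#' feasible `(n, p, s0)` combinations at the given SNR levels. Matched
#' pairs share replicate seeds for variance reduction; infeasible
#' combinations (too few blocks for the signals) are skipped with a
#' message.
#'
#' @param n_levels,p_levels,s0_levels,snr_levels factor levels.
#' @param methods,n_reps,root_seed,tasks passed to [run_scenario()].
#' @return a record tibble covering both designs for every retained
#'   combination.
#' @export
experiment_toeplitz <- function(n_levels = c(100, 200, 300),
                                p_levels = c(500, 1000, 2000, 4000),
                                s0_levels = c(10, 20, 40),
                                snr_levels = c(1, 2, 4),
                                methods = c("lasso", "ridge", "henet",
                                            "scad"),
                                n_reps = 64, root_seed = 1L,
                                tasks = c("prediction", "selection",
                                          "ranking")) {
  grid <- expand.grid(n = n_levels, p = p_levels, s0 = s0_levels,
                      snr = snr_levels, KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$s0 / 2 > g$p / 100) {        # needs s0/2 blocks of size 100
      message("skipping (p=", g$p, ", s0=", g$s0,
              "): s0/s0_B exceeds the number of blocks")
      next
    }
    for (des in c("toeplitz", "pairwise")) {
      cfg <- scenario_config(des, n = g$n, p = g$p, s0 = g$s0,
                             snr = g$snr, p_B = 100, s0_B = 2,
                             rho = if (des == "pairwise") 0.7)
      out[[paste(des, i)]] <- run_scenario(cfg, methods = methods,
                                           tasks = tasks,
                                           n_reps = n_reps,
                                           root_seed = root_seed)
    }
  }
  dplyr::bind_rows(out)
}

#' Stability-selection tuning sweep
#'
#' Crosses the stability-selection tuning grid — expected-false-positive
#' bound `V in {1, 5, 10, 15, 20}`, threshold `pi_thr in {0.6, 0.9}` and
#' subsample proportion `gamma in {0.4, 0.5, 0.6, 0.7}` — on the four
#' reference scenarios (independence and pairwise `rho = 0.7`,
#' `p_B = 10`, `s0_B = 2`; `n = 200`, `p = 1000`, `s0` 10 or 20,
#' SNR = 2). One stability path is computed per (replicate, gamma) and
#' all `(V, pi_thr)` pairs are evaluated from it.
#'
#' @param V_levels,pi_levels,gamma_levels tuning grids.
#' @param s0_levels scenario sparsity levels.
#' @param designs which of the two reference designs to run.
#' @param n,p,snr scenario constants.
#' @param M subsamples per stability path.
#' @param n_reps replicates (default 100).
#' @param root_seed root seed.
#' @return a record tibble with columns for the tuning parameters.
#' @export
experiment_stability_tuning <- function(V_levels = c(1, 5, 10, 15, 20),
                                        pi_levels = c(0.6, 0.9),
                                        gamma_levels = c(0.4, 0.5, 0.6,
                                                         0.7),
                                        s0_levels = c(10, 20),
                                        designs = c("independence",
                                                    "pairwise"),
                                        n = 200, p = 1000, snr = 2,
                                        M = 100, n_reps = 100,
                                        root_seed = 1L) {
  out <- list()
  for (des in designs) {
    for (s0 in s0_levels) {
      cfg <- if (des == "pairwise")
        scenario_config("pairwise", n, p, s0, snr, p_B = 10, s0_B = 2,
                        rho = 0.7)
      else scenario_config("independence", n, p, s0, snr)
      sid <- scenario_id(cfg)
      for (r in seq_len(n_reps)) {
        seed_r <- child_seed(root_seed, sid, r)
        cfg$seed <- seed_r
        ds <- gen_dataset(cfg)
        for (g in gamma_levels) {
          sr <- stability_path(ds$X_train, ds$y_train, M = M,
                               n_sub = floor(g * n), seed = seed_r + 1L)
          for (V in V_levels) for (pi_thr in pi_levels) {
            sel <- stable_set(sr, pi_thr = pi_thr, V_bound = V)
            cm <- confusion(sel, ds$active_set, p)
            tv <- tpr_ppv(cm["tp"], cm["fp"], cm["fn"])
            out[[length(out) + 1L]] <- tibble::tibble(
              scenario = sid, design = des, n = n, p = p, s0 = s0,
              snr = snr, gamma = g, V_bound = V, pi_thr = pi_thr,
              replicate = r, tpr = unname(tv["tpr"]),
              ppv = unname(tv["ppv"]), n_selected = length(sel))
          }
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Heterogeneous-coefficient selection experiment
#'
#' Independence design with `n = 300`, `p = 4000`, `s0 = 40`: half the
#' signals carry coefficient `beta' = sqrt(18 / (1 + c^2))` and half
#' `c * beta'`, over a grid of heterogeneity factors `c`, keeping the
#' signal energy (and hence the calibrated noise) constant. Methods
#' lasso, heavy elastic net and SCAD are fitted with ten-fold CV;
#' overall TPR/PPV records are emitted together with separate
#' strong-half and weak-half TPR diagnostics.
#'
#' @param c_beta_levels heterogeneity grid (default 0.1 to 1 by 0.1).
#' @param snr_levels SNR levels (default `c(2, 4)`).
#' @param methods methods to run.
#' @param n,p,s0 scenario constants.
#' @param n_reps replicates (default 50).
#' @param root_seed root seed.
#' @return a record tibble; metrics `tpr`, `ppv`, `tpr_strong`,
#'   `tpr_weak`.
#' @export
experiment_heterogeneous <- function(c_beta_levels = seq(0.1, 1, by = 0.1),
                                     snr_levels = c(2, 4),
                                     methods = c("lasso", "henet",
                                                 "scad"),
                                     n = 300, p = 4000, s0 = 40,
                                     n_reps = 50, root_seed = 1L) {
  registry <- method_registry()
  stopifnot(all(methods %in% names(registry)))
  out <- list()
  for (snr in snr_levels) for (cb in c_beta_levels) {
    cfg <- scenario_config("independence", n, p, s0, snr, c_beta = cb)
    sid <- scenario_id(cfg)
    for (r in seq_len(n_reps)) {
      seed_r <- child_seed(root_seed, sid, r)
      cfg$seed <- seed_r
      ds <- gen_dataset(cfg)
      strong <- ds$active_set[seq_len(s0 / 2)]
      weak <- setdiff(ds$active_set, strong)
      for (m in methods) {
        cv <- fit_method_cv(registry[[m]], ds$X_train, ds$y_train,
                            seed = seed_r + 2L)
        sel <- selected_set(cv)
        cm <- confusion(sel, ds$active_set, p)
        tv <- tpr_ppv(cm["tp"], cm["fp"], cm["fn"])
        out[[length(out) + 1L]] <- tibble::tibble(
          scenario = sid, design = "independence", n = n, p = p,
          s0 = s0, snr = snr, c_beta = cb, method = m, replicate = r,
          tpr = unname(tv["tpr"]), ppv = unname(tv["ppv"]),
          tpr_strong = length(intersect(sel, strong)) / length(strong),
          tpr_weak = length(intersect(sel, weak)) / length(weak))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Plot a metric against a design factor
#'
#' Minimal panel helper: aggregated metric means against a chosen
#' factor, one line per method. Requires ggplot2.
#'
#' @param summary an aggregated tibble from [aggregate_records()].
#' @param metric metric name to plot.
#' @param x design-factor column name (e.g. `"p"`, `"rho"`, `"snr"`).
#' @return a ggplot object.
#' @export
plot_metric <- function(summary, metric, x = "p") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_metric requires ggplot2")
  df <- summary[summary$metric == metric, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$mean,
                                   colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = metric, x = x)
}
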