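#' Benchmark method registry
#'
#' The eight compared methods with their fixed parameter mappings:
#' lasso/ridge/HENet/LENet are the elastic net at mixing weights 1, 0,
#' 0.3 and 0.6; SCAD uses shape 3.7; the adaptive lasso uses
#' ridge-initialized weights with exponent 1; stability selection uses
#' M = 100 lasso subsamples of size `floor(0.632 n)` and threshold 0.6.
#'
#' @return a named list of method descriptors (`name`, `family`,
#'   parameters).
#' @export
method_registry <- function() {
  list(
    lasso = list(name = "lasso", family = "enet", alpha = 1),
    ridge = list(name = "ridge", family = "enet", alpha = 0),
    henet = list(name = "henet", family = "enet", alpha = 0.3),
    lenet = list(name = "lenet", family = "enet", alpha = 0.6),
    adalasso = list(name = "adalasso", family = "adalasso", gamma_w = 1),
    scad = list(name = "scad", family = "scad", a = 3.7),
    dantzig = list(name = "dantzig", family = "dantzig"),
    stabsel = list(name = "stabsel", family = "stabsel", M = 100,
                   pi_thr = 0.6)
  )
}

#' Method applicability rules
#'
#' Encodes which method runs where: the Dantzig selector is restricted
#' to the synthetic independence design and synthetic correlated
#' designs with `p <= 1000` (computational demands under
#' multicollinearity); the adaptive lasso is not run on the synthetic
#' correlated designs; stability selection does not produce a
#' predictor and is excluded from the prediction task; ridge performs
#' no variable selection and is excluded from the selection task.
#'
#' @param method method name (see [method_registry()]).
#' @param config a [scenario_config()] (or its design string via
#'   `design`/`p`).
#' @param task `"prediction"`, `"selection"` or `"ranking"`.
#' @return `TRUE` if the method/scenario/task combination is run.
#' @export
applicable <- function(method, config, task) {
  design <- config$design; p <- config$p
  if (method == "dantzig") {
    if (design %in% c("semisyn_low", "semisyn_high")) return(FALSE)
    if (design %in% c("pairwise", "toeplitz") && p > 1000) return(FALSE)
  }
  if (method == "adalasso" && design %in% c("pairwise", "toeplitz"))
    return(FALSE)
  if (method == "stabsel" && task == "prediction") return(FALSE)
  if (method == "ridge" && task == "selection") return(FALSE)
  TRUE
}

#' Deterministic per-replicate child seed
#'
#' Expands a root seed into independent child seeds by a counter-based
#' polynomial hash of the scenario identifier and replicate number, kept
#' below 2^31 so any replicate is reproducible in isolation.
#'
#' @param root_seed integer root seed.
#' @param scenario_id scenario identifier string.
#' @param replicate replicate number (1-based).
#' @return an integer seed.
#' @export
child_seed <- function(root_seed, scenario_id, replicate) {
  mod <- 2147483647
  h <- 0
  for (ch in utf8ToInt(scenario_id)) h <- (h * 131 + ch) %% mod
  as.integer((h * 1009 + root_seed * 7919 + replicate * 104729) %% mod)
}

fit_method_cv <- function(spec, X, y, seed) {
  switch(spec$family,
    enet = cv_select(X, y, family = "enet", alpha = spec$alpha,
                     seed = seed),
    adalasso = cv_select(X, y, family = "adalasso",
                         gamma_w = spec$gamma_w, seed = seed),
    scad = cv_select(X, y, family = "scad", a = spec$a, seed = seed),
    dantzig = cv_select(X, y, family = "dantzig", seed = seed))
}

record_row <- function(config, method, replicate, task, metric, value) {
  tibble::tibble(scenario = scenario_id(config), design = config$design,
                 n = config$n, p = config$p, s0 = config$s0,
                 snr = config$snr,
                 p_B = config$p_B %||% NA_integer_,
                 s0_B = config$s0_B %||% NA_integer_,
                 rho = config$rho %||% NA_real_,
                 c_beta = config$c_beta, method = method,
                 replicate = replicate, task = task, metric = metric,
                 value = unname(value))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one scenario across methods and replicates
#'
#' For each replicate: generate a dataset from the scenario (all
#' methods see the same data within a replicate), fit each applicable
#' method with ten-fold CV (prediction RMSE on the test split; selected
#' set = nonzero coefficients at the CV lambda), reuse the full-data
#' path for the ranking scores, and run stability selection where
#' requested. Semisynthetic selection applies the expected-false-
#' positive bound `V = 10` to stability selection; synthetic designs
#' run it without explicit control. A solver failure yields flagged
#' `NA` records, never a crashed run.
#'
#' @param config a [scenario_config()] (its own seed is ignored;
#'   replicate seeds derive from `root_seed`).
#' @param methods character vector of method names from
#'   [method_registry()].
#' @param tasks subset of `c("prediction", "selection", "ranking")`.
#' @param n_reps number of replicate datasets (default 64).
#' @param root_seed root seed expanded by [child_seed()].
#' @param pool covariate pool for semisynthetic designs.
#' @param max_fp false-positive cap of the ranking pAUC window.
#' @param stabsel_V optional expected-false-positive bound for
#'   stability selection; default 10 for semisynthetic designs, none
#'   otherwise.
#' @return a tibble of metric records (one row per scenario, method,
#'   replicate, task, metric).
#' @export
run_scenario <- function(config, methods = names(method_registry()),
                         tasks = c("prediction", "selection", "ranking"),
                         n_reps = 64, root_seed = 1L, pool = NULL,
                         max_fp = 50, stabsel_V = NULL) {
  stopifnot(inherits(config, "scenario_config"), n_reps >= 1)
  registry <- method_registry()
  stopifnot(all(methods %in% names(registry)))
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (is.null(stabsel_V) &&
      config$design %in% c("semisyn_low", "semisyn_high"))
    stabsel_V <- 10
  sid <- scenario_id(config)
  out <- list()
  for (r in seq_len(n_reps)) {
    seed_r <- child_seed(root_seed, sid, r)
    cfg <- config; cfg$seed <- seed_r
    ds <- gen_dataset(cfg, pool = pool)
    for (m in methods) {
      spec <- registry[[m]]
      mtasks <- tasks[vapply(tasks, function(tk)
        applicable(m, config, tk), logical(1))]
      if (length(mtasks) == 0) next
      res <- tryCatch({
        if (m == "stabsel") {
          sr <- stability_path(ds$X_train, ds$y_train, M = spec$M,
                               seed = seed_r + 1L)
          rows <- list()
          if ("selection" %in% mtasks) {
            sel <- stable_set(sr, pi_thr = spec$pi_thr,
                              V_bound = stabsel_V)
            cm <- confusion(sel, ds$active_set, config$p)
            tv <- tpr_ppv(cm["tp"], cm["fp"], cm["fn"])
            rows <- c(rows, list(
              record_row(config, m, r, "selection", "tpr", tv["tpr"]),
              record_row(config, m, r, "selection", "ppv", tv["ppv"])))
          }
          if ("ranking" %in% mtasks) {
            pa <- pauc(method_scores(sr), ds$active_set, config$p,
                       max_fp)
            rows <- c(rows, list(
              record_row(config, m, r, "ranking", "pauc", pa)))
          }
          rows
        } else {
          cv <- fit_method_cv(spec, ds$X_train, ds$y_train,
                              seed = seed_r + 2L)
          rows <- list()
          if ("prediction" %in% mtasks) {
            err <- rmse(ds$y_test, predict(cv, ds$X_test))
            rows <- c(rows, list(
              record_row(config, m, r, "prediction", "rmse", err)))
          }
          if ("selection" %in% mtasks) {
            cm <- confusion(selected_set(cv), ds$active_set, config$p)
            tv <- tpr_ppv(cm["tp"], cm["fp"], cm["fn"])
            rows <- c(rows, list(
              record_row(config, m, r, "selection", "tpr", tv["tpr"]),
              record_row(config, m, r, "selection", "ppv", tv["ppv"])))
          }
          if ("ranking" %in% mtasks) {
            sc <- method_scores(cv, method = m)
            pa <- pauc(sc, ds$active_set, config$p, max_fp)
            rows <- c(rows, list(
              record_row(config, m, r, "ranking", "pauc", pa)))
          }
          rows
        }
      }, error = function(e) {
        warning("method ", m, " failed on ", sid, " replicate ", r,
                ": ", conditionMessage(e))
        lapply(mtasks, function(tk)
          record_row(config, m, r, tk, "failed", NA_real_))
      })
      out <- c(out, res)
    }
  }
  dplyr::bind_rows(out)
}

#' Aggregate metric records
#'
#' Means and standard errors per scenario, method, task and metric;
#' `NA` values (e.g. the undefined PPV of empty selections) are
#' excluded from the averages and counted in `n_missing`.
#'
#' @param records a record tibble from [run_scenario()].
#' @return a tibble with `mean`, `se`, `n_used`, `n_missing` per group.
#' @export
aggregate_records <- function(records) {
  stopifnot(nrow(records) > 0)
  dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(
      c("scenario", "design", "n", "p", "s0", "snr", "p_B", "s0_B",
        "rho", "c_beta", "method", "task", "metric")))),
    mean = mean(.data$value, na.rm = TRUE),
    se = if (sum(!is.na(.data$value)) > 1)
      sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value)))
      else 0,
    n_used = sum(!is.na(.data$value)),
    n_missing = sum(is.na(.data$value)),
    .groups = "drop")
}

#' Write metric records to CSV
#'
#' @param records record tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
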