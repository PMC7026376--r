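#' Scenario configuration for a single simulation design point
#'
#' A scenario fixes one point of the factorial benchmark design: the
#' covariate design family, problem dimensions, sparsity, signal-to-noise
#' ratio and (for block designs) the block structure.
#'
#' @param design one of `"independence"`, `"pairwise"`, `"toeplitz"`,
#'   `"semisyn_low"`, `"semisyn_high"`.
#' @param n training sample size (the setting of interest has `p > n`).
#' @param p number of covariates.
#' @param s0 number of active variables (nonzero true coefficients).
#' @param snr signal-to-noise ratio, defined as
#'   `sqrt(beta' X'X beta / (n sigma^2))`; the noise standard deviation is
#'   calibrated to attain it on the realized training design.
#' @param p_B block size for block-structured designs (pairwise, toeplitz,
#'   semisyn_high). Must divide `p` for the synthetic block designs.
#' @param s0_B signals per block; the first `s0 / s0_B` blocks carry
#'   signals, the remaining blocks none.
#' @param rho within-block pairwise correlation (pairwise design only).
#' @param decay base of the within-block correlation `decay^|j1 - j2|`
#'   (toeplitz design only, default 0.95).
#' @param c_beta coefficient heterogeneity factor in `[0, 1]`. At 1 all
#'   active coefficients equal 3; below 1, half the signals get
#'   `sqrt(18 / (1 + c_beta^2))` and the other half that value times
#'   `c_beta`, keeping the expected signal energy fixed.
#' @param n_test test sample size for synthetic designs (default 500).
#'   Semisynthetic designs use all held-out pool rows instead.
#' @param seed integer seed; identical configurations (including seed)
#'   generate bit-identical datasets.
#' @return an object of class `"scenario_config"` (a named list).
#' @seealso [gen_dataset()], [enumerate_scenarios()]
#' @export
scenario_config <- function(design, n, p, s0, snr,
                            p_B = NULL, s0_B = NULL, rho = NULL,
                            decay = 0.95, c_beta = 1, n_test = 500,
                            seed = 1L) {
  design <- match.arg(design,
                      c("independence", "pairwise", "toeplitz",
                        "semisyn_low", "semisyn_high"))
  stopifnot(n >= 1, p >= 1, s0 >= 1, s0 <= p, snr > 0,
            c_beta >= 0, c_beta <= 1, n_test >= 1)
  blocked <- design %in% c("pairwise", "toeplitz", "semisyn_high")
  if (blocked) {
    if (is.null(p_B) || is.null(s0_B))
      stop("design '", design, "' requires p_B and s0_B")
    if (design != "semisyn_high" && p %% p_B != 0)
      stop("p_B must divide p")
    if (s0 %% s0_B != 0)
      stop("s0_B must divide s0")
    if (s0 / s0_B > p / p_B)
      stop("too many signal blocks: s0/s0_B must not exceed p/p_B ",
           "(equivalently s0_B >= s0/B)")
    if (design == "pairwise") {
      if (is.null(rho) || rho <= 0 || rho >= 1)
        stop("pairwise design requires rho in (0, 1)")
    }
    if (design == "toeplitz") {
      if (decay <= 0 || decay >= 1) stop("decay must lie in (0, 1)")
      if (s0_B != 2) stop("toeplitz design uses s0_B = 2 (signal pairs)")
    }
  } else {
    p_B <- NULL; s0_B <- NULL; rho <- NULL
  }
  if (c_beta < 1 && s0 %% 2 != 0)
    stop("heterogeneous coefficients (c_beta < 1) require even s0")
  structure(list(design = design, n = as.integer(n), p = as.integer(p),
                 s0 = as.integer(s0), snr = snr,
                 p_B = if (!is.null(p_B)) as.integer(p_B),
                 s0_B = if (!is.null(s0_B)) as.integer(s0_B),
                 rho = rho, decay = if (design == "toeplitz") decay,
                 c_beta = c_beta, n_test = as.integer(n_test),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", scenario_id(x), "\n", sep = "")
  invisible(x)
}

#' Compact identifier string for a scenario
#'
#' @param config a [scenario_config()].
#' @return a single string encoding the design factors (not the seed).
#' @export
scenario_id <- function(config) {
  parts <- c(config$design,
             paste0("n", config$n), paste0("p", config$p),
             paste0("s", config$s0), paste0("snr", config$snr))
  if (!is.null(config$p_B)) parts <- c(parts, paste0("pB", config$p_B))
  if (!is.null(config$s0_B)) parts <- c(parts, paste0("sB", config$s0_B))
  if (!is.null(config$rho)) parts <- c(parts, paste0("rho", config$rho))
  if (config$c_beta != 1) parts <- c(parts, paste0("cb", config$c_beta))
  paste(parts, collapse = "_")
}

#' Default factorial design grid
#'
#' The factor levels of the main benchmark: `n` in {100, 200, 300}, `p` in
#' {500, 1000, 2000, 4000}, `s0` in {10, 20, 40}, SNR in {0.5, 1, 2, 4}
#' for all design families; block size `p_B` in {10, 100}, within-block
#' correlation `rho` in {0.5, 0.7, 0.9} and signals per block `s0_B` in
#' {1, 2, 5} for the synthetic pairwise design; `p_B = 10` and the same
#' `s0_B` levels for the semisynthetic high-correlation design. SNR 0.5
#' is excluded from the pairwise design, and block combinations must
#' satisfy `s0_B >= s0 / B` with `B = p / p_B`.
#'
#' @return a named list of factor levels consumed by
#'   [enumerate_scenarios()].
#' @export
default_grid <- function() {
  list(n = c(100, 200, 300),
       p = c(500, 1000, 2000, 4000),
       s0 = c(10, 20, 40),
       snr = c(0.5, 1, 2, 4),
       pairwise = list(p_B = c(10, 100), rho = c(0.5, 0.7, 0.9),
                       s0_B = c(1, 2, 5), drop_snr = 0.5),
       semisyn_high = list(p_B = 10, s0_B = c(1, 2, 5)))
}

#' Read a design grid from a YAML or JSON file
#'
#' The file mirrors the structure of [default_grid()]; missing entries
#' fall back to the defaults.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return a grid list as produced by [default_grid()].
#' @export
read_grid <- function(path) {
  spec <- yaml::read_yaml(path)  # yaml::read_yaml also parses JSON
  # YAML 1.1 reads a bare key `n` as the boolean FALSE; map it back
  names(spec)[names(spec) %in% c("FALSE", "F")] <- "n"
  grid <- default_grid()
  for (nm in names(spec)) {
    if (nm %in% c("pairwise", "semisyn_high")) {
      for (sub in names(spec[[nm]])) grid[[nm]][[sub]] <- spec[[nm]][[sub]]
    } else grid[[nm]] <- spec[[nm]]
  }
  grid
}

#' Enumerate the full scenario grid
#'
#' Expands the factorial design into one row per scenario, applying the
#' inclusion rules: the pairwise design drops its excluded SNR level;
#' block combinations are kept only when `s0_B` divides `s0` and
#' `s0_B >= s0 / B` (enough blocks for all signals); the semisynthetic
#' high design uses block size 10 only; the independence and
#' semisynthetic low designs carry no block factors. The default grid
#' yields 2394 scenarios (144 independence + 144 semisynthetic low +
#' 432 semisynthetic high + 1674 pairwise).
#'
#' @param grid a grid list, see [default_grid()] and [read_grid()].
#' @param designs which design families to enumerate.
#' @return a [tibble::tibble()] with one row per scenario; block columns
#'   are `NA` where not applicable.
#' @export
enumerate_scenarios <- function(grid = default_grid(),
                                designs = c("independence", "semisyn_low",
                                            "semisyn_high", "pairwise")) {
  designs <- match.arg(designs, several.ok = TRUE,
                       choices = c("independence", "semisyn_low",
                                   "semisyn_high", "pairwise"))
  base <- expand.grid(n = grid$n, p = grid$p, s0 = grid$s0, snr = grid$snr,
                      KEEP.OUT.ATTRS = FALSE)
  out <- list()
  if ("independence" %in% designs)
    out$independence <- tibble::tibble(design = "independence", base,
                                       p_B = NA_integer_, s0_B = NA_integer_,
                                       rho = NA_real_)
  if ("semisyn_low" %in% designs)
    out$semisyn_low <- tibble::tibble(design = "semisyn_low", base,
                                      p_B = NA_integer_, s0_B = NA_integer_,
                                      rho = NA_real_)
  if ("semisyn_high" %in% designs) {
    sh <- grid$semisyn_high
    blk <- expand.grid(p_B = sh$p_B, s0_B = sh$s0_B, KEEP.OUT.ATTRS = FALSE)
    g <- merge(base, blk)
    g <- g[g$s0 %% g$s0_B == 0 & g$s0_B >= g$s0 / (g$p / g$p_B), ]
    out$semisyn_high <- tibble::tibble(design = "semisyn_high",
                                       g[c("n", "p", "s0", "snr")],
                                       p_B = as.integer(g$p_B),
                                       s0_B = as.integer(g$s0_B),
                                       rho = NA_real_)
  }
  if ("pairwise" %in% designs) {
    pw <- grid$pairwise
    blk <- expand.grid(p_B = pw$p_B, s0_B = pw$s0_B, rho = pw$rho,
                       KEEP.OUT.ATTRS = FALSE)
    g <- merge(base, blk)
    if (!is.null(pw$drop_snr)) g <- g[!g$snr %in% pw$drop_snr, ]
    g <- g[g$p %% g$p_B == 0, ]
    g <- g[g$s0 %% g$s0_B == 0 & g$s0_B >= g$s0 / (g$p / g$p_B), ]
    out$pairwise <- tibble::tibble(design = "pairwise",
                                   g[c("n", "p", "s0", "snr")],
                                   p_B = as.integer(g$p_B),
                                   s0_B = as.integer(g$s0_B),
                                   rho = g$rho)
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::distinct(res)
  res <- res[order(res$design, res$p, res$s0, res$n, res$snr), ]
  res$scenario <- vapply(seq_len(nrow(res)), function(i)
    scenario_id(as_scenario_config(res[i, ])), character(1))
  res
}

#' Convert a scenario-table row to a scenario_config
#'
#' @param row a one-row data frame from [enumerate_scenarios()].
#' @param seed seed to attach.
#' @param ... further arguments passed to [scenario_config()]
#'   (e.g. `c_beta`, `n_test`).
#' @return a [scenario_config()].
#' @export
as_scenario_config <- function(row, seed = 1L, ...) {
  stopifnot(nrow(row) == 1)
  scenario_config(design = row$design, n = row$n, p = row$p, s0 = row$s0,
                  snr = row$snr,
                  p_B = if (!is.na(row$p_B)) row$p_B,
                  s0_B = if (!is.na(row$s0_B)) row$s0_B,
                  rho = if (!is.na(row$rho)) row$rho,
                  seed = seed, ...)
}

#' Rescaled sample size
#'
#' The theory-motivated difficulty index `r = n / (s0 * log(p - s0))`
#' (natural logarithm). Large `r` indicates an "easy" scenario: sample
#' size large relative to dimensionality and sparsity.
#'
#' @param n sample size.
#' @param p number of covariates.
#' @param s0 number of active variables; requires `p > s0`.
#' @return the scalar `r` (vectorized over inputs).
#' @examples
#' rescaled_n(200, 1000, 10)  # ~2.90
#' @export
rescaled_n <- function(n, p, s0) {
  if (any(p <= s0)) stop("rescaled_n requires p > s0")
  n / (s0 * log(p - s0))
}
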