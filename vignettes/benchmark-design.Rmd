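---
title: "Benchmarking penalized regression: models, designs and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking penalized regression: models, designs and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdbench)
```

## The problem

In many biomedical applications — gene-expression studies being the
canonical example — a continuous outcome is regressed on far more
covariates than there are samples. hdbench provides a complete
simulation bench for this setting: it generates data from the sparse
linear model

$$ y = X\beta + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2 I), $$

with $p > n$ and $s_0 = |\{j : \beta_j \neq 0\}|$ small, fits seven
penalized estimators, and scores them on the three tasks practitioners
actually face: *prediction* (root-mean-squared test error),
*variable selection* (TPR and PPV of the selected set against the true
active set) and *variable ranking* (partial AUC of an importance
score). The package reproduces, at configurable scale, a factorial
study of 2394 scenarios crossing sample size, dimension, sparsity,
signal-to-noise ratio and covariate-correlation structure.

## Data-generating designs

All covariates are Gaussian. Four design families are built in:

* **independence** — i.i.d. standard normal covariates;
* **pairwise blocks** — blocks of size $p_B$ with constant within-block
  correlation $\rho$, independent across blocks (shared-factor
  construction $x = \sqrt{\rho}\, z_{block} + \sqrt{1-\rho}\, e$, whose
  population covariance is exactly block-equicorrelated);
* **toeplitz blocks** — within-block correlation $0.95^{|j_1-j_2|}$
  (Cholesky of the AR(1)-type block covariance); the two signals in a
  block sit 7 positions apart, giving them correlation
  $0.95^7 \approx 0.70$;
* **semisynthetic** — covariates subsampled from a pool with realistic
  correlation structure; responses remain simulated. The built-in pool
  generator plants latent-factor clusters inside otherwise weakly
  correlated Gaussian columns, calibrated so the mean absolute pairwise
  correlation is 0.08 (the level observed in the ovarian-cancer
  expression matrix of 594 samples that the semisynthetic designs
  emulate). A real matrix can be substituted from CSV via
  `read_pool()`.

Signals are placed deterministically in the synthetic block designs
(first $s_0/s_0^B$ blocks, first $s_0^B$ positions of each — positions
within an equicorrelated block are exchangeable, so this choice is
statistically irrelevant and keeps datasets reproducible), uniformly
at random in the semisynthetic low-correlation design, and by a greedy
maximum-correlation block construction in the high-correlation design
(sign-agnostic absolute Pearson correlation, ties broken by lowest
column index; the anchor column of each block is always a signal).

Active coefficients are all 3 by default. The heterogeneous variant
gives half the signals $\beta' = \sqrt{18/(1+c_\beta^2)}$ and half
$c_\beta \beta'$, which keeps $\sum_j \beta_j^2 = 9 s_0$ for every
$c_\beta$, so the calibrated noise level is unchanged in expectation.

The noise standard deviation is set per replicate from the realized
training design by inverting
$\mathrm{SNR} = \sqrt{\beta^\top X^\top X \beta / (n\sigma^2)}$, so the
realized SNR identity holds exactly on every dataset. An optional
`noise_fun` hook swaps the Gaussian errors for any other distribution;
only Gaussian errors are exercised by the shipped tests.

The difficulty of a scenario is usefully summarized by the rescaled
sample size $r = n/(s_0 \ln(p - s_0))$ (natural logarithm — the printed
reference values $r = 2.9$ at $(200, 1000, 10)$ and $r = 0.6$ at
$(200, 4000, 40)$ are consistent only with base $e$).

## Estimators

All solvers standardize the covariates (mean 0, $1/n$-variance 1) and
center the response; the elastic-net family also scales the response
to unit variance internally, which makes the fit equivariant to
rescaling of $y$ and matches the convention of standard elastic-net
software — a detail that matters because the quadratic part of the
penalty is not scale-invariant. Coefficients are always returned on
the original scale; `lambda` is reported in original-response units.

* **Elastic net family** (`fit_enet_path`): penalty
  $\lambda(\alpha|\beta_j| + (1-\alpha)\beta_j^2/2)$ with $\alpha = 1$
  (lasso), $0.6$ (light elastic net), $0.3$ (heavy elastic net) and
  $0$ (ridge). We use the standard halved-quadratic parameterization so
  that the mixing weights carry their conventional meaning and fits
  agree with reference software; the package's path-persistence
  ranking results are sensitive to this convention, and the standard
  form is the one that reproduces published reference values. Paths are
  fitted by cyclic coordinate descent with warm starts, sequential
  strong-rule screening and a full KKT check at every grid point (so
  screening never changes the solution). Ridge is solved exactly in
  closed form through the eigendecomposition of $XX^\top$ (dual form
  when $p > n$).
* **SCAD** (`fit_scad_path`): the non-convex quadratic-spline penalty
  with shape $a = 3.7$; coordinate descent applies the exact univariate
  SCAD thresholding operator. The reported path is the local solution
  reached from the warm-started largest-$\lambda$ end — the standard
  convention for non-convex path solvers — and is deterministic given
  data and grid.
* **Adaptive lasso** (`fit_adaptive_lasso`): weights
  $w_j = 1/|\tilde\beta_j|^\gamma$ with $\gamma = 1$ from a
  cross-validated ridge initial estimate, implemented as per-variable
  penalty factors in the same coordinate-descent core (algebraically
  identical to rescaling columns). A zero initial estimate yields an
  infinite weight and the variable is excluded at every $\lambda$; an
  `zero_eps` floor is available instead. Weights are computed once on
  the full training data and held fixed while $\lambda$ is
  cross-validated.
* **Dantzig selector** (`fit_dantzig`): minimizes $\|\beta\|_1$ subject
  to $\|X^\top(y - X\beta)\|_\infty \le \lambda$, solved as a linear
  program in the split $\beta = \beta^+ - \beta^-$ ($2p$ variables,
  $2p$ constraint rows). The constraint uses the raw correlation scale
  (no $1/n$), and Dantzig grids are built on the $\|X^\top y\|_\infty$
  scale accordingly.
* **Stability selection** (`stability_path`): $M = 100$ subsamples of
  size $\lfloor 0.632\, n\rfloor$ drawn without replacement (plain
  subsampling, not complementary pairs), lasso as the base learner on a
  common grid, selection frequencies $\hat\Pi_{\lambda j}$ thresholded
  at $\pi_{thr} = 0.6$. By default no explicit false-positive control
  is applied (the full grid is used); supplying a bound $\tilde V$ on
  the expected number of false positives restricts the grid top-down to
  the prefix whose running average selected-set size $q$ satisfies
  $q \le \sqrt{\tilde V (2\pi_{thr} - 1) p}$, the standard
  stability-selection error bound. The running $q$ is the cumulative
  maximum of the per-$\lambda$ average selected-set size across
  subsamples — exposed as `q_avg` so the bound can be audited.

### Tuning parameters

$\lambda$ is chosen by ten-fold cross-validation minimizing the mean
held-out squared error, with the final fit on the full data at the
common grid. The minimizing rule (rather than the one-standard-error
rule) is the default because the characteristic over-selection of
CV-tuned lasso-type methods — visible in this bench's own selection
results — is a property of the minimizing rule; `rule = "1se"` is
available. Grids are geometric with 100 points from
$\lambda_{\max} = \max_j |x_j^\top y| / (n \max(\alpha, 0.001) w_j)$
down to $0.01\,\lambda_{\max}$ (ridge uses a deeper $10^{-5}$ ratio
since its penalty scale enters through the $\alpha$ floor; its CV
optimum is interior either way). Coordinate descent converges when the
largest absolute coefficient change in a sweep falls below $10^{-7}$
(standardized units) within a budget of 5000 sweeps per grid point;
non-convergence is reported per $\lambda$ and never fatal.

## Metrics

* **RMSE** $\|y_{test} - \hat y\|_2 / \sqrt{n_{test}}$ on an
  independent test set (500 fresh rows for synthetic designs; all
  held-out pool rows for semisynthetic ones).
* **TPR / PPV** of the selected set at the CV-chosen $\lambda$
  (exact zeros define exclusion). The PPV of an empty selection is
  undefined: it is recorded as missing, excluded from averages, and
  counted — not imputed.
* **Partial AUC**: sparse path methods are ranked by the
  path-persistence score $s_j$ — the largest grid $\lambda$ up to which
  variable $j$ stays continuously in the active set from
  $\lambda_{\min}$ (0 if absent at $\lambda_{\min}$); ridge is ranked
  by $|\hat\beta_{cv,j}|$ and stability selection by
  $\max_\lambda \hat\Pi_{\lambda j}$. The ROC curve is built by
  descending score with tie blocks traversed as single diagonal
  segments (threshold averaging — important because path scores contain
  many exact zeros), integrated over the false-positive window
  $[0, 50/(p - s_0)]$ with linear interpolation at the right boundary,
  and normalized by the window width to lie in $[0, 1]$. The
  normalization is required for consistency with published reference
  values (e.g. a pAUC of 0.42 at $p = 4000$ exceeds the raw window area
  $50/3960 \approx 0.013$ by far).

## The runner

`run_scenario()` realizes the per-replicate protocol: one dataset per
replicate (all methods see the same data), CV fits for prediction and
selection, full paths for ranking, stability selection where
applicable. Applicability rules are encoded in `applicable()`: the
Dantzig selector runs only on the independence design and correlated
synthetic designs with $p \le 1000$ (its LP is orders of magnitude
slower than coordinate descent under multicollinearity at large $p$);
the adaptive lasso is not run on the synthetic correlated designs;
stability selection yields no predictor and ridge no selection.
Semisynthetic selection applies $\tilde V = 10$ to stability selection;
the synthetic main grid applies no explicit control.

Seeding is counter-based: a root seed and the scenario identifier and
replicate number hash to a child seed below $2^{31}$, so any replicate
is reproducible in isolation and designs contrasted against each other
(independence baselines, toeplitz vs pairwise) share replicate seeds —
common random numbers sharpen scaled-down comparisons. Reruns of a
plan are bit-identical; solver failures yield flagged missing records,
never a crashed grid.

Default replicate counts mirror the reference study (64 for the main
grid, 100 for the stability-selection tuning sweep, 50 for the
heterogeneous-coefficient experiment); every preset exposes the count
for desk-scale runs.

## Problem sizes used by the shipped checks

The full factorial study (2394 scenarios × 64 replicates × 8 methods)
is a cluster-scale computation and is not run by the package's tests.
The test suite and the acceptance script rerun the pivotal slices at
reduced but statistically meaningful scale, chosen as the package's own
desk-scale defaults:

* ranking in the single-block pairwise design
  ($n = 200$, $p = 4000$, $s_0 = 40$, SNR 1, $\rho = 0.9$): 32
  replicates in the acceptance script, 12 in the test suite;
* the heavy-elastic-net TPR gain between matched pairwise and
  independence designs: 32 / 10 matched-seed replicates;
* the heterogeneous-coefficient floor at $c_\beta = 0.1$: 25 / 6
  replicates;
* the PPV-spread check runs a 6-scenario slice of the independence
  SNR = 2 family ($n \in \{100, 200, 300\}$ crossed with
  $(p, s_0) \in \{(500, 10), (1000, 20)\}$, spanning easy to moderate
  difficulty) at 3 replicates with the five selection-capable
  methods (the median over scenarios is insensitive to the replicate
  count at this slice's effect size).

## What the synthetic data do and do not show

The generators emulate the study conditions exactly: Gaussian
covariates with block or factor correlation, exact-sparse coefficient
vectors, SNR-calibrated Gaussian noise. Real expression data differ in
ways the pool generator does not model — non-Gaussian marginals,
heavy-tailed technical noise, correlation that decays smoothly rather
than in blocks, and batch structure. Passing benchmarks here therefore
demonstrates correctness of the estimators and fidelity to the study
design, and supports relative method comparisons under the modeled
covariance structures; it does not by itself guarantee the same
orderings on any particular real dataset. The semisynthetic designs
with a user-supplied real pool (`read_pool()`) are the bridge for that
question.

## Numerical choices and degenerate inputs

Zero-variance columns are rejected at standardization. A response that
is exactly constant yields the zero coefficient path. In the adaptive
lasso, all-zero initial estimates are an error (nothing to weight).
Empty stable sets and empty CV selections are legal outcomes and flow
through the metrics as TPR 0 / PPV missing. The strong-rule screen is
always verified by a full KKT pass, so it is an accelerator, not an
approximation; SCAD's screen reuses the lasso rule as a heuristic and
relies on the same KKT pass for correctness of the fixed point. LP
failures in the Dantzig selector raise an error that the runner
converts into flagged missing records.

## Known limitations

* SCAD solutions are local minima by nature of the penalty; a
  different grid or warm-start route can reach a different local
  solution. The shipped convention (descending grid, warm starts) is
  deterministic and matches standard non-convex path solvers.
* The Dantzig LP uses a dense simplex backend and is practical only
  for moderate $p$; the applicability rules in the runner encode this.
* Generalized linear models, group/fused penalties and
  estimation-stability CV are out of scope.
* The semisynthetic pool generator reproduces summary correlation
  structure, not expression-specific distributions.
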