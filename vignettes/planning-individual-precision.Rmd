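---
title: "Planning sample size for precise individual risk predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning sample size for precise individual risk predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmprecision)
```

## The model and its assumptions

`pmprecision` answers a design-stage question: if we fit a logistic
regression prediction model to $n$ participants drawn from a given
population, how precise will the *individual* risk estimates be? Everything
rests on three ingredients the user must assume before data exist:

1. **A core predictor set** — the variables that will certainly be in the
   model (plus any attributes, like ethnicity or sex, needed for fairness
   checks even if not predictors).
2. **A case-mix** — the joint distribution of those predictors in the target
   population, either observed (an existing dataset) or declared (a
   `predictor_spec()` of categorical cell probabilities and/or continuous
   moments with correlations).
3. **A core model** — the assumed truth
   $\mathrm{logit}(p_i) = \alpha + \delta(\beta_1 x_{1i} + \dots + \beta_P x_{Pi})$
   mapping predictor values to risk.

Under standard maximum-likelihood asymptotics the covariance of the fitted
coefficients factorises as $\mathrm{var}(\hat\beta) = n^{-1}\mathbf I^{-1}$
with unit information $\mathbf I = E[p(1-p)\,x'x]$, so the anticipated
variance of a new individual's estimated logit risk is
$n^{-1} x_{new} \mathbf I^{-1} x_{new}'$. All outputs — Wald uncertainty
intervals on the risk scale, misclassification probabilities at clinical
thresholds, mean absolute prediction error (MAPE), and required sample sizes
for target widths — are deterministic functions of that variance.

The assumptions to keep in view: the asymptotic (Wald) approximation is used
at the *planned* $n$, which can be optimistic for very small $n$ or very
sparse cells (the repeated-refit test below quantifies this at $n$ of a few
hundred); the core model is taken as the truth, so results are conditional
on it — sensitivity analysis over plausible coefficients and C-statistics is
part of sensible use; and estimation is unpenalised logistic regression
(no shrinkage, no sandwich variances, no survival outcomes).

## The case-mix generator

`sample_cohort()` draws synthetic cohorts from a declared joint
distribution. Categorical predictors (pre-encoded as numeric design columns)
are sampled from their cell table; continuous blocks come from a
multivariate normal with the declared means, SDs and correlation matrix
(a Gaussian-copula-style construction: draw correlated standard normals,
rescale to the marginal moments). When both blocks are present they are
sampled **independently** — published summaries essentially never provide
the cross-block dependence, and declaring independence explicitly is better
than inventing a joint law. The generator's default cohort size is 10,000:
large enough that sampling noise in the entries of $\mathbf I$ is a
second-order contribution to two-decimal summaries, small enough to be
instant.

What the generator does *not* emulate: measurement error, missingness,
model-form misspecification, outcome labels of any kind (none are needed),
or dependence learned from real records. Passing tests therefore certify the
mathematics of the precision machinery under a known truth, not the
real-world adequacy of any particular core model.

Two case-mix modes feed `unit_information()`. The default averages
$p(1-p)x'x$ over the rows of a (real or simulated) table. When the case-mix
is a finite cell table, passing the cell probabilities as `weights` computes
the expectation exactly; this removes simulation noise from deterministic
targets and is what the worked-example tests use. Both routes agree within
binomial sampling error (tested at $10^4$ rows within 4 SEs).

## Calibrating a core model to a prevalence and C-statistic

When only *relative* predictor weights are defensible, `calibrate_core_model()`
finds $(\alpha, \delta)$ so the implied model attains a target overall risk
$\varphi$ and C-statistic $C$ over the case-mix. Two monotonicities make
this a nested one-dimensional search: mean risk is strictly increasing in
$\alpha$ at fixed $\delta$ (inner root-find via `uniroot`), and the
model-implied concordance is non-decreasing in $\delta \ge 0$ (outer
bisection, bracket grown by doubling). Both are asserted numerically on test
grids.

A deliberate refinement: the C-statistic inside the loop is the *expected*
concordance $\sum_{i\ne j} p_i(1-p_j)[\mathbf 1(lp_i > lp_j) + \tfrac12
\mathbf 1(lp_i = lp_j)] / \sum_{i\ne j} p_i(1-p_j)$ computed in
$O(n\log n)$, not a rank statistic on one simulated outcome vector. This
removes Monte-Carlo noise from the convergence test (tolerance 0.001 on both
targets, 200-iteration cap); a simulation oracle in the test suite confirms
the expected concordance matches the average rank-based AUROC over repeated
outcome draws. Ties in the linear predictor count one half — the standard
AUROC convention, which matters for discrete case-mixes. Calibration is
invariant to rescaling the relative weights ($\delta$ absorbs it), and an
unreachable $C$ (e.g. a near-degenerate predictor) is reported with the last
achieved values rather than looping forever.

## Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `level` | 0.95 | coverage | conventional reporting level; z = 1.96 |
| `thresholds` | none | risk scale | clinical decision threshold(s); drive misclassification probabilities |
| `n_samples` (MAPE) | 1000 | draws/individual | MAPE Monte-Carlo error ≈ 0.3% of the value at 1000 draws |
| `increment` (width→variance) | 0.0005 | logit-variance | grid resolution of the target-variance solver |
| `tolerance` (calibration) | 0.001 | probability / C units | convergence margin on prevalence and C |
| `n_default` (generator) | 10,000 | individuals | simulation noise in I negligible at reporting precision |
| shrinkage S | 0.9 | calibration slope | established overfitting target in the minimum criteria |

## Numerical choices and degenerate inputs

* **Quadratic forms** $x\mathbf I^{-1}x'$ use one Cholesky factorisation of
  $\mathbf I$ and triangular solves per batch of rows; $\mathbf I^{-1}$ is
  only formed when exported via `vcov_beta()`. Singularity is decided by an
  eigenvalue ratio ($\lambda_{\min} \le 10^{-10}\lambda_{\max}$) and the
  error names the columns loading on the null direction; a condition number
  above $10^{10}$ attaches a collinearity warning at construction.
* **Width→variance** exploits strict monotonicity of interval width in the
  variance: the grid mode returns the largest multiple of `increment` whose
  width is within target (so it never overshoots, and the resulting $n$ is
  conservative); a bisection mode refines continuously, and targets narrower
  than the first grid point fall back to sub-increment bisection with a
  message.
* **Banded targets** assign each individual the representative risk nearest
  their own, ties broken toward the *lower* band — the conservative side for
  risks below 0.5, where the same width implies a smaller logit-variance.
  The default ladder is 0.01, 0.025, 0.05, then 0.05 steps from 0.10 to
  0.95.
* **Misclassification** uses the closed normal-tail form on the logit scale
  (exactly 0.5 at the threshold, 0 for a point mass on the correct side);
  Monte-Carlo agreement is property-tested rather than shipped as the
  default path.
* **MAPE** derives a per-row seed from the global seed and the row's
  position, so one row's draws never contaminate another's; a zero variance
  returns exactly 0.
* **Degenerate risks** 0 and 1 are rejected (infinite logit); zero-SD
  columns cannot be standardized; empty tables, sub-2-row concordance and
  empty scopes raise argument errors; published cell percentages that sum
  to ≈100% but not exactly (rounding) must be renormalized *explicitly*
  (`normalize = TRUE`) so the user acknowledges the adjustment.
* **Rounding of sample sizes**: each minimum criterion is rounded up before
  taking the maximum; events are $\lceil n\varphi \rceil$. Criterion (iii)'s
  shrinkage is floored at 0.9 so it can never be looser than criterion (ii).

## Open design decisions, and how they were resolved

* *Expected frequencies vs re-drawing for a finite cell table*: both are
  supported (`weights` vs a sampled cohort). The worked-example tests use
  exact weights for determinism; the end-to-end script samples 10,000
  individuals, mirroring ordinary use.
* *C→$R^2_{CS}$ conversion*: the binormal simulation (events' linear
  predictor shifted by $\sqrt2\,\Phi^{-1}(C)$, univariable refit, $1 -
  e^{-LR/N}$) at $N = 10^6$ is stable to about ±0.001 across seeds. The
  minimum sample sizes inherit that jitter — a few participants either way
  for typical inputs — which is why C-driven minima are reported as
  Monte-Carlo quantities while the criterion-(i) closed form is exact.
* *Smoothed envelopes* for prediction-instability plots use `lowess` with a
  fixed bandwidth fraction 0.3 through the (risk, bound) pairs. They are
  purely presentational; every plotted series is also written as a table and
  no reported statistic depends on the smoother.
* *Mixed categorical+continuous case-mixes* are independent across blocks
  unless the user supplies cell-conditional moments themselves (by building
  separate specs per cell and binding cohorts).

## Problem sizes used in the shipped checks

The test-suite defaults were chosen as the smallest sizes at which each
statistical check is decisive: synthetic cohorts of $10^3$–$10^4$ rows
($10^5$ for moment-matching of the generator), 400–500 repeated ML refits
when verifying the closed-form variance against the empirical covariance of
refitted coefficients (agreement within 10% of the empirical SD at $n$ = 200
and 1000), $2\times10^5$ draws for Monte-Carlo comparisons (3-SE
agreement), and $2\times10^5$ simulated subjects for quick C→$R^2$
stability checks; the end-to-end script uses the full $10^6$.

## Known limitations

* Wald intervals on the logit scale can undercover for extremely sparse
  cells at small $n$; the framework flags exactly those cells as unstable,
  which is the conservative direction for planning.
* The expected concordance treats the case-mix table as the population; for
  small observed tables the implied C carries that table's noise.
* The minimum-criteria module restates the established published formulas so
  the comparison floor is self-contained; users wanting the reference
  implementation's exact Monte-Carlo seed behaviour for the C conversion
  will see ±1% differences in criterion-(ii)/(iii) sizes.
* No support for penalised fits, survival outcomes, net-benefit or
  calibration-slope instability, or learning a joint predictor distribution
  from real records.
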