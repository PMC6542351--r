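---
title: "Estimating national key population sizes from incomplete municipal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating national key population sizes from incomplete municipal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

National HIV programs need estimates of the sizes of key populations —
female sex workers (FSW), men who have sex with men (MSM), transgender
women (TGW) — but direct municipal size estimates are expensive and are
usually collected only where programs already expect high burden, plus
perhaps a small random sample of other municipalities.  kpsize treats the
municipalities without direct estimates as a missing-data problem.

Write $Y_i$ for the key population count in municipality $i = 1, \dots,
k$, $N_i$ for the population that could belong to it (e.g. women aged
15–49 for FSW), $S_i$ for the indicator that a direct estimate exists,
and $Z_i$ for contextual covariates known everywhere (population density,
poverty, tourism, HIV prevalence, …).  The estimand is the national
proportion

$$\pi = \frac{\sum_i Y_i}{\sum_i N_i}.$$

All estimators in the package are built on intercept-only Poisson
regression with offset $\log N_i$, whose MLE is exactly a (weighted)
count ratio; covariate-conditional models add spline-expanded $Z$ terms.

## Assumptions

* **Exchangeability.** The crude complete-case estimator
  $\sum_{S=1} Y_i / \sum_{S=1} N_i$ is consistent only if sampled and
  unsampled municipalities have the same expected proportion.  Purposive
  sampling makes this implausible; the package therefore relaxes it to
  *conditional* exchangeability given $Z$.
* **Positivity.** Conditional exchangeability only helps if every
  covariate stratum containing municipalities had a positive chance of
  being sampled.  `positivity_table()` cross-classifies municipalities
  (by default tertiles of the first two continuous covariates, the
  density-by-poverty stratification that matters in practice) and lists
  strata with zero sampled municipalities; `balance_table()` reports
  standardized differences between sampled and all municipalities.
* **Known counts.** Direct estimates are taken as known quantities; no
  uncertainty is propagated from the municipal estimation itself, so all
  intervals are conditional on the direct estimates.  Counts may be
  non-integer (they are themselves estimates); every model is fit by
  quasi-likelihood, which only uses the mean structure.

## The four estimators

* **Complete case** (`estimate_complete_case`): the crude ratio over
  sampled municipalities, with a robust sandwich SE of $\log\hat\pi$ and
  a Wald CI exponentiated from the log scale.  The CI method is chosen
  for symmetry with IPSW.
* **IPSW** (`estimate_ipsw`): a logistic model of $S$ on spline-expanded
  $Z$ over all municipalities gives fitted sampling probabilities
  $\hat p_i$; sampled municipalities are weighted by $W_i = 1/\hat p_i$
  in the intercept-only Poisson model, so
  $\hat\pi = \sum_{S=1} W_i Y_i / \sum_{S=1} W_i N_i$.  The sandwich SE
  treats the weights as known.
* **Multiple imputation** (`estimate_mi`): a Poisson outcome model of
  $Y$ on spline-expanded $Z$ (offset $\log N$) is fit to the sampled
  municipalities; coefficient draws $\beta^{(m)} \sim
  MVN(\hat\beta, \hat\Sigma)$ from the approximate posterior and Poisson
  draws $Y_i^{(m)} \sim \text{Pois}(N_i e^{Z_i\beta^{(m)}})$ complete the
  unsampled rows (*proper* imputation — parameter and count noise are
  both propagated, which Rubin's rules require).  Each completed country
  is analysed with the intercept-only model; the log proportions are
  pooled by Rubin's rules $T = \bar W + (1 + 1/M)B$ with a t CI at
  $\nu = (M-1)(1 + \bar W/((1+1/M)B))^2$ degrees of freedom.  The
  analysis model is unweighted: imputation already adjusts for
  selection, weighting would double-correct.
* **Augmented IPSW** (`estimate_aipw`): the "regression" augmented
  estimator — fit the sampling model, fit the *IPSW-weighted* outcome
  model on sampled rows, predict $\hat Y_i$ for every municipality, and
  take $\hat\pi = \sum_i \hat Y_i / \sum_i N_i$.  Because the weighted
  fit solves $\sum_{S=1} W_i (Y_i - \hat Y_i) = 0$, the estimator is
  consistent when either model (sampling or outcome) is correctly
  specified: double robustness.  The SE is the SD of $\log\hat\pi$ over
  $B$ nonparametric bootstrap resamples of the municipalities (default
  $B = 1000$), the inferential units, preserving each row's $S$; the CI
  is built on the log scale and exponentiated to keep it positive, the
  same convention used everywhere else in the package.

Predicted counts are truncated at $N_i$ before averaging — a count
cannot exceed the population at risk.  With only ~50 sampled
municipalities, rare bootstrap resamples can otherwise push an
exponential-link extrapolation to absurd values; the truncation is a
feasibility bound, not a tuning knob.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_knots` | 3 | restricted quadratic spline knots per continuous covariate, at the 5th/50th/95th percentiles |
| `min_distinct` | 25 | continuous covariates with fewer distinct values fall back to a linear term (small-sample stability) |
| `M` | 50 | imputations (20 inside simulations) |
| `B` | 1000 | bootstrap resamples (200 inside simulations) |
| `truncate_at` | off | optional weight truncation percentile; off because untruncated weights are the reference analysis |

Restricted quadratic splines are zero below the first knot, smooth
(continuous first derivative), and *linear* beyond the last knot, so
fitted sampling probabilities and rates cannot explode in the covariate
tails; the $(t_K - t_1)$ normalization keeps basis columns on the scale
of $x$, which conditions the GLM better and is inferentially neutral
(a full-rank linear reparameterization).

## Cluster-indicator covariates

Survey indicators measured at geolocated clusters (e.g. DHS HIV
prevalence) are converted to municipality covariates by piecewise-linear
barycentric interpolation over a Delaunay triangulation of the cluster
locations, evaluated at the centers of a fine grid (default 100 × 100
over the bounding box), restricted to the convex hull of the clusters,
and averaged over the cells of each municipality.  Linear interpolation
is deterministic, convexity-preserving (never overshoots the observed
values), and exact on linear surfaces — which is exactly what the test
suite checks.  Cell membership uses cell centers, not area weights, and
coordinates are treated as planar (adequate at the spatial extent of a
country like the DR).  A municipality whose cells all fall outside the
hull receives the nearest valued cell's value and an explicit `imputed`
flag, because covariates must be complete downstream; ties in the
nearest-cell distance break by cell enumeration order.

## What the synthetic generator emulates

`scenario()` / `generate_country()` build DR-like countries: 154
municipalities in 31 provinces; log population density normal; poverty
and HIV prevalence beta; tourism Bernoulli with density-linked
probability; denominators rounded lognormals scaled to density (median
~8,000, national total ~2 million).  True municipal rates follow
$\log \pi_i = \beta_0 + \beta' \tilde Z_i$ with standardized covariates;
the default loadings make the key population *rarer* in dense municipalities
and more common in poor ones, while sampling prefers dense, touristic,
less poor municipalities.  That configuration reproduces the phenomenon
that motivates the whole design: the crude complete-case estimate
understates the national FSW-like proportion by roughly 25–30%, because
program-driven site selection targets urban areas where the *proportion*
(not the count) is low.

Two selection mechanisms are provided:

* `"two_stage"` (default, used by `dr_like_fixture()`): the 30
  highest-scoring municipalities on a perceived-risk index
  $\alpha'\tilde Z + \text{Gumbel noise}$ are sampled purposively, then
  20 more uniformly at random.  Under noisy top-$n$ selection no
  logistic model is exactly correct — a realistic stress test.
* `"logistic"`: a single Bernoulli stage with
  $P(S=1|Z) = \text{expit}(\alpha_0 + \alpha'\tilde Z)$, the intercept
  solved so the expected sample size is 50.  Here the fitted logistic
  sampling model is exactly correctly specified, which is what the
  "sampling model correct" cells of the simulation study require; the
  simulation and acceptance runs use this switch.

The outcome intercept $\beta_0$ is solved once, at scenario
construction, from a 500,000-draw Monte Carlo over the covariate
superpopulation, so that the superpopulation proportion equals the
target (FSW-like 0.037, MSM-like 0.012, TGW-like 0.0019).  Every
replicate country then shares one fixed data-generating law whose
national proportion `pi_star` is the scoring target of the simulation
study.  This matters for coverage: the sandwich, Rubin, and
iid-municipality bootstrap variances all estimate superpopulation
uncertainty.  Scored against each replicate's *realized* $\sum Y/\sum N$
(which co-moves with the estimator), those intervals would appear to
cover essentially always; against the superpopulation proportion they
attain near-nominal coverage, which is the meaningful calibration
statement.  The realized proportion is still carried per replicate
(attribute `pi_true`, summary column `mean_realized_pi`).

Counts are Poisson around $N_i \pi_i$ (a binomial switch exists), so
the outcome model in the analysis is exactly correctly specified when it
includes all four covariates.  Real municipal counts are almost
certainly overdispersed relative to this; passing simulations therefore
demonstrate correctness of the estimators under their stated
assumptions, not robustness to unmodeled heterogeneity, measurement
error in the direct estimates, or within-municipality survey error,
none of which the generator emulates.

## The simulation study

`run_scenario()` generates independent replicate countries from
substreams of one master seed and summarizes per-method bias, relative
bias, RMSE, empirical SE, coverage, and CI width against `pi_star`;
failures are counted, never silently averaged over, and a method failing
in more than 10% of replicates is flagged invalid.
`double_robustness_suite()` runs the 2 × 2 cross of
{sampling model correct/incorrect} × {outcome model correct/incorrect},
where "incorrect" omits the scenario's key covariate (population
density, the dominant driver of both selection and the outcome) from the
corresponding analysis model.  A `wrong_functional_form` switch instead
replaces the key covariate by its above-median indicator in the sampling
model.

Design choices made for desk-scale runtime, stated as the package's own
defaults: 500 replicates per cell, $M = 20$, $B = 200$, and AIPW
bootstrap CIs computed only in the both-correct cell (where coverage is
assessed; elsewhere only the point estimate enters the bias contrasts).
At these sizes the Monte-Carlo SE of a relative-bias estimate is about
0.4%, small against the 10% decision threshold.  Within the simulation
both analysis models use the package's spline-expanded default — the
flexible specification a practitioner would fit, and the reason the
augmented estimator's interval is genuinely wider than MI's (its
weighted outcome fit carries extrapolation variance that MI's unweighted
fit does not).

## Numerical choices

* IRLS via `stats::glm.fit` on pre-built model matrices, deviance
  tolerance $10^{-12}$, 100-iteration cap; quasipoisson/binomial
  families (identical iterations, no integer-count warnings).
* Rank deficiency errors with the dropped columns named; no silent
  column dropping.
* Separation in the sampling model errors loudly (penalization would
  change the estimand): triggered by non-convergence, by a fitted
  probability below $10^{-6}$ at a *sampled* municipality (its weight
  would be unbounded), or by fitted probabilities that strictly separate
  sampled from unsampled municipalities.  A numerically-zero fitted
  probability at an unsampled extreme-covariate municipality carries no
  weight and is not an error.
* A non-positive-semidefinite posterior covariance (numerically
  possible) is repaired by clipping negative eigenvalues at zero, with a
  warning.
* Bootstrap replicates that fail (no sampled rows, separation,
  non-convergence) are discarded and counted; more than 10% discarded is
  an error.
* One user seed spawns independent substreams for imputation draws,
  bootstrap resamples, and simulation replicates, so changing $M$ or $B$
  never correlates streams.

## Known limitations

* No propagation of uncertainty in the direct estimates themselves
  (intervals are accordingly too narrow to that extent).
* No municipality-level small-area estimates — the national proportion
  is the only estimand.
* Planar geometry; no kriging or geostatistical modelling of the
  cluster indicators.
* Sandwich variances treat estimated weights as known.
* The two-stage purposive mechanism is only approximately compatible
  with the logistic sampling model; `selection = "logistic"` exists
  precisely to separate that approximation error from estimator
  properties.
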