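---
title: "Probabilistic multiplier models and model averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic multiplier models and model averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevmult)
```

## The estimation problem

Hidden populations — here, individuals with opioid use disorder (OUD) in a
metropolitan region — cannot be counted directly: surveys under-reach them
and direct enumeration is infeasible. The benchmark–multiplier method infers
their number `C` from an observable endpoint count `A` and a multiplier `B`,
the annual proportion of the hidden population experiencing that endpoint:

$$C = A / B.$$

A region typically offers several candidate benchmarks (overdose deaths,
treatment admissions, emergency department overdose visits), each with its
own multiplier drawn from the literature. Any single model may be biased or
wildly imprecise; `prevmult` therefore treats the multiplier as uncertain
(first-order, parameter uncertainty) and the choice of benchmark as
uncertain (second-order, structural uncertainty), and reports a
model-averaged distribution.

## The multiplier distribution

A pooled multiplier arrives as a mean `m` and standard error `s` on the
proportion scale. Since `B` is a proportion, its sampling distribution is
modelled as beta, fitted by the method of moments:

$$\nu = \frac{m(1-m)}{s^2} - 1, \qquad \alpha = m\nu, \qquad \beta = (1-m)\nu,$$

which reproduces `(m, s)` exactly (asserted in the tests at `1e-10` relative
error). The fit requires `s^2 < m(1-m)`; infeasible moments are rejected
with an explicit error. `s = 0` is supported as a degenerate point mass so
deterministic limits are expressible.

```{r fit}
fit_beta_moments(cincinnati_models())[, c("label", "alpha", "beta")]
```

Because `C = A/B`, the closed-form moments of `1/B`,

$$E[1/B] = \frac{\alpha+\beta-1}{\alpha-1}, \qquad
  E[1/B^2] = \frac{(\alpha+\beta-1)(\alpha+\beta-2)}{(\alpha-1)(\alpha-2)},$$

give analytic oracles for every Monte Carlo summary (defined for `alpha > 1`
and `alpha > 2` respectively; the package returns `NA` with a warning
otherwise — all realistic multiplier fits here have `alpha` in the tens to
hundreds). The test suite checks these against direct numerical integration
of the beta density, and every simulation against them.

## Simulation and coupling

`simulate_models()` draws, per model, `n_iter` uniforms `u_i` from a
dedicated stream and sets `C_i = A/\mathrm{qbeta}(u_i, \alpha, \beta)`. Two
deliberate choices:

* **Inverse-CDF sampling, not `rbeta()`.** Exposing the uniforms lets the
  averaging step impose common random numbers across models.
* **Per-label streams.** Each model's stream seed derives from the master
  seed and the model's label (a small polynomial hash mod $2^{31}-1$), so
  adding or removing a model never perturbs the others' draws — asserted in
  the tests by comparing a model simulated alone with the same model inside
  the full table.

Draws stay at full floating precision; rounding to whole persons happens
only at presentation time.

## Model averaging

The three coupling schemes in `average_models()` express different stances
on structural uncertainty:

* **Comonotonic** (default): every model is evaluated at the same uniform
  quantile per iteration and the draws are averaged. Implemented as the
  monotone rearrangement — per-model draws are sorted, averaged element-wise
  as order statistics, and re-ordered by a common uniform stream. This makes
  percentile additivity (each percentile of the average equals the mean of
  the models' percentiles) exact by construction, and SD additivity (SD of
  the average equals the mean of per-model SDs) holds up to the sampling
  correlation of finite sorted vectors — measured at well under 0.5% at
  10 000 iterations, which is the tolerance the tests assert. This scheme is
  the package default because the averaged spread then *preserves* the
  models' average uncertainty instead of shrinking it by ~√3, an
  appropriately conservative statement when the models share an unknown
  common structure.
* **Independent**: models keep independent streams; draws are averaged per
  iteration. The averaged SD is provably no larger than the comonotonic one
  (tested), and close to mean SD/√3 when models are comparably precise.
* **Model selection**: each iteration picks one model uniformly at random —
  a mixture rather than an average. Its mean matches the grand mean, and its
  SD exceeds the comonotonic SD whenever between-model spread is large
  (tested on the packaged configuration).

The reported interval is the **mean ± 1 SE** of the averaged draws — a ±1 SD
band, not a 95% interval; its nominal coverage under normality would be
about 68%.

## Pooling study-level multipliers

`pool_estimates()` combines study proportions with patient-count weights,
$m = \sum n_i p_i / \sum n_i$. The SE of a pooled literature multiplier is
ambiguous, so both are implemented:

* `between_study_weighted` (default):
  $\sqrt{\sum n_i (p_i - m)^2 / \sum n_i} / \sqrt{k}$ — between-study
  heterogeneity scaled by the number of studies. This is the default because
  binomial SEs on pooled patient totals in the tens of thousands are an
  order of magnitude smaller than the multiplier SEs actually reported in
  this literature; heterogeneity dominates.
* `binomial`: $\sqrt{m(1-m)/\sum n_i}$, the homogeneous-sample lower bound.

Formal meta-analysis machinery (random-effects $\tau^2$, $I^2$) is out of
scope; the pooled mean and a defensible SE are all the pipeline consumes.

## The packaged Cincinnati configuration

The shipped `cincinnati.yaml` encodes the 2017 analysis of the 14-county
Cincinnati CBSA: population 2 165 139; endpoints 996 fatal overdoses, 2752
treatment admissions (2016 treatment data used unadjusted in a 2017
estimate, a deliberate data-availability compromise carried in the config's
`data_year` field), and 7342 non-fatal ED overdose visits; multipliers
7.182% (SE 0.533%), 21.376% (SE 2.142%), 40.890% (SE 5.111%).

The ED endpoint deserves a note: raw ED visit counts include repeat visits
by the same person, and an endpoint must count persons. The package applies
a fixed repeat-visit deflation, `round(raw * (1 - fraction))` with halves
away from zero, to any model flagged `adjust_repeat_visits`; the packaged
config documents the 35% repeat fraction but flags no model, because 7342
is already a deduplicated person count (a raw count near 11 295 deflates to
it).

```{r run}
report <- run_pipeline(cincinnati_config())
tidy(report)
glance(report)[, c("mean", "se", "count_low", "count_high", "pct_low", "pct_high")]
```

## What the synthetic generator emulates — and what it does not

`generate_region()` plants a hidden population of known size in a region and
realises each endpoint binomially: every member experiences endpoint `j`
with probability equal to that endpoint's true multiplier. Binomial (rather
than Poisson) realisation gives the hard upper bound endpoint ≤ hidden
population — endpoints are subsets of the population. `generate_study_set()`
emulates the literature inputs: per-study latent proportions are the truth
plus additive normal heterogeneity (clipped into (0,1) with a warning),
observed binomially at each study's size.

`recovery_experiment()` closes the loop: it treats the stated multiplier SE
as genuine first-order uncertainty, drawing each replicate's generating
multipliers from the beta distribution fitted to (truth, SE), realising
endpoints from them, and running the full pipeline with the modelled
multiplier moments. Under the default scenario (population 2 million, true
hidden count 15 000, multipliers 0.07/0.21/0.41, relative multiplier SE
7.4% — the relative precision of the best-pooled multiplier in the packaged
configuration; 200 replicates of 2000 iterations), the averaged estimate
shows ~0.5% relative bias (Jensen's inequality on `E[1/B]` makes a small
positive bias structural) and the ±1 SE band covers the truth in roughly
86% of replicates — below nominal 95%, as a ±1 SD band must be, and above
68% because comonotonic averaging deliberately over-states the spread of an
average of independently-generated models.

The generator does **not** emulate: correlated endpoints (the same person
dying and entering treatment in one year), temporal drift between data years,
under- or over-reporting of counts, or multiplier non-generalisability from
the literature's populations to the region. Passing recovery tests therefore
show the *pipeline arithmetic* is unbiased and its uncertainty statement
calibrated under the model's own assumptions — not that those assumptions
hold in any real region.

## Numerical and design choices

* Percentiles use linear interpolation between order statistics
  (`quantile(type = 7)`).
* Equal model weights; no data-driven weighting or stacking.
* The Monte Carlo size defaults to 10 000 iterations, which resolves the
  averaged mean to about ±16 persons (SE/√n); the recovery experiment uses
  2000 iterations per replicate since bias and coverage, not single-run
  precision, are its object.
* Master seed → per-label streams; the averaging schemes use streams keyed
  off the averaged label, so per-model draws are untouched by the scheme
  choice.
* Validation is eager and names the offending field (`population`,
  `multiplier_se`, ...) so configuration errors surface before any
  simulation.

## Limitations

The estimate inherits every limitation of its inputs: endpoint counts are
single-year administrative tallies, multipliers are assumed transportable
from published cohorts, and the three models are treated as exchangeable.
The ±1 SE band quantifies parameter and structural spread under those
assumptions, not total error. For regions whose multiplier fits give
`alpha ≤ 2`, the analytic oracle SD is undefined and only simulation-based
summaries are available (the package warns).
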