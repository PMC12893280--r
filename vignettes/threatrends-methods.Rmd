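---
title: "Methods: multi-threat population trend modelling in threatrends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-threat population trend modelling in threatrends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and defaults, what
the synthetic-data generator does and does not emulate, the numerical
choices, and known limitations. Every number quoted here is produced by
the package's tests or by `scripts/acceptance.R`; nothing is asserted that
the code does not compute.

## 1. Data model and inclusion rules

Input data are Living-Planet-style wide tables: one row per population
with metadata (identifiers, coordinates, system, taxon, six 0/1 threat
flags, an optional threat-status flag) and one column per calendar year.
`read_lpd()` parses them into a nested tibble; `filter_series()` applies
the inclusion envelope used throughout: an inclusive calendar span of at
least 10 years, at least 5 data points, and (by default) a known threat
status. "10 years of monitoring" is read as the inclusive span
`last - first + 1` rather than a point count, because the point count is
governed by the separate 5-point rule; both thresholds are exposed as
arguments, which also supports span-sensitivity re-analyses (e.g.
re-running at a 20-year minimum).

`prepare_series()` produces the modelling frame: per series, year is
centred by its mean, abundance is log-transformed and the logs centred by
their mean. This parameterisation pins every series' intercept near zero,
so the model needs no random intercepts — random variation enters through
year slopes only. Two documented switches:

* **Zero abundances.** The log is undefined at zero, and the source data
  convention is silent. Default policy (`zero_policy = "mean_fraction"`):
  add 1% of the series mean abundance to *every* observation of a series
  containing zeros, recording the offset in `offset_applied`. `"add_one"`
  and `"error"` are alternatives. Positive-only series are never offset.
* **Centring order.** Whether abundance was centred before or after the
  log transform is ambiguous; `center = "log_mean"` (default) subtracts
  the mean of the logs, which makes the response exactly mean-zero.
  `center = "abundance_mean"` subtracts the log of the mean abundance
  instead (centring on the abundance scale); it is only approximately
  mean-zero and is provided for sensitivity analysis.

## 2. The threat-combination design

Threat sets of size 1–3 over six categories are encoded as binary
columns. For the observed label set `L`, the design has `2 + 2|L|`
columns: intercept, centred year, and per label an indicator (1 when all
the label's categories are present in the row's threat set) plus its year
interaction. Indicators obey the product rule — an interaction column
always equals the elementwise product of its constituent singles — which
the test suite verifies against a brute-force enumerator over all sets of
four categories. Labels are canonical (tokens sorted alphabetically,
joined by `"."`; label list ordered by interaction order then
alphabetically), fixing the coefficient indexing across runs. The
ASCII suffix `":year"` marks year-interaction columns.

By default only *observed* combinations (plus all sub-combinations of
observed multi-threat sets) get columns, mirroring the 36-column (not the
full 41) global design of the motivating analysis; `observed_only =
FALSE` enumerates all `C(6,1)+C(6,2)+C(6,3) = 41`. Four-way and higher
interactions are out of scope (such exposures are rare in the source
data and `max_threats = 3` is enforced end to end).

Two manipulations drive the downstream inference, and both act jointly on
an indicator *and* its year twin (trends live in the year interactions,
so the pair must move together):

* `switch_interactions(d, combo, "off")` zeroes an interaction column —
  the additive prediction; `"on"` restores the product rule bit-exactly.
* `remove_threat(d, threat)` zeroes every column whose label contains the
  threat, including all interactions containing it — the counterfactual
  semantics. Removals are idempotent and commute.

## 3. Spatial covariance

Site coordinates are rounded to the nearest integer degree (halves away
from zero: 10.65 → 11, 0.5 → 1), pooling nearby sites and bounding the
matrix size. Pairwise Haversine (spherical, radius 6371 km) distances `D`
are mapped to proximities. The description "normalised between 0 and 1
with 1 = neighbouring" admits many transforms; the package default is the
minimal one, `1 - D/max(D)`, with `exp(-D/length_scale)` available as a
pluggable alternative.

`1 - D/max(D)` is not guaranteed positive semidefinite, and how (or
whether) the original analysis enforced validity is unstated, so the
repair here is an engineering choice: negative eigenvalues are clipped to
zero, the matrix is rescaled to unit diagonal, off-diagonals are clamped
to [0, 1], and a nugget (default `1e-6`) is added to the diagonal before
the Cholesky factorisation used by the sampler (with an escalating jitter
fallback). All-coincident sites fall back to an identity-plus-nugget
matrix to avoid a singular all-ones covariance.

## 4. The hierarchical model and its sampler

The likelihood, priors and noncentered parameterisation are given in the
README. Points that needed a decision:

* **AR(1) across gaps.** Lag 1 is defined on *consecutive observations*
  within a series regardless of the calendar gap between them — the
  discrete "ar1" convention for possibly irregular series. This is a
  documented limitation: a 5-year gap carries the same correlation as a
  1-year step. The first observation of each series has no lagged
  residual (its AR term is zero).
* **A single shared ρ.** All series share one residual correlation, as in
  the global analysis; system- or taxon-specific refits (obtained by
  filtering the prepared tibble and refitting, with the proximity matrix
  recomputed automatically for the subset) each estimate their own ρ.
* **Priors.** `rho ~ Normal(0, 0.25)` is read as standard deviation
  0.25 (the convention of the fitting software the analysis used).
  Scales are `Exponential(1)` sampled on the log scale with the Jacobian
  term included.

No MCMC backend exists in the target environment, so `fit_model()` uses
the package's own sampler (`R/hmc.R`): adaptive HMC with dual-averaging
step-size tuning towards 0.8 acceptance, Stan-style warmup phases with a
diagonal mass matrix estimated from warmup draws, trajectory length
`int_time / stepsize` capped at 128 leapfrog steps and jittered over the
upper half of its range to avoid resonance. This is a NUTS-class
gradient-based method without the tree-doubling machinery; its
correctness is established by (i) an analytic-gradient check against
finite differences, (ii) a likelihood oracle (the model's log density at
fixed parameters equals a brute-force per-observation evaluation to
1e-8), (iii) seed-determinism and row-order-invariance properties, and
(iv) parameter recovery: with 120 synthetic series (~25 points each,
σ = 0.3, ρ = 0.3, one interaction effect of −0.08), 2 chains × 1500
iterations recover ≥ 80% of fixed effects inside their 90% intervals and
cover ρ. The full-scale profile is `chains = 4, iter = 5000, warmup =
2500` (the function default); desk-scale work uses 2 × 1500 or smaller.
Post-warmup draw counts are reported as `chains × (iter − warmup)`.

**Centring and AR(1) attenuation.** Per-series mean-centring of the
response absorbs each series' residual mean. For an AR(1) process
observed at T points this attenuates the fitted correlation by roughly
`(1 + 3ρ)/T` (≈ −0.09 at ρ = 0.3, T ≈ 21): a genuine property of the
published method, not of this implementation. The generator therefore
also returns `truth$model_frame`, the exact generative frame whose
response is `slope × year + AR(1) noise` with no recentring; recovery
experiments fit that frame (standard simulation-based-calibration
practice — validate the inference on data drawn from the model itself),
while pipeline tests use the emitted abundances end to end. Fitting the
recentred abundances instead recovers every trend parameter but
underestimates ρ by about the amount above on short series; users
comparing ρ across datasets with different series lengths should keep
this in mind.

Diagnostics are standard: split-Rhat (flagged above 1.01), effective
sample size via Geyer's initial-positive-sequence estimator, divergence
counts, and posterior predictive checks reporting the mean residual,
variance constancy, and the pooled lag-1 autocorrelation of raw versus
AR(1)-whitened residuals (whitening should remove lag-1 structure when
the model is well specified; fitting without the AR term on correlated
data leaves raw lag-1 autocorrelation > 0.3 — both directions are
tested). The description of Rhat in the source text (an ESS fraction) is
not Rhat; standard split-Rhat is implemented.

## 5. Trend estimand

A "trend" is the mean first derivative of predicted log abundance: per
posterior draw, predictions are formed on a unit-spaced year grid for a
context (a threat set, with interactions on or off) and successive
difference quotients are averaged, unweighted, exactly as the estimand is
defined. For the linear model this equals the implied slope on any grid,
so the choice of grid (default: 25 unit-spaced years; whether the
original used the fitted-year grid is unstated) is immaterial for
conditional predictions; the derivative machinery still handles irregular
grids, which the tests exercise directly. The percent scale is
`100·(exp(trend) − 1)` — the multiplicative change a log-linear model
implies; the transform is not stated in the source, so a linear option
(`method = "linear"`) exists behind a flag. Posteriors are summarised at
50/80/95% equal-tailed intervals.

`influence_decomposition()` contrasts three trend posteriors: *null*
(threats and random effects zero — the global year slope), *random* (null
threat matrix plus every fitted random identity, averaged across series
into a marginal posterior) and *fixed* (every threat column set to 1,
conditional). The two differences (random − null, fixed − null) measure
what each component contributes to trend direction; a zero difference
means no contribution. Additivity (null + (fixed − null) = fixed,
draw-by-draw) is asserted in the tests.

## 6. Interaction classification

For a combination, the *interactive* trend uses the design as built; the
*additive* trend turns off every interaction column of order ≥ 2 among
the combination's categories (for pairs this is the single interaction
column; for triples, the three pairs and the triple). The difference
posterior is summarised by an equal-tailed interval at `ci_level`
(default 0.80; percentile, not HPD — only a "credible interval" is
specified): containing zero → additive; entirely negative → synergistic;
entirely positive → antagonistic. The additive null is the simple sum of
single effects — no multiplicative or dominance nulls, matching the
stated rationale that a mechanistic null is unjustifiable across taxa and
systems at this scale.

`sensitivity_scan()` re-classifies across levels; nested intervals make
non-additivity monotone in the level, which is property-tested.
Calibration is tested by simulation: with the interaction truth at zero,
the additive verdict is returned at the nominal 80% rate over 200
replicates (asserted with a two-standard-error binomial allowance, since
the nominal rate itself is the target); with an interaction of −0.1 on 60
affected series the synergistic verdict is returned in ≥ 80% (empirically
~100%) of replicates. These replicate experiments run through
`fit_fixed_effects()`, the exact conjugate posterior of the
fixed-effects-only Gaussian core (ridge-form multivariate normal with σ
at its MLE) — the difference posterior depends only on the fixed-effect
draws, so hundreds of replicates cost seconds instead of hundreds of HMC
runs.

`summarize_classes()` reports per-threat class shares. How the original
fractional percentages were aggregated is unstated, so both implemented
modes are labelled and neither claims to replicate them: `"combo"` (each
combination one vote) and `"draw"` (a non-additive combination weighted
by the posterior mass supporting its direction, remainder to additive),
the latter yielding fractional shares diluted below the combo-weighted
ones.

## 7. Counterfactuals

`run_counterfactual(fit, removal_set)` follows the three-step procedure:
drop unthreatened populations; zero every design column involving a
removed threat; re-estimate each remaining population's trend under the
modified matrix. Baseline and counterfactual use the *same* posterior
draws, so Monte Carlo noise cancels in the comparison, and an empty
removal set (or removing a threat absent from the data) reproduces the
baseline bit-for-bit — both are acceptance-tested. Population random
slopes are included by default for full fits (the scenario distribution
is a distribution of *population* trends); `include_random = FALSE` gives
purely conditional scenarios.

Pooling and summary were open choices: the default pools one value per
population (its per-draw trend median) and summarises by the median,
matching a box-plot-of-population-trends presentation; `pooling = "draw"`
and `summary = "mean"` are alternatives. Relative change is
`100·(counterfactual − baseline)/|baseline|`; a zero baseline is reported
as `NA` with the absolute change attached and a warning. Under additive,
uniformly negative effects, larger removal sets never lower the median
trend and the all-threat removal dominates — both property-tested.

## 8. The synthetic world

`generator_config()` states the emulated world once; the defaults are not
tuned to any test outcome:

* **Structure**: 60 species × 2 populations at 60 sites (sizes are
  arguments; the real compilation is ~26× larger and is not reproducible
  at desk scale). Sites are area-uniform on the sphere, clipped to
  inhabited latitudes (−65°, 75°).
* **Spans**: 10 + Gamma(shape 2, scale 9) years, resampled into [10, 65]
  — median 25 at scale, matching the stated duration distribution;
  calendar windows inside 1950–2019. Interior years are dropped with
  probability `missingness = 0.2` (endpoints kept, ≥ 5 points enforced)
  to exercise irregular-grid handling.
* **Threat prevalences** (share of assignment tokens, "none" included):
  none 20.00%, disease 3.04%, invasive 5.69%, climate change 6.07%,
  pollution 7.16%, habitat loss 27.20%, exploitation 30.60%. Tokens are
  drawn i.i.d. from this distribution — a first token ("none" ends
  assignment) plus further tokens with probability 0.5 each, capped at
  three — so token shares are exactly multinomial, which the
  prevalence-emulation test verifies at n = 2000 within three binomial
  standard errors. The sum-to-one reading (populations counted per
  assignment) is what makes the published shares coherent with
  multi-threat populations.
* **Effects**: the no-threat year slope is log(1.017) ≈ +1.7%/yr and the
  six single-threat moderations are the published single-threat trends
  converted to log scale (e.g. invasive −6.01%/yr ⇒ moderation −0.079);
  interactions default to zero (an additive world) and are overridden per
  experiment via `true_beta`. σ_obs = 0.3 (AR innovation), ρ = 0.3,
  random-slope scales 0.02/0.02/0.01 — trend-scale heterogeneity a
  field ecologist would call realistic for multi-decadal vertebrate
  series.
* **What it does not emulate**: taxonomic/geographic clustering beyond
  the configurable counts, threat severity or recurrence, observation
  protocols, and real zero-inflation (abundances are positive by
  construction; a `zero_rate` corruption option exercises the offset
  path deliberately). A green test on this world therefore establishes
  correctness of the *inference machinery* on the model's own data, not
  fidelity of the model to real LPD biases.

`recovery_report()` compares posterior medians/intervals to the
generating truth by parameter name and errors on any mismatch, so silent
misalignment of coefficient indexing cannot pass.

## 9. Known limitations

* The AR(1) process ignores calendar gaps (Section 4) and ρ is attenuated
  by per-series centring on short series — both inherent to the method as
  published.
* `1 − D/max(D)` makes the proximity of the most distant pair exactly 0
  and depends on the realised maximum distance, so proximities are not
  comparable across datasets with different spatial extents.
* Counterfactuals are model predictions under threat-column deletion, not
  causal estimates of management effects; no causal identification is
  attempted, and the scenario tables should be read as "influence of
  threats on predicted trends".
* The headline numbers of the motivating analysis derive from partly
  confidential source data and are deliberately out of scope; the
  acceptance machinery validates analytic counts, oracle equivalences and
  property-based recovery on synthetic data instead.
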