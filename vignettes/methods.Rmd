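---
title: "Models and methods in densnest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in densnest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densnest)
```

`densnest` analyses density-dependent breeding success in territorial
farmland birds.  This vignette explains each model, its assumptions, the
tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Territory density metrics

Territory centres are song-post coordinates in planar metres; at farm
scale, geodesic curvature is negligible, so distances are Euclidean.  For
each territory, `territory_density()` reports:

* **NND** — distance to the nearest other territory centre in the *same
  farm and year*, capped at `cap` (default 1000 m).  An isolated territory
  scores the cap exactly.
* **NTND** — mean of the `k = 3` nearest capped distances.  When fewer than
  three neighbours exist, each missing neighbour contributes the cap; this
  keeps NTND defined (and equal to NND = cap for an isolated point) and
  preserves NND ≤ NTND everywhere.  The alternative of averaging only the
  neighbours that exist is available via `partial_average = TRUE`.

Cross-farm neighbours are never considered, mirroring per-farm territory
mapping; whether a cross-farm neighbour should count is genuinely open, so
the grouping is by farm-year and documented rather than configurable per
pair.  Duplicate coordinates are an error (zero distance between distinct
territories is undefined); the generator re-draws duplicated points for the
same reason.

Boundary classification (`classify_boundary()`) applies the six-class
scheme in strict rule order for hedgerows — gappiness first (> 20 % gaps),
then canopy bands (< 10 %, 10–50 %, > 50 % cover from trees over 3 m) —
and splits non-hedgerow boundaries on 1 m of adjoining herbaceous
vegetation.  Printed rules use strict inequalities, so exact 10 % and 50 %
fall in the middle band, exact 20 % is not gappy and exactly 1 m is a bare
fence.  Non-hedgerow boundaries with > 50 % tree canopy are tree lines and
join the "> 50 % trees" class.

## Exposure days and the logistic-exposure model

Nest monitoring is interval-censored: visits at most `visit_interval_max`
(3) days apart observe status only.  Exposure is computed by the
"Last Active-B" rule: for failed nests, from the first visit to the
midpoint of the last-active and first-inactive visit days; for successful
or censored nests, to the last day observed active.  Midpoints produce
half-day exposures, which are deliberately kept fractional: the
likelihood below is evaluated with the continuous binomial kernel
$f\log h + (t-f)\log(1-h)$, whose combinatorial constant is dropped — a
convention that changes no MLE, SE, or AICc *difference*, and is used
consistently across all candidate models.

Exposure before the hatch day accrues to the egg stage, after it to the
nestling stage.  Hatch day is an input (observed, or field-estimated from
nestling feather development); nestling ageing itself is out of scope.  A
nest that failed at the egg stage and was never aged accrues all exposure
to the egg stage.  Outcomes follow the fledging rule: nestlings present at
age ≥ 7 days and an intact empty nest at the following check mean fledging;
a damaged nest, or one that emptied earlier, failed.  The rule cannot
distinguish predation in the last two days before fledging from fledging
itself — a small, known misclassification inherited from the field
protocol, visible in the generator where a nest depredated between the
age-7 and age-10 checks with an intact cup is recorded as fledged.

The **logistic-exposure** model treats each nest as a binomial observation
with $t_i$ trials (exposure days) and $f_i \in \{0,1\}$ successes
(failure), with $\mathrm{logit}\,h_i = x_i'\beta$ on the daily failure
probability.  This is the natural GLM extension of the Mayfield estimator:
the intercept-only MLE is *algebraically* $\hat h = \sum f_i / \sum t_i$,
an identity the test suite checks to 10⁻¹⁰ on random data.  Fitting is
Newton–Raphson on the exact score $X'(f - t h)$ and observed information
$X' \mathrm{diag}(t h (1-h)) X$, tolerance 10⁻¹⁰ on the step, at most 200
iterations, initialized at the pooled Mayfield rate.  Steps are damped to
length 5 on the logit scale; a linear predictor exceeding ±30, a singular
information matrix, or non-convergence raises a separation warning and
flags the fit (`$extra$separation`) rather than failing silently —
all-successes data is the canonical trigger.

Two documented alternatives exist because the historical literature is
split on the encoding:

* `method = "interval"` fits the likelihood in which a nest surviving $t$
  days contributes $(1-h)^t$ and a failed nest $1-(1-h)^t$ (fitted by
  BFGS with a numerical Hessian for SEs).  The binomial-trials form is the
  default.
* Random intercepts (farm, or farm/nest nested) use the identical
  likelihood re-expressed as a weighted binomial GLMM (response $f_i/t_i$,
  weights $t_i$) and are fitted by Laplace-approximated ML via `lme4`,
  which is the established, well-tested implementation of exactly that
  marginal likelihood; writing a second Laplace optimizer would duplicate
  it without adding control.

## Multimodel inference

Every analysis is declared as a global model (`model_spec()`) and explored
by all-subsets enumeration (`dn_dredge()`) under marginality: an
interaction `a:b` or quadratic `I(x^2)` enters only with its parents.
Candidates are ranked by AICc, $-2\ell + 2k + 2k(k+1)/(n-k-1)$, where $k$
counts fixed coefficients plus ordinal thresholds, random-intercept
variances and the Gaussian residual variance, and $n$ is the number of
rows (nests, watches, or nestlings as appropriate).  More than 20 free
terms is refused by default (combinatorial guard, raisable).

The top set is every model with ΔAICc strictly below 2 — the standard
reading of "models with AICc < 2"; a model at exactly Δ = 2 is excluded.
Averaging is *conditional* (subset) by default: a term's estimate is its
weight-averaged value over the models that contain it, with weights
renormalized over those models, and `n_models` reports the retention
count, matching the "No. models" column convention of averaged coefficient
tables.  Full-model (zero-substitution) averaging is available via
`method = "full"`.  Standard errors use the unconditional form
$\mathrm{SE} = \sum_i \tilde w_i \sqrt{\mathrm{SE}_i^2 + (\beta_i - \bar\beta)^2}$,
and intervals are Wald ±1.96 SE (the original CI construction is unstated;
Wald is the convention the unconditional SE was designed for).

All mixed models are fitted by **ML, never REML**, so likelihoods are
comparable across fixed structures; Gaussian and Poisson mixed models use
`lme4` (Laplace), and the deterministic initialization of each fit makes
dredge output reproducible.

**Ordinal fledgling counts** use a cumulative-logit (proportional-odds)
model written in the package: ordered thresholds are parametrized as a
first threshold plus log-increments (so ordering is unconstrained during
BFGS), SEs come from the numerical Hessian on the natural scale at the
interior optimum, and an optional single random intercept is integrated by
a one-dimensional Laplace approximation per group (inner mode by golden
search on ±6σ, curvature by central differences).  The fixed-effects path
is cross-checked against `MASS::polr` in the test suite.  Because the
averaged nest-level tables use one row per nest, the ordinal analysis
supports one grouping factor; the nested farm/nest structure of the
original repeated-measures design collapses to the farm level here.  Fit
quality for ordinal models is reported as McFadden's pseudo-R²,
$1 - \ell/\ell_0$.

**Variance-partition R²** (marginal/conditional) divides the variance of
the fixed-effect predictor by fixed + random-intercept + residual
variance; the residual term is the ML residual variance (Gaussian),
$\ln(1/\bar\lambda + 1)$ with $\bar\lambda$ the mean count (Poisson, log
link), or $\pi^2/3$ (logit links).  Denominators use $n-1$ consistently,
so a fixed-effects Gaussian model reduces exactly to classical R².

## Demographic projection

For $P$ pairs (default 100): successful nests per pair = re-nesting rate
(1.66 nests pair⁻¹ season⁻¹) × per-nest success (0.45); total young =
$P$ × that × young per successful nest; adults next year =
$2P \times S_{ad} + \text{young} \times S_{juv}$ with $S_{ad} = 0.449$,
$S_{juv} = 0.440$; annual change % = $100(\text{adults}' - 2P)/2P$.  The
accounting treats $P$ pairs as $2P$ adults, both sexes surviving at the
adult rate, and fledglings recruiting at the juvenile rate with no
second-year discount — the unique reading of the printed inputs that
reproduces the printed outputs for both managements.  No density
dependence, immigration or sex-ratio adjustment is modelled; computations
are at full precision with rounding to one decimal only at presentation.
`demographic_sensitivity()` re-projects over a grid of one parameter
(annual change is strictly increasing in every vital rate, and zero
exactly when recruits balance adult losses).

## The synthetic-data generator

The generator exists so that every downstream stage is exercised against
data whose truth is known.  It emulates, with overridable defaults:

* **Farms** in organic/conventional pairs inside alternating landscapes,
  as non-overlapping 1-km squares; per-habitat boundary totals drawn from
  configured ranges and split into 1–3 segments summing exactly to the
  total.
* **Territory counts** per farm-year: Poisson with log-mean
  intercept + Σ slope·log(length+1) + year + landscape.  Default
  coefficients are the published farmland estimates (hedgerow 0.394,
  vegetated fence 0.065 per log-metre, −0.748 for the second year, +0.364
  in organic landscapes), so simulated studies resemble the field system
  in density and spacing.  Points are placed uniformly along
  length-weighted boundary segments, re-drawn on exact duplicates.
* **Nests**: at most one monitored nest per territory (the analysis rule;
  re-nesting within a season is deliberately not simulated), clutches of
  3–4 (P(3) = 0.68, giving a mean near the observed 3.3), concealment
  scores 1–5 from a configurable categorical distribution (no field
  distribution is published), 12-day incubation and fledging at age 9 so
  the day-7/day-10 rule is exercised.  True fate follows a daily Bernoulli
  failure process from discovery at stage-specific hazards (default 0.03
  per day at both stages, consistent with ~45 % per-nest success over a
  ~24-day attempt), logit-linear in NND centred at 300 m.  Only the
  interval-censored visit record is exposed downstream; true fates,
  hazards and failure days ride along in `true_*` columns for recovery
  tests.
* **Provisioning watches** at nestling ages 2–7 with Gaussian noise (SD 2
  trips hr⁻¹) around a linear predictor carrying NND×corvid-activity and
  NND×brood interactions; corvid activity is Poisson(3), invertebrate
  abundance log-normal, temperature normal(15 °C, 3) — families chosen as
  realistic for count/abundance/weather covariates whose generative law no
  study states.
* **Nestling masses**: two timed measurements in the linear growth phase
  (ages 2–7), the second a linear function of the first mass, hours
  elapsed (~48 h), age and NND (default 0.3 g per 100 m).

The generator does **not** emulate hedgerow network topology, home-range
movement, renesting, multi-brood phenology, nest height, geographic
clustering, or spatially autocorrelated predator fields.  Passing tests
therefore demonstrate that the estimators recover the generative structure
they target under realistic sampling — not that real farmland data meet
these assumptions.

Determinism: each generator stage seeds its own offset from the configured
seed, so both individual `gen_*` calls and full `simulate_dataset()` runs
are bit-reproducible for a given configuration.

## Pipeline and problem sizes

`run_pipeline()` chains simulation (or CSV input), density metrics,
exposure summaries, the seven analyses, and demography, writing one model
table and one averaged table per analysis plus R², demography and a seeded
run log.  `default_run_config(full = TRUE)` carries the complete
global-model structures (within simulated covariates: nest height and
geographic cluster do not exist in the generator and are omitted; per-nest
provisioning rate enters nest-level models as the mean across watches).
The `full = FALSE` configuration uses smaller candidate sets — examples
and the test suite use it so a complete run finishes in seconds; the full
configuration enumerates thousands of mixed-model candidates and is meant
for real analyses.  The NTND sensitivity re-run (`ntnd_swap = TRUE`)
substitutes NTND for NND in every term of every affected analysis and
writes a parallel, labelled table set.

Validation sizes were chosen to make Monte-Carlo error small relative to
the tolerance checked: 800 farms for the Poisson-mean check, ≥ 5000 egg
exposure-days for the hazard-rate check, 200 replicates of 1000 nests for
CI coverage, 100 random datasets for the Mayfield identity, 50 random
model structures and 100 random point sets against brute-force oracles,
and n = 5000 (500 groups × 10) for the 1/1/2 variance-partition R²
recovery.

## Known limitations

* Stage assignment of failures near hatch is interval-censored: a failure
  midpoint can land on the wrong side of the hatch day, slightly inflating
  the apparent egg-stage rate; this mirrors what field data contain.
* No competing risks, predator identity, or time-varying within-interval
  covariates in the survival models.
* The ordinal model supports a single random intercept.
* The demographic projection is deterministic point arithmetic; no CI
  propagation.
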