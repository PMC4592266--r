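# densnest

Density-dependent breeding success analysis for territorial farmland birds.

Territorial songbirds such as the yellowhammer (*Emberiza citrinella*) nest
in linear boundary habitat (hedgerows, vegetated fences) but forage
elsewhere, so high territory density — usually read as a sign of good
habitat — can instead mark an **ecological trap**: more neighbours mean more
competition for nestling food and more attention from corvid nest
predators, and productivity per pair falls.  `densnest` packages the full
analysis chain needed to test this on field (or simulated) data:

1. **Territory density metrics.** Nearest-neighbour distance (NND) and the
   mean distance to the three nearest neighbours (NTND) from mapped
   song-post coordinates, computed within farm and year, with every
   neighbour distance capped at 1 km (an isolated territory scores exactly
   1000 m).  Boundary habitat is classified into six classes (hedge by
   canopy-cover bands, gappy hedge, vegetated fence, bare fence/wall) and
   summed per farm.

2. **Mayfield exposure-day nest survival.** Visit histories taken at ≤3-day
   intervals are reduced to exposure days using the "Last Active-B" rule
   (failure assigned to the midpoint of the last active and first inactive
   visits), split into egg and nestling stages at the hatch day, and
   outcomes classified by the day-7/day-10 fledging rule.  Daily failure
   probability is modelled by the **logistic-exposure** likelihood: nest
   *i* with exposure *t<sub>i</sub>* and failure indicator
   *f<sub>i</sub>* ∈ {0, 1} contributes

   &nbsp;&nbsp;&nbsp;&nbsp;ℓ<sub>i</sub> = f<sub>i</sub> log h<sub>i</sub> + (t<sub>i</sub> − f<sub>i</sub>) log(1 − h<sub>i</sub>),&nbsp;&nbsp; logit h<sub>i</sub> = x<sub>i</sub>′β,

   whose intercept-only maximum-likelihood estimate is exactly the classic
   Mayfield daily failure rate Σf/Σt.  Random intercepts (farm, or
   farm/nest nested) are supported, as is an interval-likelihood variant.

3. **AICc multimodel inference.** All-subsets enumeration from a global
   model under marginality constraints, AICc ranking
   (−2ℓ + 2k + 2k(k+1)/(n−k−1)), Akaike weights, averaging of the ΔAICc < 2
   top set with unconditional standard errors
   (SE = Σ w̃<sub>i</sub> √(SE<sub>i</sub>² + (β<sub>i</sub> − β̄)²)), and
   marginal/conditional variance-partition R².  Gaussian, Poisson,
   binomial, logistic-exposure and cumulative-logit (ordinal fledgling
   count) families are supported, all fitted by ML.

4. **Demographic projection.** Per-pair productivity (re-nesting rate ×
   per-nest success × young per successful nest) and annual adult/juvenile
   survival are converted into young per 100 pairs and annual percentage
   population change.

5. **Synthetic data.** A seeded generator reproduces the statistical
   structure of a two-year paired organic/conventional farm study —
   Poisson territory counts driven by log(length+1) of boundary habitat,
   a constant-hazard daily nest-failure process observed through realistic
   visit schedules, provisioning rates with NND×corvid and NND×brood
   interactions, and linear nestling mass gain increasing with NND — so
   every stage of the pipeline is testable without field data.

## Worked example

```r
library(densnest)

# four territories on the corners of a 100 m square
pts <- data.frame(territory_id = 1:4, farm_id = "A", year = 2007,
                  x = c(0, 100, 0, 100), y = c(0, 0, 100, 100))
territory_density(pts)
#>   territory_id farm_id year     ntnd nnd n_neighbours_used
#> 1            1       A 2007 113.8071 100                 3
#> ...

# logistic-exposure survival model on simulated nests
set.seed(1)
nests <- simulate_logexp(500, beta = c(-3.5, 0.8))
logexp_fit(failed ~ z, nests, exposure = "exposure")
#> <dn_fit> family=binomial-exposure  logLik=-960.0581  k=2  n=500
#>               estimate         se
#> (Intercept) -3.5473304 0.07661305
#> z            0.8576517 0.07386551

mayfield_dsr(sum(nests$failed), sum(nests$exposure), period = 21)
#> DSR 0.9680 (SE 0.0021), 21-day survival 0.505

# demographic projection for organic-farm productivity
project_population(demographic_params(young_per_successful_nest = 2.42))
#> Successful nests per pair: 0.747
#> Young produced:            180.8
#> Adults next year:          169.3
#> Annual change:             -15.3%
```

Each NND here is the 100 m side of the square and NTND averages the two
sides and the diagonal: (100 + 100 + 100√2)/3 ≈ 113.8 m.  The survival fit
recovers the simulated coefficients (−3.5, 0.8) within one standard error,
and a daily survival rate of 0.968 compounds to about 50% survival over a
21-day nesting attempt.  The projection says 100 pairs producing 2.42 young
per successful nest shrink by 15.3% per year at the given survival rates;
with 3.19 young per nest the decline is only 2.7%.

A full simulated study runs end to end with

```r
run_pipeline(default_run_config(full = FALSE, seed = 1), out_dir = "run1")
```

writing per-analysis model-ranking and averaged-coefficient tables
(`term, n_models, estimate, se, lower_ci, upper_ci`), density metrics,
exposure summaries, R² values, a demography table and a seeded run log.
`default_run_config(full = TRUE)` declares the complete seven-analysis
global-model structure; `ntnd_swap = TRUE` re-runs every NND analysis with
NTND substituted.

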