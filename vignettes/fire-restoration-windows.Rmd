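---
title: "Restorative fire-severity windows: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restorative fire-severity windows: models, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firewindow)
```

## The question and the modelling chain

Dry conifer forests of the interior Pacific Northwest were historically
maintained by frequent low-severity fire; a century of fire exclusion has
left many stands several times denser than their historical condition,
with composition shifted toward fire-intolerant firs. `firewindow` asks at
which remotely sensed burn severities (RdNBR) a single fire is likely to
return such stands to their historical structure, and with how much
certainty.

The chain has five stages, each a module of exported functions:

1. **Species-level mortality models** (`fit_mortality_model()`): per
   species group, a binomial GLMM of individual-tree death on DBH, RdNBR,
   and years surveyed post-fire, with a Gaussian plot random intercept
   absorbing within-plot correlation.
2. **Uncertainty propagation** (`draw_coefficients()`,
   `species_curves()`): fixed-effect point estimates are replaced by
   independent normal draws centred on the estimates with SDs equal to the
   standard errors, giving a distribution of mortality curves rather than
   a single line.
3. **Stand-level fire simulation** (`severity_sweep()`): each tree record
   of a standardized 1-ha stand receives its own coefficient draw, a
   probability of death three years post-fire, and a uniform(0,1)
   comparison; live basal area, density, and composition aggregate per
   stand × severity × iteration.
4. **Restoration assessment** (`restorative_ranges()`,
   `generalized_range()`, `validate_predictions()`): outcomes are compared
   to historical references (mean ± 1 SD), severity windows meeting
   probability thresholds are extracted and generalised, and predictions
   are validated with Mean Bias Error, empirical 95% prediction-interval
   coverage, and range-classification accuracy.
5. **Landscape classification** (`classify_pixels()`, `class_summary()`):
   a severity raster plus a vegetation-type raster become a
   restoration-probability class map.

## Model assumptions

* Mortality is Bernoulli per inventory record given the linear predictor;
  a record's whole expansion weight lives or dies together, which keeps
  live + dead basal area exactly equal to the pre-fire total in every
  simulated outcome (conservation is an invariant, not an approximation).
* Severity acts at the plot/stand level (one RdNBR per plot), matching the
  resolution of gridded severity products; there is no within-stand
  severity heterogeneity.
* Delayed mortality enters only through the linear years-post-fire term;
  predictions fix years at 3 to capture most delayed death without
  conflating longer-term dynamics.
* Coefficient draws use independent marginals, deliberately ignoring
  estimator covariance — the propagated uncertainty is therefore slightly
  conservative where coefficients are correlated.
* The plot random intercept is set to zero for prediction (a
  population-level curve); an alternative reading — adding plot-effect
  draws from `N(0, σ_u)` — would widen stand-level spread and is easy to
  emulate by enlarging the intercept SE, but is not the default.
* No regeneration, growth, fuels, reburns, or spatial arrangement of trees
  within stands; trees below 15 cm DBH are excluded at the stand stage
  because historical references lack them.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `nAGQ` (`fit_mortality_model`) | 1 (Laplace) | nodes | With internally z-scored predictors the Laplace fit is numerically clean and matches a 9-node adaptive quadrature fit to three decimals at the data sizes used here; raise for very small plots. |
| `min_trees` | 50 | trees | Below this the GLMM is refused rather than fit badly. |
| interaction gate | 2,000 | trees | DBH×severity interactions are only screened for well-sampled species, then kept on a ΔAICc ≥ 2 improvement. |
| curve grid | −50..1350 by 10 | RdNBR | Species-curve display domain (141 points × 75 draws per size class). |
| `draws_per_point` | 75 | draws | Enough to render the probability cloud without dominating runtime. |
| stand grid | −50..1000 by 5 | RdNBR | Stand-sweep domain (211 points). |
| `iterations` | 5 | per stand × severity | The headline simulation size; convergence checks in tests use hundreds. |
| `years` | 3 | years | Delayed-mortality horizon for all stand predictions. |
| thresholds | 0.90 / 0.75 / 0.50 | probability | Restoration-probability levels reported and mapped. |
| HRV width | mean ± 1 SD | metric units | Reference envelope; lower bound floored at 0. |
| PI floor | 1 m²/ha, 5 trees/ha | — | Prediction-interval lower bounds below these are rounded down to 0: 1-ha simulations rarely reach exactly zero even when fire essentially removes the stand. |

## The synthetic generator

`synth_truth()` fixes a generating model: per-species logit-scale
coefficients (all severity effects positive; strongly negative DBH effects
for the fire-tolerant yellow pine, Douglas-fir, and western larch; a
DBH-sensitive, delayed-mortality-prone hardwood group), a plot
random-intercept SD of 0.5, truncated-lognormal diameter distributions
(floor 7 cm for burned plots, 15 cm for stands), and contemporary stand
templates departed from the historical references by 4.7×/4.6×
(density, dry mixed conifer / ponderosa pine) and 2.3× (basal area).
Coefficient magnitudes were chosen once so that mortality runs from near 0
at RdNBR −50 to near 1 at 1000 for typical trees — a realistic severity
response, not a calibration to any particular dataset.

What the generator emulates: plot-level severity assignment, within-plot
correlation via the random intercept, right-skewed diameter structure,
overstocking relative to historical conditions, spatially autocorrelated
severity with vegetation-type patches, and independent validation plots.
What it does not: real species frequency tables, climate or topographic
covariates, measurement error in RdNBR, spatial correlation between
neighbouring plots, or non-conifer vegetation dynamics. Passing tests
therefore demonstrate that the estimators and simulators are correct and
calibrated *under the stated model*, not that the model captures every
feature of field data.

The historical reference tables are synthetic constructions with
magnitudes realistic for eastern-Oregon dry forests (open stands around
18–22 m²/ha and 120–140 trees/ha, yellow-pine-dominated); they stand in
for reconstruction datasets and are labelled as such.

## Numerical choices

* **Fitting.** `lme4::glmer` maximises the marginal likelihood (Laplace by
  default, adaptive Gauss–Hermite via `nAGQ`). Predictors are z-scored
  internally and the coefficient vector and covariance matrix mapped back
  to natural units by the exact linear reparameterization; the z-scored
  fit also serves as the standardized-effect display. No restart schedule
  is needed: the scaled problem converges reliably with the default
  optimiser.
* **AICc.** `k` counts the fixed effects *plus* the random-intercept SD;
  the formula is `-2ℓ + 2k + 2k(k+1)/(n−k−1)` with `n` the number of
  trees. Counting the RE SD is a choice, stated here so comparisons are
  reproducible.
* **Smoothing.** All curves use tri-cube-weighted local linear regression
  (LOESS, degree 1, span 0.25); on short series the span widens to keep at
  least `degree + 2` points per window, and series shorter than 5 points
  pass through unsmoothed. Smoothed composition proportions are clamped at
  0 and renormalised to sum to 1 per severity.
* **Windows.** The restorative range is the *longest contiguous run* of
  grid severities meeting the threshold, ties broken toward lower
  severity. For unimodal proportion curves — the shape severity responses
  take — this makes windows at 0.90 ⊆ 0.75 ⊆ 0.50 automatically; for
  pathological non-unimodal curves the longest-run rule can in principle
  break that nesting, which is why the nesting property is tested on
  unimodal maps and the run-finder separately against a brute-force scan
  on arbitrary maps.
* **Generalisation.** Grid severities inside any group's ≥75% window are
  pooled with multiplicity and summarised by their 25th–75th percentiles
  (linear-interpolation quantiles, R type 7).
* **Percent of observed range.** `window_fraction()` uses nearest-integer
  rounding of `100·(hi−lo)/span`.
* **Intervals.** HRV and window endpoints are inclusive; prediction
  intervals are empirical 2.5–97.5 percentiles of the simulated outcomes
  (the simulation distribution is the model's uncertainty statement, so no
  parametric form is imposed), with the small lower bounds floored to 0 as
  above.
* **Degenerate inputs.** Single-outcome-class or single-plot data refuse
  to fit with explicit errors; zero-variance predictors are named; stands
  whose trees are all filtered away return an empty stand with a warning;
  severities at which every simulated outcome lost all basal area are
  reported as gaps in composition profiles, never interpolated.

## Open design decisions taken

* Coefficient draws are per tree and independent; a `share_draws` option
  draws once per species × iteration instead, modelling systematic
  parameter error (wider stand-level spread, same mean). Per-tree is the
  default because it matches the per-tree replacement described by the
  simulation framework.
* Severity-curve SD bands are smoothed per-severity sample SDs of the
  drawn probabilities (not SDs of smoother residuals).
* `average_range()` aggregates groups unweighted.
* The validation generator simulates at the population level (plot effect
  zero), matching the prediction side, so the coverage check is a genuine
  calibration test of the interval construction.

## Problem sizes and limitations

The test suite exercises the estimators at the scale the pipeline is meant
for — about 300 plots × 70 trees for fitting experiments (20 replicates
for the recovery study), 35 stands × 211 severities × 5 iterations for the
default sweep, 500 self-generated records for the coverage calibration —
sizes chosen as representative of regional analyses. Known limitations:
single-fire horizon, no sub-stand severity heterogeneity, composition
restoration is assessed but nothing in the model moves composition toward
historical dominance except differential mortality, and rasters are
exchanged as headered ASCII grids (a deliberate plain-text interchange;
convert to GeoTIFF downstream with any GIS tool).
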