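# firewindow

Can a single wildfire restore the structure of a dry conifer forest?
`firewindow` implements a multi-scale Monte Carlo pipeline for answering
that question with remotely sensed burn severity: it fits species-level
probabilistic tree-mortality models driven by RdNBR (Relativized
differenced Normalized Burn Ratio), propagates coefficient uncertainty into
simulated post-fire stand structure and composition, compares the outcomes
to historical reference conditions to find *restorative severity windows*,
validates the stand-level predictions against independent plots, and
reclassifies severity rasters into restoration-probability maps. It is
aimed at fire ecologists and silviculturists evaluating managed wildfire
and landscape-scale prescribed fire as restoration tools.

Because the inventory datasets such analyses rest on are typically
proprietary or undeposited, the package ships a first-class synthetic-data
generator with known ground truth (`synth_truth()`, `gen_*()`), so every
stage of the pipeline is testable end to end.

## The model

Tree mortality is modelled per species group as a binomial GLMM on the
logit scale with a Gaussian plot random intercept \(u_j \sim N(0,
\sigma^2_u)\):

```
logit p_ij = β0 + β1·DBH_ij + β2·RdNBR_j + β3·Years_j [+ β4·DBH_ij·RdNBR_j] + u_j
```

The interaction model is considered for species with more than 2,000
records and retained when it improves AICc by at least 2. Uncertainty is
propagated by Monte Carlo: each fixed-effect estimate is replaced by a draw
`β_MC,x ~ N(β̂_x, σ̂_x)` (independent marginals), the draw is inverse-logit
transformed into a probability of death three years post-fire, and a
uniform(0,1) comparison decides each tree's fate. Aggregating simulated
trees gives live basal area (m²/ha), density (trees/ha), and composition
per stand, severity (−50..1000 RdNBR by 5), and iteration.

A severity is *restorative* for a stand group when the simulated metric
falls within the historical range of variation (HRV, reconstruction mean
± 1 SD). The restorative window at probability `q` is the longest
contiguous severity run where at least a fraction `q` of simulated stands
land inside the HRV; the windows are generalised across forests as the
interquartile range of pooled in-window severities.

## Worked example

```r
library(firewindow)

truth   <- synth_truth("default")      # known generating model
records <- gen_burned_plots(truth, n_plots = 120, trees_per_plot = 60, seed = 1)
fit     <- fit_mortality_model(dplyr::filter(records, species_group == "white_fir"))
fit
#> <mortality_model> white_fir
#>           intercept       dbh severity    years
#> estimate  -4.243714 -0.013542 0.007892 0.100554
#> std_error  0.372563  0.005902 0.000480 0.027000
#> plot RE SD: 0.4588 | trees: 1366 | plots: 120
#> logLik: -443.91 | AICc: 897.86 | R2m: 0.71 | R2c: 0.727
```

The fit recovers the generating coefficients (truth: −4.4, −0.018, 0.008,
0.12, plot SD 0.5) within their standard errors. Sweeping simulated fire
across overstocked stands and comparing to the historical references:

```r
stands <- gen_stand_set(truth, forests = "Malheur", n_stands = 6, seed = 2)
sweep  <- severity_sweep(stands, truth_models(truth), seed = 3)
refs   <- gen_historical_refs(forests = "Malheur")
ranges <- restorative_ranges(sweep, refs)
dplyr::filter(ranges, metric == "basal_area", threshold == 0.75)
#>   metric     threshold forest  forest_type          lo    hi empty
#> 1 basal_area      0.75 Malheur dry_mixed_conifer   670   720 FALSE
#> 2 basal_area      0.75 Malheur ponderosa_pine      620   735 FALSE

generalized_range(dplyr::filter(ranges, threshold == 0.75,
                                metric == "basal_area", !empty))
#>    lo    hi
#> 662.5 707.5
```

So for this synthetic forest, basal area is restored with ≥75% probability
only inside a narrow moderate-severity band (generalised window 662–708
RdNBR — about 3% of the observed −52..1394 severity range,
`window_fraction()`); colder fire leaves stands overstocked, hotter fire
removes too much. `classify_pixels()` then maps those windows across a
severity raster, `autoplot()` draws the too-cold / restorative / too-hot
map, and `run_pipeline()` chains all stages with a manifest of seeds and
checksums.

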