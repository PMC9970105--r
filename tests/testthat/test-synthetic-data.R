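# Synthetic generators: determinism, distributional fidelity, and the
# departure multipliers that define the study conditions.

test_that("burned-plot generator matches its own generating probabilities", {
  # extreme negative intercept forces survival
  truth <- synth_truth("default", re_sd = 0)
  truth$species[, c("b0", "b_dbh", "b_sev", "b_yrs", "b_int")] <- 0
  truth$species$b0 <- -20
  recs <- gen_burned_plots(truth, n_plots = 100, trees_per_plot = 100, seed = 1)
  expect_lt(mean(recs$status == "dead"), 0.001)

  # null preset: p = 0.5 everywhere
  recs <- gen_burned_plots(synth_truth("null"),
    n_plots = 100, trees_per_plot = 100, seed = 2
  )
  n <- nrow(recs)
  expect_lt(abs(mean(recs$status == "dead") - 0.5), 3 * sqrt(0.25 / n))

  # default preset: empirical mortality within 3 MC SEs of the stored p_true
  recs <- gen_burned_plots(synth_truth("default"),
    n_plots = 300, trees_per_plot = 70, seed = 3
  )
  mc_se <- sqrt(sum(recs$p_true * (1 - recs$p_true))) / nrow(recs)
  expect_lt(abs(mean(recs$status == "dead") - mean(recs$p_true)), 3 * mc_se)
})

test_that("burned-plot generator validates inputs and is seed-deterministic", {
  truth <- synth_truth()
  expect_error(gen_burned_plots(truth, n_plots = 1), ">= 2")
  expect_error(
    gen_burned_plots(truth, severity_range = c(-600, 100)),
    "\\[-500, 2000\\]"
  )
  degenerate <- truth
  degenerate$mix_burned[] <- 0
  expect_error(gen_burned_plots(degenerate, seed = 1), "degenerate")

  a <- gen_burned_plots(truth, n_plots = 20, trees_per_plot = 10, seed = 42)
  b <- gen_burned_plots(truth, n_plots = 20, trees_per_plot = 10, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$dbh >= 7))
  expect_true(all(a$severity >= -52 & a$severity <= 1340))
})

test_that("plot random intercepts induce within-plot correlation", {
  # between-plot variance of the mortality fraction grows with the RE SD
  # (null fixed effects so the severity gradient does not dominate)
  plot_var <- function(re_sd) {
    recs <- gen_burned_plots(synth_truth("null", re_sd = re_sd),
      n_plots = 300, trees_per_plot = 40, seed = 9
    )
    per_plot <- tapply(recs$status == "dead", recs$plot_id, mean)
    stats::var(per_plot)
  }
  expect_gt(plot_var(2), plot_var(0) * 1.5)
})

test_that("stand generator hits the historical departure multipliers", {
  truth <- synth_truth()
  refs <- gen_historical_refs(forests = "Malheur")
  ref <- refs[refs$forest_type == "dry_mixed_conifer", ]
  stand_stats <- function(st) {
    per <- dplyr::summarise(dplyr::group_by(st, stand_id),
      tph = sum(expf), ba = sum(expf * tree_basal_area(dbh)),
      .groups = "drop"
    )
    c(tph = mean(per$tph), ba = mean(per$ba))
  }

  # identity multipliers: mean density within 5% of the historical mean
  unity <- truth
  unity$templates$dry_mixed_conifer$density_mult <- 1
  unity$templates$dry_mixed_conifer$ba_mult <- 1
  s1 <- stand_stats(gen_stand_set(unity,
    forests = "Malheur",
    types = "dry_mixed_conifer", n_stands = 200, seed = 4
  ))
  expect_lt(abs(s1[["tph"]] / ref$tph_mean - 1), 0.05)

  # default departure: density ratio in [4.2, 5.2] over 200 stands
  s2 <- stand_stats(gen_stand_set(truth,
    forests = "Malheur",
    types = "dry_mixed_conifer", n_stands = 200, seed = 5
  ))
  expect_gt(s2[["tph"]] / ref$tph_mean, 4.2)
  expect_lt(s2[["tph"]] / ref$tph_mean, 5.2)
  expect_lt(abs(s2[["ba"]] / ref$ba_mean - 2.3), 0.3)

  # determinism and standardization invariants
  a <- gen_stand_set(truth, forests = "Malheur", n_stands = 3, seed = 7)
  b <- gen_stand_set(truth, forests = "Malheur", n_stands = 3, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$dbh >= 15))
  expect_false(any(a$species_group == "hardwood"))
  expect_error(gen_stand_set(truth, types = "oak_savanna"), "oak_savanna")
})

test_that("historical reference presets satisfy their invariants", {
  for (preset in c("eastern-oregon", "uniform", "dmc-vs-pp")) {
    refs <- gen_historical_refs(preset)
    expect_true(all(refs$ba_sd > 0 & refs$tph_sd > 0))
    props <- rowSums(refs[, startsWith(names(refs), "prop_")])
    expect_true(all(abs(props - 1) < 1e-09))
  }
  uni <- gen_historical_refs("uniform")
  split_by_forest <- split(uni[, -1], uni$forest)
  for (d in split_by_forest) expect_equal(d, split_by_forest[[1]], ignore_attr = TRUE)

  contrast <- gen_historical_refs("dmc-vs-pp")
  expect_gt(
    contrast$prop_yellow_pine[contrast$forest_type == "ponderosa_pine"],
    contrast$prop_yellow_pine[contrast$forest_type == "dry_mixed_conifer"]
  )
})

test_that("landscape generator produces autocorrelated, deterministic rasters", {
  adj_cor <- function(scale) {
    m <- gen_landscape(64, 64, autocorrelation_scale = scale, seed = 11)$severity
    stats::cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  }
  expect_lt(adj_cor(1), adj_cor(10))

  a <- gen_landscape(16, 16, seed = 3)
  b <- gen_landscape(16, 16, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$veg_type %in% c("dry_mixed_conifer", "ponderosa_pine", "other")))

  expect_error(gen_landscape(4, 64), ">= 8")
  expect_error(gen_landscape(64, 64, autocorrelation_scale = 0), "positive")
})

test_that("an all-other landscape classifies to a fully masked map", {
  ls <- gen_landscape(16, 16,
    seed = 2,
    veg_props = c(dry_mixed_conifer = 0, ponderosa_pine = 0, other = 1)
  )
  ranges <- dplyr::bind_rows(lapply(
    c("dry_mixed_conifer", "ponderosa_pine"),
    function(ft) {
      tibble::tibble(
        metric = "basal_area", threshold = c(0.75, 0.50), forest = "Malheur",
        forest_type = ft, lo = c(400, 300), hi = c(500, 600), empty = FALSE
      )
    }
  ))
  map <- classify_pixels(ls, ranges)
  expect_true(all(is.na(map$class)))
  summ <- class_summary(map, ls)
  expect_equal(summ$prop_all[summ$veg_type == "all" & summ$measure == "masked"], 1)
})

test_that("validation generator honours forced severities and is self-consistent", {
  truth <- synth_truth()
  stands <- gen_stand_set(truth, forests = "Malheur", n_stands = 2, seed = 1)
  pre <- dplyr::summarise(dplyr::group_by(stands, stand_id),
    ba = sum(expf * tree_basal_area(dbh)), .groups = "drop"
  )

  certain_death <- truth
  certain_death$species[, c("b_dbh", "b_sev", "b_yrs", "b_int")] <- 0
  certain_death$species$b0 <- 30
  v <- gen_validation_set(certain_death, stands, n = 10, seed = 2)
  expect_true(all(v$ba_obs == 0 & v$tph_obs == 0))

  certain_life <- certain_death
  certain_life$species$b0 <- -30
  v <- gen_validation_set(certain_life, stands, n = 10, seed = 2)
  expect_equal(v$ba_obs, v$ba_pre)
  expect_equal(v$tph_obs, v$tph_pre)
  expect_equal(
    sort(unique(v$ba_pre)),
    sort(pre$ba[match(unique(v$stand_id), pre$stand_id)])
  )

  expect_error(gen_validation_set(truth, stands[0, ], n = 5), "empty")
  expect_error(gen_validation_set(truth, stands, n = 0), ">= 1")
})
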