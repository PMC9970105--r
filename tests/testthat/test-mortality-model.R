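# Species-level GLMM fitting, AICc selection, link-scale R^2, and
# standardized effects.

test_that("AICc matches hand computation and its limits", {
  expect_equal(aicc(0, k = 2, n = 100), 4 + 12 / 97)
  # penalty difference tends to 2 as n grows, at equal likelihood
  delta <- aicc(-100, k = 6, n = 1e7) - aicc(-100, k = 5, n = 1e7)
  expect_equal(delta, 2, tolerance = 1e-4)
  # correction vanishes: AICc -> AIC
  expect_equal(aicc(-50, k = 3, n = 1e8), -2 * -50 + 2 * 3, tolerance = 1e-4)
  expect_error(aicc(0, k = 5, n = 6), "n > k \\+ 1")
})

test_that("model selection retains the interaction only at delta AICc >= 2", {
  # invert the AICc formula to hit exact deltas
  n <- 10000L
  make_pair <- function(delta) {
    ll_main <- -500
    a_main <- aicc(ll_main, k = 5, n = n)
    # solve aicc(ll_int, k = 6, n) = a_main - delta for ll_int
    ll_int <- -(a_main - delta - 2 * 6 - 2 * 6 * 7 / (n - 7)) / 2
    main <- toy_model(log_likelihood = ll_main, n_trees = n)
    inter <- toy_model(
      dbh_severity = 1e-05, log_likelihood = ll_int,
      n_trees = n
    )
    list(main = main, inter = inter)
  }
  p <- make_pair(5.5) # the decisive improvement
  expect_equal(aicc(p$main) - aicc(p$inter), 5.5, tolerance = 1e-9)
  expect_true(select_mortality_model(p$main, p$inter)$has_interaction)

  p <- make_pair(1.9) # below the threshold
  expect_false(select_mortality_model(p$main, p$inter)$has_interaction)

  p <- make_pair(-3) # interaction worse
  expect_false(select_mortality_model(p$main, p$inter)$has_interaction)

  other <- toy_model(log_likelihood = -500, n_trees = 9999L)
  expect_error(select_mortality_model(p$main, other), "same records")
})

test_that("Nakagawa R2 follows the theoretical-variance formula", {
  # all fixed effects zero: no fixed-effect variance
  m0 <- toy_model(intercept = 0, dbh = 0, severity = 0, years = 0, re_sd = 1)
  recs <- tibble::tibble(
    plot_id = "p1", dbh = c(10, 20, 30), severity = c(0, 100, 200),
    years_post_fire = 1:3, status = "live"
  )
  r2 <- nakagawa_r2(m0, recs)
  expect_equal(r2[["r2_marginal"]], 0)

  # s2_f = 1, s2_a = 1 by construction: dbh effect 1 on values with var 1
  m1 <- toy_model(intercept = 0, dbh = 1, severity = 0, years = 0, re_sd = 1)
  recs1 <- tibble::tibble(
    plot_id = "p1", dbh = c(1, 2, 3), severity = 0,
    years_post_fire = 0, status = "live"
  )
  r2 <- nakagawa_r2(m1, recs1)
  expect_equal(r2[["r2_marginal"]], 1 / (2 + pi^2 / 3), tolerance = 1e-9)
  expect_equal(r2[["r2_conditional"]], 2 / (2 + pi^2 / 3), tolerance = 1e-9)

  # no random-effect variance: marginal equals conditional
  m2 <- toy_model(intercept = 0, dbh = 1, severity = 0, years = 0, re_sd = 0)
  r2 <- nakagawa_r2(m2, recs1)
  expect_equal(r2[["r2_marginal"]], r2[["r2_conditional"]])
})

test_that("fitting refuses degenerate inputs with clear errors", {
  truth <- single_species_truth()
  recs <- gen_burned_plots(truth, n_plots = 30, trees_per_plot = 10, seed = 1)
  expect_error(fit_mortality_model(recs[1:40, ]), "minimum of 50")

  one_class <- recs
  one_class$status <- "live"
  expect_error(fit_mortality_model(one_class), "inestimable")

  one_plot <- recs
  one_plot$plot_id <- "p1"
  expect_error(fit_mortality_model(one_plot), "2 plots")

  no_var <- recs
  no_var$dbh <- 30
  expect_error(fit_mortality_model(no_var), "dbh")
})

test_that("standardized effects are scale-invariant and preserve the likelihood", {
  truth <- single_species_truth(re_sd = 0.3)
  recs <- gen_burned_plots(truth, n_plots = 60, trees_per_plot = 25, seed = 8)

  eff <- standardized_effects(recs)
  expect_setequal(eff$predictor, c("dbh", "severity", "years"))

  doubled <- recs
  doubled$dbh <- recs$dbh / 2 # rescaling leaves the z-scored fit unchanged
  eff2 <- standardized_effects(doubled)
  expect_equal(
    eff$estimate[eff$predictor == "dbh"],
    eff2$estimate[eff2$predictor == "dbh"],
    tolerance = 1e-6
  )

  # the z-scored fit is a reparameterization: identical maximised likelihood
  fit_scaled <- fit_mortality_model(recs, scale_predictors = TRUE)
  fit_raw <- suppressWarnings(fit_mortality_model(recs, scale_predictors = FALSE))
  expect_equal(fit_scaled$log_likelihood, fit_raw$log_likelihood, tolerance = 1e-6)
  expect_equal(fit_scaled$coefficients, fit_raw$coefficients, tolerance = 5e-2)

  frozen <- recs
  frozen$years_post_fire <- 3
  expect_error(standardized_effects(frozen), "years")
})

test_that("adding the interaction term never decreases the log-likelihood", {
  truth <- single_species_truth("yellow_pine", re_sd = 0.3)
  recs <- gen_burned_plots(truth, n_plots = 80, trees_per_plot = 30, seed = 12)
  main <- fit_mortality_model(recs)
  inter <- fit_mortality_model(recs, include_interaction = TRUE)
  expect_gte(inter$log_likelihood, main$log_likelihood - 1e-6)
  expect_true(inter$has_interaction)
  expect_length(inter$coefficients, 5)
  # fit statistics invariants
  expect_true(main$r2_marginal <= main$r2_conditional)
  expect_true(all(main$std_errors > 0))
})

test_that("coefficient bias shrinks as trees per plot grow", {
  truth <- single_species_truth(re_sd = 0.5)
  b_sev_true <- truth$species$b_sev[truth$species$species_group == "white_fir"]
  mean_abs_err <- function(tpp, seeds) {
    errs <- vapply(seeds, function(s) {
      recs <- gen_burned_plots(truth,
        n_plots = 150, trees_per_plot = tpp,
        seed = 1000 + s
      )
      fit <- fit_mortality_model(recs)
      abs(fit$coefficients[["severity"]] - b_sev_true)
    }, numeric(1))
    mean(errs)
  }
  seeds <- 1:8
  expect_lt(mean_abs_err(60, seeds), mean_abs_err(10, seeds))
})

test_that("fit_species_models fits each group and applies the interaction gate", {
  truth <- synth_truth()
  recs <- gen_burned_plots(truth, n_plots = 60, trees_per_plot = 40, seed = 21)
  models <- suppressWarnings(fit_species_models(recs, min_trees = 100))
  expect_true(length(models) >= 3)
  expect_true(all(vapply(models, inherits, TRUE, "mortality_model")))
  # below the gate nothing carries an interaction term
  small_groups <- names(models)[vapply(models, function(m) m$n_trees <= 2000, TRUE)]
  for (g in small_groups) expect_false(models[[g]]$has_interaction)
  # tidy/glance expose the fitted surface
  g <- glance(models[[1]])
  expect_true(all(c("AICc", "r2_marginal", "random_intercept_sd") %in% names(g)))
  expect_named(
    tidy(models[[1]]),
    c("species_group", "term", "estimate", "std.error")
  )
})
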