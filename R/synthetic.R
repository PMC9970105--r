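# Synthetic data with known ground truth --------------------------------
#
# Generates every pipeline input from a known generating model so the whole
# chain (GLMM fit -> Monte Carlo curves -> stand sweep -> restoration
# windows -> landscape classification) can be tested without any download:
# burned-plot tree records from a logit-linear mortality model with plot
# random intercepts, overstocked contemporary stands departed from
# historical references by known multipliers, historical mean +/- SD
# reference tables, validation plots, and a spatially autocorrelated
# severity raster with vegetation-type patches. All references are synthetic
# constructions with realistic magnitudes, not reconstructions.

#' Synthetic ground truth parameters
#'
#' Bundles the generating parameters for the synthetic pipeline: per-species
#' logit-scale mortality coefficients (intercept, per-cm DBH effect, per-unit
#' RdNBR severity effect, per-year delayed-mortality effect, optional
#' DBH-by-severity interaction), the plot random-intercept SD, the burned-plot
#' species mix and DBH distribution, and the contemporary stand templates
#' (species mix, DBH shape, and density/basal-area departure multipliers
#' relative to the historical references).
#'
#' Presets: `"default"` (fire-tolerant species get strongly negative DBH
#' effects, hardwoods are DBH-sensitive and prone to delayed mortality;
#' contemporary stands 4.7x/4.6x denser and 2.3x the basal area of the
#' historical references), `"interaction"` (adds negative DBH-by-severity
#' interactions for yellow pine and Douglas-fir), and `"null"` (all
#' coefficients and the random-effect SD zero, so every tree dies with
#' probability one half).
#'
#' @param preset Preset name.
#' @param re_sd Optional override of the plot random-intercept SD.
#' @return An object of class `synth_truth` with fields `species` (tibble of
#'   generating coefficients), `re_sd`, `mix_burned`, `dbh_lnorm`,
#'   `templates`, and `ref_preset`.
#' @export
#' @examples
#' truth <- synth_truth("default")
#' truth$species
synth_truth <- function(preset = c("default", "interaction", "null"), re_sd = NULL) {
  preset <- match.arg(preset)
  species <- tibble::tribble(
    ~species_group, ~b0, ~b_dbh, ~b_sev, ~b_yrs, ~b_int,
    "yellow_pine", -4.8, -0.040, 0.0080, 0.20, 0,
    "douglas_fir", -4.6, -0.035, 0.0075, 0.20, 0,
    "white_fir", -4.4, -0.018, 0.0080, 0.12, 0,
    "western_larch", -5.5, -0.045, 0.0075, 0.10, 0,
    "lodgepole_pine", -3.8, -0.004, 0.0075, 0.15, 0,
    "other_conifer", -4.0, -0.015, 0.0075, 0.15, 0,
    "hardwood", -3.5, -0.030, 0.0060, 0.25, 0
  )
  sd_plot <- 0.5
  if (preset == "interaction") {
    species$b_int[species$species_group == "yellow_pine"] <- -3e-05
    species$b_int[species$species_group == "douglas_fir"] <- -2e-05
  }
  if (preset == "null") {
    species[, c("b0", "b_dbh", "b_sev", "b_yrs", "b_int")] <- 0
    sd_plot <- 0
  }
  if (!is.null(re_sd)) sd_plot <- re_sd
  mix_burned <- c(
    yellow_pine = 0.22, douglas_fir = 0.25, white_fir = 0.20,
    western_larch = 0.03, lodgepole_pine = 0.12, other_conifer = 0.08,
    hardwood = 0.10
  )
  templates <- list(
    dry_mixed_conifer = list(
      density_mult = 4.7, ba_mult = 2.3, dbh_sdlog = 0.45, stand_cv = 0.20,
      mix = c(
        yellow_pine = 0.20, douglas_fir = 0.22, white_fir = 0.40,
        western_larch = 0.04, lodgepole_pine = 0.06, other_conifer = 0.08
      )
    ),
    ponderosa_pine = list(
      density_mult = 4.6, ba_mult = 2.3, dbh_sdlog = 0.45, stand_cv = 0.20,
      mix = c(
        yellow_pine = 0.70, douglas_fir = 0.06, white_fir = 0.12,
        western_larch = 0.00, lodgepole_pine = 0.07, other_conifer = 0.05
      )
    )
  )
  truth <- structure(
    list(
      preset = preset,
      species = species,
      re_sd = sd_plot,
      mix_burned = mix_burned,
      dbh_lnorm = c(meanlog = 3.1, sdlog = 0.55, floor = 7),
      templates = templates,
      ref_preset = "eastern-oregon"
    ),
    class = "synth_truth"
  )
  validate_synth_truth(truth)
}

validate_synth_truth <- function(truth) {
  if (truth$re_sd < 0) abort("plot random-intercept SD must be >= 0.")
  if (any(truth$mix_burned < 0) || sum(truth$mix_burned) <= 0) {
    abort("degenerate burned-plot species mix.")
  }
  for (tpl in truth$templates) {
    if (abs(sum(tpl$mix) - 1) > 1e-09) abort("template species mix must sum to 1.")
    if (tpl$density_mult <= 0 || tpl$ba_mult <= 0) {
      abort("departure multipliers must be positive.")
    }
  }
  truth
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("<synth_truth> preset: ", x$preset, ", plot RE SD: ", x$re_sd, "\n", sep = "")
  print(x$species)
  invisible(x)
}

#' Ground-truth coefficients as mortality models
#'
#' Converts a [synth_truth()] into the named list of [mortality_model()]
#' objects the simulation functions expect, with all standard errors zero
#' (point-mass coefficient draws).
#'
#' @param truth A `synth_truth`.
#' @param species_groups Groups to include (default: all in the truth).
#' @return Named list of `mortality_model` objects.
#' @export
truth_models <- function(truth, species_groups = NULL) {
  sp <- truth$species
  if (!is.null(species_groups)) sp <- sp[sp$species_group %in% species_groups, ]
  models <- purrr::pmap(sp, function(species_group, b0, b_dbh, b_sev, b_yrs, b_int) {
    co <- c(intercept = b0, dbh = b_dbh, severity = b_sev, years = b_yrs)
    if (b_int != 0) co <- c(co, dbh_severity = b_int)
    mortality_model(species_group, co, random_intercept_sd = truth$re_sd)
  })
  names(models) <- sp$species_group
  models
}

# Truncated lognormal sampler via inverse CDF (exact, no rejection).
rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  p0 <- plnorm(lower, meanlog, sdlog)
  qlnorm(p0 + runif(n) * (1 - p0), meanlog, sdlog)
}

#' Generate burned-plot tree records
#'
#' Emulates a burned field-plot network: each plot receives one severity
#' (uniform over `severity_range`), one years-post-fire value, and one
#' Gaussian random intercept; each tree a species from the burned-plot mix, a
#' truncated-lognormal DBH (floor 7 cm), and a live/dead outcome sampled as
#' Bernoulli(inverse-logit(linear predictor + plot intercept)). The
#' generating probability is kept in `p_true` for oracle checks. Defaults
#' mirror the fitting data's scale: about 300 plots of about 74 trees over
#' severities -52..1340.
#'
#' @param truth A [synth_truth()].
#' @param n_plots Number of plots (>= 2).
#' @param trees_per_plot Trees per plot.
#' @param severity_range Plot-severity interval within `[-500, 2000]`.
#' @param years_range Integer interval of years post-fire.
#' @param seed Integer seed (identical seed, identical output).
#' @return Tibble of tree records: `plot_id`, `species`, `species_group`,
#'   `dbh`, `severity`, `years_post_fire`, `status`, plus generator columns
#'   `p_true` and `plot_effect`.
#' @export
gen_burned_plots <- function(truth, n_plots = 304, trees_per_plot = 74,
                             severity_range = c(-52, 1340),
                             years_range = c(0, 13), seed = 1) {
  if (n_plots < 2) abort("`n_plots` must be >= 2.")
  if (severity_range[1] < -500 || severity_range[2] > 2000) {
    abort("`severity_range` must lie within [-500, 2000].")
  }
  mix <- truth$mix_burned[truth$mix_burned > 0]
  if (length(mix) == 0) abort("degenerate species mix: no group has positive weight.")
  set.seed(seed)
  n <- n_plots * trees_per_plot
  plot_sev <- runif(n_plots, severity_range[1], severity_range[2])
  plot_yrs <- sample(seq(years_range[1], years_range[2]), n_plots, replace = TRUE)
  plot_re <- rnorm(n_plots, 0, truth$re_sd)
  plot_ix <- rep(seq_len(n_plots), each = trees_per_plot)
  grp <- sample(names(mix), n, replace = TRUE, prob = mix)
  dbh <- pmin(
    rlnorm_trunc(
      n, truth$dbh_lnorm[["meanlog"]], truth$dbh_lnorm[["sdlog"]],
      truth$dbh_lnorm[["floor"]]
    ),
    300
  )
  sp <- truth$species[match(grp, truth$species$species_group), ]
  sev <- plot_sev[plot_ix]
  yrs <- plot_yrs[plot_ix]
  lp <- sp$b0 + sp$b_dbh * dbh + sp$b_sev * sev + sp$b_yrs * yrs +
    sp$b_int * dbh * sev + plot_re[plot_ix]
  p <- plogis(lp)
  dead <- rbinom(n, 1, p) == 1
  tibble::tibble(
    plot_id = sprintf("plot_%03d", plot_ix),
    species = grp,
    species_group = grp,
    dbh = dbh,
    severity = sev,
    years_post_fire = yrs,
    status = ifelse(dead, "dead", "live"),
    p_true = p,
    plot_effect = plot_re[plot_ix]
  )
}

#' Generate historical reference conditions
#'
#' One mean +/- SD reference per forest x forest type, with live basal-area
#' composition proportions. These are synthetic stand-ins for historical
#' reconstructions, with magnitudes realistic for eastern-Oregon dry forests
#' (open, yellow-pine-dominated stands around 18-22 m^2/ha and 120-140
#' trees/ha).
#'
#' Presets: `"eastern-oregon"` (per-forest variation around the base),
#' `"uniform"` (identical references for every forest), `"dmc-vs-pp"` (one
#' forest, maximal compositional contrast between the two types).
#'
#' @param preset Preset name.
#' @param forests Forest labels (default the four national forests of the
#'   study area).
#' @return Tibble: `forest`, `forest_type`, `ba_mean`, `ba_sd`, `tph_mean`,
#'   `tph_sd`, and `prop_*` composition columns summing to 1.
#' @export
gen_historical_refs <- function(preset = c("eastern-oregon", "uniform", "dmc-vs-pp"),
                                forests = c("Malheur", "Fremont-Winema", "Deschutes", "Ochoco")) {
  preset <- match.arg(preset)
  base <- tibble::tribble(
    ~forest_type, ~ba_mean, ~ba_sd, ~tph_mean, ~tph_sd,
    "dry_mixed_conifer", 22, 7, 140, 45,
    "ponderosa_pine", 18, 6, 120, 40
  )
  comp <- tibble::tribble(
    ~forest_type, ~prop_yellow_pine, ~prop_douglas_fir, ~prop_white_fir,
    ~prop_western_larch, ~prop_other,
    "dry_mixed_conifer", 0.55, 0.18, 0.12, 0.05, 0.10,
    "ponderosa_pine", 0.85, 0.04, 0.02, 0.00, 0.09
  )
  if (preset == "dmc-vs-pp") forests <- forests[1]
  factors <- switch(preset,
    "eastern-oregon" = setNames(
      c(1.0, 0.95, 1.05, 0.9)[seq_along(forests)],
      forests
    ),
    setNames(rep(1, length(forests)), forests)
  )
  out <- purrr::map_dfr(forests, function(f) {
    d <- dplyr::left_join(base, comp, by = "forest_type")
    d$forest <- f
    fac <- factors[[f]]
    for (col in c("ba_mean", "ba_sd", "tph_mean", "tph_sd")) d[[col]] <- d[[col]] * fac
    d
  })
  dplyr::select(
    out, "forest", "forest_type", "ba_mean", "ba_sd", "tph_mean", "tph_sd",
    dplyr::starts_with("prop_")
  )
}

# Solve the truncated-lognormal meanlog whose per-tree expected basal area
# matches a target, at fixed sdlog and truncation floor.
.solve_meanlog <- function(target_ba, sdlog, floor_dbh) {
  e_ba <- function(mu) {
    # E[D^2 | D >= L] for lognormal(mu, sdlog), closed form via Mills-type ratio
    num <- exp(2 * mu + 2 * sdlog^2) *
      pnorm((mu + 2 * sdlog^2 - log(floor_dbh)) / sdlog)
    den <- pnorm((mu - log(floor_dbh)) / sdlog)
    pi / 40000 * num / den
  }
  stats::uniroot(
    function(mu) e_ba(mu) - target_ba,
    lower = log(floor_dbh), upper = log(200), extendInt = "upX", tol = 1e-10
  )$root
}

#' Generate contemporary stand inventories
#'
#' One-hectare conifer tree lists (all trees >= 15 cm DBH, expansion factor
#' 1) for each forest x forest-type cell, departed from the historical
#' references by the template multipliers: expected density equals the
#' historical mean times `density_mult` and expected basal area the
#' historical mean times `ba_mult`. Stand-to-stand heterogeneity is a shared
#' lognormal size factor (CV `stand_cv`) with tree counts Poisson around the
#' stand target; DBH is truncated lognormal with the template's shape and a
#' mean solved so the basal-area target is met in expectation.
#'
#' @param truth A [synth_truth()].
#' @param forests Forest labels.
#' @param types Forest types (subset of `dry_mixed_conifer`,
#'   `ponderosa_pine`).
#' @param n_stands Stands per forest x type cell (>= 1).
#' @param seed Integer seed.
#' @return Standardized stand tibble: `stand_id`, `forest`, `forest_type`,
#'   `species_group`, `dbh`, `expf`.
#' @export
gen_stand_set <- function(truth, forests = c("Malheur", "Fremont-Winema"),
                          types = FOREST_TYPES, n_stands = 17, seed = 1) {
  if (n_stands < 1) abort("`n_stands` must be >= 1.")
  bad <- setdiff(types, FOREST_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown forest-type label(s): ", paste(bad, collapse = ", ")))
  }
  refs <- gen_historical_refs(truth$ref_preset, forests = forests)
  set.seed(seed)
  out <- list()
  for (f in forests) {
    for (ft in types) {
      ref <- refs[refs$forest == f & refs$forest_type == ft, ]
      if (nrow(ref) != 1) abort(paste0("no reference for ", f, " / ", ft))
      tpl <- truth$templates[[ft]]
      tph_target <- ref$tph_mean * tpl$density_mult
      ba_per_tree <- (ref$ba_mean * tpl$ba_mult) / tph_target
      mu <- .solve_meanlog(ba_per_tree, tpl$dbh_sdlog, 15)
      cv <- tpl$stand_cv
      for (s in seq_len(n_stands)) {
        f_stand <- exp(rnorm(1, -cv^2 / 2, cv))
        n <- rpois(1, tph_target * f_stand)
        if (n == 0) n <- 1L
        grp <- sample(names(tpl$mix), n, replace = TRUE, prob = tpl$mix)
        dbh <- pmin(rlnorm_trunc(n, mu, tpl$dbh_sdlog, 15), 300)
        out[[length(out) + 1]] <- tibble::tibble(
          stand_id = sprintf("%s_%s_%02d", f, substr(ft, 1, 3), s),
          forest = f,
          forest_type = ft,
          species_group = grp,
          dbh = dbh,
          expf = 1
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# 1-D Gaussian smoothing with reflected edges.
.smooth1 <- function(v, kernel) {
  h <- (length(kernel) - 1) / 2
  n <- length(v)
  pad <- c(v[pmin(h:1, n)], v, v[pmax(n - seq_len(h) + 1, 1)])
  out <- stats::filter(pad, kernel, sides = 2)
  as.numeric(out[(h + 1):(h + n)])
}

.gauss_smooth <- function(mat, scale) {
  h <- max(1L, ceiling(3 * scale))
  k <- exp(-((-h:h)^2) / (2 * scale^2))
  k <- k / sum(k)
  sm <- t(apply(mat, 1, .smooth1, kernel = k))
  apply(sm, 2, .smooth1, kernel = k)
}

#' Generate a synthetic severity landscape
#'
#' A spatially autocorrelated RdNBR surface (Gaussian white noise smoothed at
#' `autocorrelation_scale` pixels, rescaled to a realistic burn-severity
#' distribution) with patchwise vegetation types from a second, more smoothly
#' varying field thresholded into dry mixed conifer, ponderosa pine, and
#' maskable "other" patches.
#'
#' @param rows,cols Grid dimensions (>= 8).
#' @param autocorrelation_scale Severity correlation length in pixels (> 0).
#' @param pvt_patch_scale Vegetation patch scale in pixels (> 0).
#' @param seed Integer seed.
#' @param veg_props Named proportions for `dry_mixed_conifer`,
#'   `ponderosa_pine`, `other` (summing to 1).
#' @param severity_mean,severity_sd Target RdNBR mean and SD before clamping
#'   to `[-500, 1500]`.
#' @return A [severity_landscape()].
#' @export
gen_landscape <- function(rows = 64, cols = 64, autocorrelation_scale = 8,
                          pvt_patch_scale = 16, seed = 1,
                          veg_props = c(
                            dry_mixed_conifer = 0.45,
                            ponderosa_pine = 0.35, other = 0.20
                          ),
                          severity_mean = 350, severity_sd = 300) {
  if (rows < 8 || cols < 8) abort("`rows` and `cols` must be >= 8.")
  if (autocorrelation_scale <= 0 || pvt_patch_scale <= 0) {
    abort("autocorrelation and patch scales must be positive.")
  }
  if (abs(sum(veg_props) - 1) > 1e-09) abort("`veg_props` must sum to 1.")
  set.seed(seed)
  z <- .gauss_smooth(matrix(rnorm(rows * cols), rows, cols), autocorrelation_scale)
  z <- (z - mean(z)) / sd(z)
  sev <- pmin(pmax(severity_mean + severity_sd * z, -500), 1500)
  u <- .gauss_smooth(matrix(rnorm(rows * cols), rows, cols), pvt_patch_scale)
  # rank-based assignment hits the requested proportions exactly and keeps
  # zero-proportion types genuinely absent
  fr <- (rank(u, ties.method = "first") - 0.5) / length(u)
  veg <- matrix("other", rows, cols)
  veg[fr < veg_props[["dry_mixed_conifer"]]] <- "dry_mixed_conifer"
  veg[fr >= veg_props[["dry_mixed_conifer"]] &
    fr < veg_props[["dry_mixed_conifer"]] + veg_props[["ponderosa_pine"]]] <-
    "ponderosa_pine"
  severity_landscape(sev, veg)
}

#' Generate independent validation records
#'
#' Emulates an independent set of burned one-hectare plots: each record draws
#' a stand from the supplied collection and a severity (uniform over the
#' stand-level grid domain unless forced), simulates one post-fire outcome
#' under the generating model at the population level (plot random effect
#' zero), and reports the observed live basal area and density with the
#' stand's forest type and nearest-forest label.
#'
#' @param truth A [synth_truth()] or a named list of [mortality_model()]
#'   objects (e.g. fitted models, for self-consistency calibration).
#' @param stands Standardized stand tibble.
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @param severity Optional forced severity (recycled over records).
#' @param grid Severity grid whose domain and spacing the drawn severities
#'   snap to (default -50..1000 by 5).
#' @param years Years post-fire (default 3).
#' @return Tibble: `record_id`, `stand_id`, `forest`, `forest_type`,
#'   `severity`, `ba_pre`, `tph_pre`, `ba_obs`, `tph_obs`.
#' @export
gen_validation_set <- function(truth, stands, n = 44, seed = 1, severity = NULL,
                               grid = seq(-50, 1000, by = 5), years = 3) {
  if (n < 1) abort("`n` must be >= 1.")
  if (nrow(stands) == 0) abort("empty stand collection.")
  models <- if (inherits(truth, "synth_truth")) truth_models(truth) else truth
  check_models_cover(stands, models)
  set.seed(seed)
  ids <- unique(stands$stand_id)
  pick <- sample(ids, n, replace = TRUE)
  sev <- if (is.null(severity)) {
    grid[sample.int(length(grid), n, replace = TRUE)]
  } else {
    rep_len(severity, n)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    st <- stands[stands$stand_id == pick[i], , drop = FALSE]
    sim <- simulate_stand(st, models, severity = sev[i], years = years)
    out[[i]] <- tibble::tibble(
      record_id = sprintf("val_%04d", i),
      stand_id = pick[i],
      forest = if ("forest" %in% names(st)) st$forest[1] else NA_character_,
      forest_type = if ("forest_type" %in% names(st)) st$forest_type[1] else NA_character_,
      severity = sev[i],
      ba_pre = sim$ba_pre,
      tph_pre = sim$tph_pre,
      ba_obs = sim$ba_live,
      tph_obs = sim$tph_live
    )
  }
  dplyr::bind_rows(out)
}
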