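# Tabular I/O and the end-to-end pipeline --------------------------------
#
# Interchange format is headered, comma-separated UTF-8 text. Rasters go
# through the ASCII-grid functions in landscape.R. run_pipeline() chains the
# stages (synth -> fit -> curves -> simulate -> assess -> classify) and
# writes a manifest with seeds and per-file checksums so a run is
# reproducible from its manifest alone.

#' Read a tree-record table
#'
#' Expects columns `plot_id`, `species`, `dbh_cm`, `rdnbr`,
#' `years_post_fire`, `status`. Species are pooled to species groups via
#' [pool_species()]. Rows with unparseable or out-of-range DBH/severity or an
#' unknown status are rejected (counted in the `n_rejected` attribute and a
#' warning), not fatal.
#'
#' @param path CSV file path.
#' @return Tibble of validated tree records (columns `plot_id`, `species`,
#'   `species_group`, `dbh`, `severity`, `years_post_fire`, `status`), with
#'   attribute `n_rejected`.
#' @export
read_tree_records <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- suppressWarnings(readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  need <- c("plot_id", "species", "dbh_cm", "rdnbr", "years_post_fire", "status")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort(paste0("empty input: ", path))
  d <- tibble::tibble(
    plot_id = raw$plot_id,
    species = raw$species,
    dbh = suppressWarnings(as.numeric(raw$dbh_cm)),
    severity = suppressWarnings(as.numeric(raw$rdnbr)),
    years_post_fire = suppressWarnings(as.integer(raw$years_post_fire)),
    status = tolower(raw$status)
  )
  ok <- !is.na(d$plot_id) & !is.na(d$species) &
    !is.na(d$dbh) & d$dbh > 0 & d$dbh <= 300 &
    is.finite(d$severity) &
    !is.na(d$years_post_fire) & d$years_post_fire >= 0 &
    d$status %in% c("live", "dead")
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warn(paste0(n_rejected, " malformed row(s) rejected while reading ", path))
  }
  d <- d[ok, ]
  d$species_group <- pool_species(d$species)
  d <- dplyr::relocate(d, "species_group", .after = "species")
  attr(d, "n_rejected") <- n_rejected
  d
}

#' Write a tree-record table
#'
#' Inverse of [read_tree_records()]: writes the documented column names
#' (`plot_id`, `species`, `dbh_cm`, `rdnbr`, `years_post_fire`, `status`).
#'
#' @param records Tree-record tibble.
#' @param path Output CSV path.
#' @export
write_tree_records <- function(records, path) {
  out <- tibble::tibble(
    plot_id = records$plot_id,
    species = records$species %||% records$species_group,
    dbh_cm = records$dbh,
    rdnbr = records$severity,
    years_post_fire = records$years_post_fire,
    status = records$status
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write fitted mortality models as a long table
#'
#' One row per coefficient, plus per-model metadata (random-intercept SD,
#' sample sizes, log-likelihood, AICc, R^2).
#'
#' @param models Named list of [mortality_model()] objects.
#' @param path Output CSV path.
#' @export
write_model_table <- function(models, path) {
  out <- purrr::map_dfr(models, function(m) {
    tibble::tibble(
      species_group = m$species_group,
      term = names(m$coefficients),
      estimate = unname(m$coefficients),
      std_error = unname(m$std_errors),
      random_intercept_sd = m$random_intercept_sd,
      n_trees = m$n_trees,
      n_plots = m$n_plots,
      log_likelihood = m$log_likelihood,
      aicc = m$aicc,
      r2_marginal = m$r2_marginal,
      r2_conditional = m$r2_conditional,
      max_dbh = m$max_dbh
    )
  })
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a mortality-model table back into model objects
#'
#' @param path CSV written by [write_model_table()].
#' @return Named list of [mortality_model()] objects.
#' @export
read_model_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  groups <- unique(d$species_group)
  models <- lapply(groups, function(g) {
    rows <- d[d$species_group == g, ]
    co <- setNames(rows$estimate, rows$term)
    se <- setNames(rows$std_error, rows$term)
    mortality_model(
      species_group = g, coefficients = co, std_errors = se,
      random_intercept_sd = rows$random_intercept_sd[1],
      n_trees = rows$n_trees[1], n_plots = rows$n_plots[1],
      log_likelihood = rows$log_likelihood[1],
      r2_marginal = rows$r2_marginal[1],
      r2_conditional = rows$r2_conditional[1],
      max_dbh = rows$max_dbh[1]
    )
  })
  names(models) <- groups
  models
}

#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], optionally
#' overridden field-by-field. The single `seed` expands to per-stage seeds as
#' `seed + stage index` (synth 1, fit 2, curves 3, simulate 4, assess 5,
#' classify 6), so any stage is independently rerunnable.
#'
#' @param ... Named overrides of the defaults.
#' @return Configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = tempfile("firewindow_run_"),
    truth_preset = "default",
    n_plots = 120, trees_per_plot = 60,
    forests = c("Malheur", "Fremont-Winema"),
    n_stands = 6,
    curve_grid = seq(-50, 1350, by = 10),
    curve_draws = 75,
    curve_classes = c(10, 20, 60),
    stand_grid = seq(-50, 1000, by = 5),
    iterations = 5,
    years = 3,
    thresholds = c(0.90, 0.75, 0.50),
    n_validation = 44,
    metric = "basal_area",
    landscape_rows = 48, landscape_cols = 48,
    landscape_forest = "Malheur",
    share_draws = FALSE,
    min_trees = 50
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  cfg[names(over)] <- over
  if (cfg$iterations < 1 || cfg$curve_draws < 1 || cfg$n_stands < 1) {
    abort("counts in the configuration must be positive.")
  }
  cfg
}

stage_seed <- function(cfg, stage) {
  cfg$seed + match(stage, c("synth", "fit", "curves", "simulate", "assess", "classify"))
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes synth -> fit -> curves -> simulate -> assess -> classify in
#' order, writing each stage's outputs as CSV (rasters as ASCII grids) under
#' `config$out_dir`, plus `manifest.json` recording the configuration,
#' per-stage seeds, package version, and an MD5 checksum of every output
#' file. A failure in any stage aborts with the stage name.
#'
#' @param config Configuration list from [pipeline_config()], or a path to a
#'   YAML file of overrides.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(obj, name) {
    p <- file.path(cfg$out_dir, name)
    readr::write_csv(obj, p, progress = FALSE)
    paths[[length(paths) + 1]] <<- p
    p
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", stage, "` failed: ", conditionMessage(e)))
    })
  }

  # synth
  res <- list(config = cfg)
  run_stage("synth", {
    truth <- synth_truth(cfg$truth_preset)
    records <- gen_burned_plots(truth,
      n_plots = cfg$n_plots,
      trees_per_plot = cfg$trees_per_plot, seed = stage_seed(cfg, "synth")
    )
    stands <- gen_stand_set(truth,
      forests = cfg$forests, n_stands = cfg$n_stands,
      seed = stage_seed(cfg, "synth")
    )
    refs <- gen_historical_refs(truth$ref_preset, forests = cfg$forests)
    landscape <- gen_landscape(cfg$landscape_rows, cfg$landscape_cols,
      seed = stage_seed(cfg, "synth")
    )
    write_tree_records(records, file.path(cfg$out_dir, "tree_records.csv"))
    paths[[length(paths) + 1]] <- file.path(cfg$out_dir, "tree_records.csv")
    emit(stands, "stands.csv")
    emit(refs, "historical_refs.csv")
    lp <- write_landscape(landscape, file.path(cfg$out_dir, "landscape"))
    paths <- c(paths, lp)
    res$truth <- truth
    res$records <- records
    res$stands <- stands
    res$refs <- refs
    res$landscape <- landscape
  })

  # fit
  run_stage("fit", {
    set.seed(stage_seed(cfg, "fit"))
    models <- fit_species_models(res$records, min_trees = cfg$min_trees)
    if (length(models) == 0) abort("no species group had enough data to fit.")
    write_model_table(models, file.path(cfg$out_dir, "models.csv"))
    paths[[length(paths) + 1]] <- file.path(cfg$out_dir, "models.csv")
    res$models <- models
  })

  # curves
  run_stage("curves", {
    curves <- purrr::imap_dfr(res$models, function(m, g) {
      species_curves(m,
        dbh_classes = cfg$curve_classes, severity_grid = cfg$curve_grid,
        draws_per_point = cfg$curve_draws, years = cfg$years,
        seed = stage_seed(cfg, "curves")
      )
    })
    emit(curves, "curves.csv")
    res$curves <- curves
  })

  # simulate
  run_stage("simulate", {
    check_models_cover(res$stands, res$models)
    sweep <- severity_sweep(res$stands, res$models,
      grid = cfg$stand_grid,
      iterations = cfg$iterations, years = cfg$years,
      seed = stage_seed(cfg, "simulate"), share_draws = cfg$share_draws
    )
    emit(sweep, "sweep.csv")
    res$sweep <- sweep
  })

  # assess
  run_stage("assess", {
    ranges <- restorative_ranges(res$sweep, res$refs, thresholds = cfg$thresholds)
    emit(ranges, "ranges.csv")
    r75 <- ranges[ranges$threshold == 0.75 & !ranges$empty, ]
    gen <- purrr::map_dfr(unique(r75$metric), function(met) {
      g <- generalized_range(r75[r75$metric == met, ], grid = cfg$stand_grid)
      tibble::tibble(metric = met, lo = g[["lo"]], hi = g[["hi"]])
    })
    emit(gen, "generalized_ranges.csv")
    vrec <- gen_validation_set(res$models, res$stands,
      n = cfg$n_validation,
      seed = stage_seed(cfg, "assess"), grid = cfg$stand_grid,
      years = cfg$years
    )
    emit(vrec, "validation_records.csv")
    metrics <- validate_predictions(vrec, res$sweep, ranges, res$refs)
    emit(metrics, "validation_metrics.csv")
    res$ranges <- ranges
    res$generalized <- gen
    res$validation <- metrics
  })

  # classify
  run_stage("classify", {
    lf <- cfg$landscape_forest
    rng <- res$ranges[res$ranges$forest == lf, ]
    map <- classify_pixels(res$landscape, rng, metric = cfg$metric)
    write_ascii_grid(map$class, file.path(cfg$out_dir, "restoration_classes.asc"),
      cellsize = res$landscape$pixel_size
    )
    paths[[length(paths) + 1]] <- file.path(cfg$out_dir, "restoration_classes.asc")
    emit(map$legend, "class_legend.csv")
    summary <- class_summary(map, res$landscape)
    emit(summary, "class_summary.csv")
    res$class_map <- map
    res$class_summary <- summary
  })

  cfg_clean <- lapply(cfg, function(x) if (is.numeric(x) && length(x) > 12) range(x) else x)
  manifest <- list(
    package = "firewindow",
    version = as.character(utils::packageVersion("firewindow")),
    config = cfg_clean,
    stage_seeds = setNames(
      lapply(
        c("synth", "fit", "curves", "simulate", "assess", "classify"),
        function(s) stage_seed(cfg, s)
      ),
      c("synth", "fit", "curves", "simulate", "assess", "classify")
    ),
    checksums = as.list(tools::md5sum(sort(unique(unlist(paths)))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  res$manifest <- manifest
  invisible(res)
}
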