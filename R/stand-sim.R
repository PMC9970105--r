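# Stand-level fire simulation -------------------------------------------
#
# A stand is a 1-ha tree list: one row per inventory record with a species
# group, DBH (cm), and an expansion factor (trees/ha represented). Fire at a
# given RdNBR severity is simulated per record: a coefficient draw from the
# species' mortality model gives a probability of death three years
# post-fire; a uniform(0,1) comparison decides the record's fate; the whole
# expansion weight lives or dies with it, which keeps basal-area conservation
# exact.

#' Standardize a raw stand tree list
#'
#' Pools species codes into species groups, removes hardwoods and all trees
#' with DBH below 15 cm (a tree of exactly 15 cm is retained), and keeps
#' per-tree expansion factors so totals are per hectare. This matches the
#' harmonisation applied to both contemporary and historical stand data
#' before simulation.
#'
#' @param raw Tibble with columns `species` (or `species_group`), `dbh`
#'   (cm), and `expf` (expansion factor, trees/ha represented); any other
#'   columns (e.g. `stand_id`, `forest`, `forest_type`) are passed through.
#' @param min_dbh Retention threshold in cm (default 15; trees strictly
#'   below are removed).
#' @return The standardized tibble with a `species_group` column. If every
#'   tree is removed an empty tibble is returned with a warning.
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   species = c("ponderosa pine", "quaking aspen", "grand fir"),
#'   dbh = c(15, 40, 14.9), expf = c(5, 2, 10)
#' )
#' standardize_stand(raw) # keeps only the 15 cm ponderosa
standardize_stand <- function(raw, min_dbh = 15) {
  if (nrow(raw) == 0) abort("empty tree list.")
  if (!"expf" %in% names(raw)) abort("stand table needs an `expf` column.")
  if (any(raw$expf <= 0)) abort("`expf` must be positive.")
  out <- raw
  if (!"species_group" %in% names(out)) {
    if (!"species" %in% names(out)) abort("need a `species` or `species_group` column.")
    out$species_group <- pool_species(out$species)
  }
  out <- dplyr::filter(out, .data$species_group != "hardwood", .data$dbh >= min_dbh)
  if (nrow(out) == 0) {
    warn("standardization removed every tree (all hardwood or below the DBH threshold).")
  }
  out
}

# Check that every species group present has a model; errors naming groups.
check_models_cover <- function(trees, models) {
  present <- unique(trees$species_group)
  missing <- setdiff(present, names(models))
  if (length(missing) > 0) {
    abort(paste0(
      "no mortality model for species group(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# Vectorised mortality simulation over an expanded tree frame.
# trees: tibble with species_group, dbh, expf; sev: severity per row;
# iter: iteration index per row (used when share_draws = TRUE).
# Returns logical `live` per row.
.sim_live <- function(trees_grp, dbh, sev, iter, models, years, share_draws) {
  n <- length(dbh)
  p <- numeric(n)
  for (g in unique(trees_grp)) {
    rows <- which(trees_grp == g)
    model <- models[[g]]
    b <- model$coefficients
    se <- model$std_errors
    if (share_draws) {
      n_it <- max(iter[rows])
      dr <- lapply(names(b), function(nm) rnorm(n_it, b[[nm]], se[[nm]]))
      names(dr) <- names(b)
      ix <- iter[rows]
      co <- lapply(dr, function(v) v[ix])
    } else {
      co <- lapply(names(b), function(nm) rnorm(length(rows), b[[nm]], se[[nm]]))
      names(co) <- names(b)
    }
    lp <- co$intercept + co$dbh * dbh[rows] + co$severity * sev[rows] +
      co$years * years
    if (!is.null(co$dbh_severity)) lp <- lp + co$dbh_severity * dbh[rows] * sev[rows]
    p[rows] <- plogis(lp)
  }
  runif(n) >= p
}

# Aggregate an expanded simulated frame to StandOutcome rows.
.aggregate_outcomes <- function(gid, grid, n_grid, live, ba, expf, comp) {
  dead <- !live
  mat <- cbind(
    ba_live = ba * live,
    ba_dead = ba * dead,
    tph_live = expf * live,
    tph_dead = expf * dead,
    ba_yp = ba * (live & comp == "yellow_pine"),
    ba_df = ba * (live & comp == "douglas_fir"),
    ba_wf = ba * (live & comp == "white_fir"),
    ba_wl = ba * (live & comp == "western_larch"),
    ba_ot = ba * (live & comp == "other")
  )
  sums <- rowsum(mat, gid)
  gids <- as.integer(rownames(sums))
  ba_live <- sums[, "ba_live"]
  pos <- ba_live > 0
  prop <- function(col) ifelse(pos, sums[, col] / ba_live, 0)
  tibble::tibble(
    severity = grid[(gids - 1L) %% n_grid + 1L],
    iteration = (gids - 1L) %/% n_grid + 1L,
    ba_pre = unname(ba_live + sums[, "ba_dead"]),
    tph_pre = unname(sums[, "tph_live"] + sums[, "tph_dead"]),
    ba_live = unname(ba_live),
    tph_live = unname(sums[, "tph_live"]),
    ba_dead = unname(sums[, "ba_dead"]),
    tph_dead = unname(sums[, "tph_dead"]),
    prop_yellow_pine = unname(prop("ba_yp")),
    prop_douglas_fir = unname(prop("ba_df")),
    prop_white_fir = unname(prop("ba_wf")),
    prop_western_larch = unname(prop("ba_wl")),
    prop_other = unname(prop("ba_ot"))
  )
}

#' Simulate fire mortality in one stand at one severity
#'
#' Applies the Monte Carlo mortality process to every tree record of a
#' standardized stand: per record a coefficient draw, a probability of
#' mortality at (`dbh`, `severity`, `years`), and a uniform(0,1) comparison
#' (dead iff `u < p`).
#'
#' @param stand Standardized stand tibble (one stand) with `species_group`,
#'   `dbh`, `expf`.
#' @param models Named list of [mortality_model()] objects covering every
#'   species group present.
#' @param severity RdNBR severity.
#' @param years Years post-fire (default 3).
#' @param seed Optional seed.
#' @param share_draws Share one coefficient draw per species (instead of
#'   independent per-tree draws)?
#' @param tree_level Return the per-tree table (with a `live` flag) instead
#'   of the aggregated outcome?
#' @return A one-row outcome tibble with live/dead basal area (m^2/ha),
#'   density (trees/ha), and live basal-area composition proportions; or the
#'   per-tree tibble when `tree_level = TRUE`.
#' @export
simulate_stand <- function(stand, models, severity, years = 3, seed = NULL,
                           share_draws = FALSE, tree_level = FALSE) {
  if (nrow(stand) == 0) abort("empty stand.")
  check_models_cover(stand, models)
  if (!is.null(seed)) set.seed(seed)
  live <- .sim_live(
    stand$species_group, stand$dbh, rep(severity, nrow(stand)),
    rep(1L, nrow(stand)), models, years, share_draws
  )
  if (tree_level) {
    out <- stand
    out$severity <- severity
    out$live <- live
    return(out)
  }
  ba <- stand$expf * tree_basal_area(stand$dbh)
  out <- .aggregate_outcomes(
    rep(1L, nrow(stand)), severity, 1L, live, ba, stand$expf,
    comp_group(stand$species_group)
  )
  out$iteration <- 1L
  if ("stand_id" %in% names(stand)) out <- dplyr::bind_cols(stand_id = stand$stand_id[1], out)
  out
}

#' Sweep simulated fire across the severity gradient
#'
#' Simulates every stand at every severity of the grid for the stated number
#' of iterations, producing one outcome row per stand x severity x
#' iteration. Within a stand all severities and iterations are simulated
#' with independent per-tree coefficient draws and uniform comparisons
#' (vectorised, reproducible under `seed`).
#'
#' @param stands Standardized stand tibble with `stand_id` (and optionally
#'   `forest`, `forest_type`) columns.
#' @param models Named list of [mortality_model()] objects.
#' @param grid RdNBR severity grid (default -50..1000 by 5, 211 points).
#' @param iterations Iterations per stand x severity (default 5).
#' @param years Years post-fire (default 3).
#' @param seed Integer seed.
#' @param share_draws Share one coefficient draw per species x iteration?
#' @return Outcome tibble: `stand_id`, `forest`, `forest_type`, `severity`,
#'   `iteration`, pre-fire and live/dead basal area and density, and live
#'   basal-area proportions for yellow pine, Douglas-fir, white fir, western
#'   larch, and other species.
#' @export
severity_sweep <- function(stands, models, grid = seq(-50, 1000, by = 5),
                           iterations = 5, years = 3, seed = NULL,
                           share_draws = FALSE) {
  if (nrow(stands) == 0) abort("empty stand collection.")
  check_models_cover(stands, models)
  if (!is.null(seed)) set.seed(seed)
  m <- length(grid)
  ids <- unique(stands$stand_id)
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    st <- stands[stands$stand_id == ids[i], , drop = FALSE]
    n <- nrow(st)
    total <- n * m * iterations
    tree_ix <- rep.int(seq_len(n), m * iterations)
    sev_ix <- rep(rep(seq_len(m), each = n), times = iterations)
    iter <- rep(seq_len(iterations), each = n * m)
    dbh <- st$dbh[tree_ix]
    expf <- st$expf[tree_ix]
    grp <- st$species_group[tree_ix]
    sev <- grid[sev_ix]
    live <- .sim_live(grp, dbh, sev, iter, models, years, share_draws)
    gid <- (iter - 1L) * m + sev_ix
    out <- .aggregate_outcomes(
      gid, grid, m, live, expf * tree_basal_area(dbh), expf, comp_group(grp)
    )
    meta <- tibble::tibble(stand_id = ids[i])
    for (v in c("forest", "forest_type")) {
      if (v %in% names(st)) meta[[v]] <- st[[v]][1]
    }
    res[[i]] <- dplyr::bind_cols(meta[rep(1, nrow(out)), , drop = FALSE], out)
  }
  dplyr::bind_rows(res)
}

#' Smoothed live basal-area composition across severity
#'
#' Averages live basal-area proportions over all simulated outcomes with
#' positive live basal area at each severity, then smooths each species
#' group's series with the package smoother (LOESS, degree 1, span 0.25) and
#' renormalises the smoothed proportions to sum to one. Severities at which
#' every outcome burned to zero basal area are reported as gaps (dropped
#' with a message), never interpolated silently.
#'
#' @param outcomes Outcome tibble from [severity_sweep()].
#' @param span LOESS span (default 0.25).
#' @return Tibble with `severity`, `species_group` (composition group),
#'   `prop_mean`, `prop_smooth`.
#' @export
composition_profile <- function(outcomes, span = 0.25) {
  if (nrow(outcomes) == 0) abort("empty outcome collection.")
  pos <- dplyr::filter(outcomes, .data$ba_live > 0)
  gaps <- setdiff(unique(outcomes$severity), unique(pos$severity))
  if (length(gaps) > 0) {
    inform(paste0(
      "no outcomes with live basal area at ", length(gaps),
      " severities (gap, not interpolated): ",
      paste(sort(gaps), collapse = ", ")
    ))
  }
  long <- tidyr::pivot_longer(
    pos,
    cols = dplyr::all_of(paste0("prop_", c(
      "yellow_pine", "douglas_fir",
      "white_fir", "western_larch", "other"
    ))),
    names_to = "species_group", names_prefix = "prop_", values_to = "prop"
  )
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$severity, .data$species_group),
    prop_mean = mean(.data$prop), .groups = "drop"
  )
  out <- dplyr::mutate(
    dplyr::group_by(means, .data$species_group),
    prop_smooth = pmax(smooth_loess(.data$severity, .data$prop_mean, span = span), 0)
  )
  out <- dplyr::mutate(
    dplyr::group_by(dplyr::ungroup(out), .data$severity),
    prop_smooth = .data$prop_smooth / sum(.data$prop_smooth)
  )
  dplyr::arrange(dplyr::ungroup(out), .data$severity, .data$species_group)
}
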