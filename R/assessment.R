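# Restoration assessment -------------------------------------------------
#
# Simulated post-fire outcomes are compared to historical reference
# conditions (mean +/- 1 SD = the historical range of variation, HRV). The
# restorative severity window at a probability threshold is the longest
# contiguous run of grid severities where at least that fraction of
# simulated stands fall inside the HRV.

metric_column <- function(metric) {
  switch(metric,
    basal_area = "ba_live",
    density = "tph_live",
    abort('`metric` must be "basal_area" or "density".')
  )
}

#' Historical range of variation bounds
#'
#' `mean +/- 1 SD` for the requested metric, with the lower bound floored at
#' zero.
#'
#' @param ref One historical reference (a one-row tibble or list with
#'   `ba_mean`, `ba_sd`, `tph_mean`, `tph_sd`).
#' @param metric `"basal_area"` or `"density"`.
#' @return Named numeric `c(lo, hi)`.
#' @export
#' @examples
#' hrv_bounds(list(ba_mean = 60, ba_sd = 20), "basal_area") # c(40, 80)
hrv_bounds <- function(ref, metric = c("basal_area", "density")) {
  metric <- match.arg(metric)
  m <- if (metric == "basal_area") ref$ba_mean else ref$tph_mean
  s <- if (metric == "basal_area") ref$ba_sd else ref$tph_sd
  c(lo = max(m - s, 0), hi = m + s)
}

#' Fraction of simulated outcomes inside an interval
#'
#' Inclusive on both endpoints.
#'
#' @param outcomes Outcome tibble (any subset, typically one severity).
#' @param bounds Numeric `c(lo, hi)`.
#' @param metric `"basal_area"` or `"density"`.
#' @return Fraction in `[0, 1]`.
#' @export
proportion_within <- function(outcomes, bounds, metric = c("basal_area", "density")) {
  metric <- match.arg(metric)
  if (nrow(outcomes) == 0) abort("empty outcome collection.")
  x <- outcomes[[metric_column(metric)]]
  mean(x >= bounds[[1]] & x <= bounds[[2]])
}

#' Per-severity proportion of outcomes within the HRV
#'
#' @param outcomes Outcome tibble from [severity_sweep()] (one forest x
#'   forest-type group).
#' @param ref The matching historical reference row.
#' @param metric `"basal_area"` or `"density"`.
#' @return Tibble `severity`, `fraction`, ordered by severity.
#' @export
restoration_proportions <- function(outcomes, ref, metric = c("basal_area", "density")) {
  metric <- match.arg(metric)
  bounds <- hrv_bounds(ref, metric)
  x <- outcomes[[metric_column(metric)]]
  inside <- x >= bounds[[1]] & x <= bounds[[2]]
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(severity = outcomes$severity, inside = inside), .data$severity),
    fraction = mean(.data$inside), .groups = "drop"
  )
  dplyr::arrange(out, .data$severity)
}

#' Restorative severity range at a probability threshold
#'
#' The longest contiguous run of grid severities whose within-HRV fraction
#' is at least `threshold`, reported as its (min, max). Ties between
#' equal-length runs break toward lower severity; if no severity qualifies
#' the range is empty (`NA` endpoints).
#'
#' @param proportions Tibble `severity`, `fraction` from
#'   [restoration_proportions()].
#' @param threshold Probability threshold (typically 0.90, 0.75, or 0.50).
#' @param metric,forest,forest_type Optional labels carried into the result.
#' @return One-row tibble `metric`, `threshold`, `forest`, `forest_type`,
#'   `lo`, `hi`, `empty`.
#' @export
restorative_range <- function(proportions, threshold,
                              metric = NA_character_, forest = NA_character_,
                              forest_type = NA_character_) {
  props <- dplyr::arrange(proportions, .data$severity)
  ok <- props$fraction >= threshold
  lo <- NA_real_
  hi <- NA_real_
  if (any(ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])] # which.max -> first (lowest severity) on ties
    lo <- props$severity[starts[best]]
    hi <- props$severity[ends[best]]
  }
  tibble::tibble(
    metric = metric, threshold = threshold, forest = forest,
    forest_type = forest_type, lo = lo, hi = hi, empty = is.na(lo)
  )
}

#' Restorative ranges for every group, metric, and threshold
#'
#' Convenience wrapper: splits the sweep by forest x forest type, matches
#' each group to its historical reference, and computes
#' [restorative_range()] for both metrics at the stated thresholds.
#'
#' @param sweep Outcome tibble from [severity_sweep()] with `forest` and
#'   `forest_type` columns.
#' @param refs Historical reference tibble (one row per forest x type).
#' @param thresholds Probability thresholds (default 0.90, 0.75, 0.50).
#' @return Tibble of ranges, one row per group x metric x threshold.
#' @export
restorative_ranges <- function(sweep, refs, thresholds = c(0.90, 0.75, 0.50)) {
  groups <- dplyr::distinct(sweep, .data$forest, .data$forest_type)
  purrr::pmap_dfr(groups, function(forest, forest_type) {
    outc <- sweep[sweep$forest == forest & sweep$forest_type == forest_type, ]
    ref <- refs[refs$forest == forest & refs$forest_type == forest_type, ]
    if (nrow(ref) != 1) {
      abort(paste0("no unique historical reference for ", forest, " / ", forest_type))
    }
    purrr::map_dfr(c("basal_area", "density"), function(met) {
      props <- restoration_proportions(outc, ref, met)
      purrr::map_dfr(thresholds, function(th) {
        restorative_range(props, th,
          metric = met, forest = forest,
          forest_type = forest_type
        )
      })
    })
  })
}

#' Average restorative range across groups
#'
#' Unweighted arithmetic mean of the lower and of the upper endpoints across
#' forest x forest-type groups, for one metric and threshold. Empty member
#' ranges are excluded with a warning.
#'
#' @param ranges Range tibble (rows of [restorative_range()]).
#' @return One-row tibble `lo`, `hi`, `n_groups`.
#' @export
average_range <- function(ranges) {
  if (nrow(ranges) == 0) abort("empty range collection.")
  if (any(ranges$empty)) {
    warn(paste0("excluding ", sum(ranges$empty), " empty range(s) from the average."))
    ranges <- ranges[!ranges$empty, ]
  }
  if (nrow(ranges) == 0) abort("all ranges empty; no average possible.")
  tibble::tibble(lo = mean(ranges$lo), hi = mean(ranges$hi), n_groups = nrow(ranges))
}

#' Generalized restorative range across all groups
#'
#' Pools every grid severity lying inside any member range (with
#' multiplicity across groups) and returns the interquartile range (25th to
#' 75th percentile, linear interpolation) of the pooled values. This is the
#' "middle 50 percent" generalisation across forests and forest types,
#' conventionally applied to the >= 75 percent ranges.
#'
#' @param ranges Range tibble for one metric (nonempty members used).
#' @param grid The severity grid the ranges were derived on.
#' @return Named numeric `c(lo, hi)`.
#' @export
generalized_range <- function(ranges, grid = seq(-50, 1000, by = 5)) {
  if (nrow(ranges) == 0) abort("empty range collection.")
  ranges <- ranges[!ranges$empty, ]
  pool <- unlist(purrr::map2(ranges$lo, ranges$hi, function(lo, hi) {
    grid[grid >= lo & grid <= hi]
  }))
  if (length(pool) == 0) abort("no grid severities fall inside any range (empty pool).")
  q <- quantile(pool, c(0.25, 0.75), type = 7, names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Restorative window as a percent of the observed severity range
#'
#' `100 * (hi - lo) / (span_hi - span_lo)`, rounded to the nearest integer
#' percent.
#'
#' @param range One-row range tibble (or list with `lo`, `hi`).
#' @param observed_span Numeric `c(lo, hi)` of the observed severity range.
#' @return Integer percent.
#' @export
#' @examples
#' window_fraction(list(lo = 280, hi = 593), c(-52, 1394)) # 22
window_fraction <- function(range, observed_span) {
  width <- observed_span[[2]] - observed_span[[1]]
  if (width <= 0) abort("observed span must have positive width.")
  if (is.na(range$lo) || is.na(range$hi)) abort("empty range has no window fraction.")
  as.integer(round(100 * (range$hi - range$lo) / width))
}

#' Validate stand-level predictions against independent records
#'
#' Matches each validation record (observed post-fire basal area and
#' density, with its severity, forest type, and nearest forest) to the
#' simulated outcomes at the nearest grid severity for the same forest x
#' type, then computes, per metric: Mean Bias Error
#' (`mean(observed - modeled mean)`; negative means the model
#' overestimates), empirical 95 percent prediction-interval coverage (2.5th
#' to 97.5th percentile of matched simulated outcomes, with lower bounds
#' below 1 m^2/ha of basal area or 5 trees/ha rounded down to zero), and the
#' accuracy of classifying records as within/outside the >= 75 percent
#' restorative range (agreement between observed-metric-in-HRV and
#' severity-in-range).
#'
#' @param records Validation tibble: `severity`, `forest`, `forest_type`,
#'   `ba_obs`, `tph_obs`.
#' @param sweep Outcome tibble from [severity_sweep()].
#' @param ranges Range tibble containing the 0.75-threshold rows per group
#'   and metric (as from [restorative_ranges()]).
#' @param refs Historical reference tibble (for the HRV classification).
#' @return One-row tibble: `mbe_ba`, `mbe_tph`, `coverage_ba`,
#'   `coverage_tph`, `accuracy_ba`, `accuracy_tph`, `n_used`, `n_excluded`.
#' @export
validate_predictions <- function(records, sweep, ranges, refs) {
  grid <- sort(unique(sweep$severity))
  n0 <- nrow(records)
  rows <- vector("list", n0)
  excluded <- 0L
  for (i in seq_len(n0)) {
    rec <- records[i, ]
    sev <- grid[which.min(abs(grid - rec$severity))]
    matched <- sweep[sweep$forest == rec$forest &
      sweep$forest_type == rec$forest_type &
      sweep$severity == sev, ]
    ref <- refs[refs$forest == rec$forest & refs$forest_type == rec$forest_type, ]
    if (nrow(matched) == 0 || nrow(ref) != 1) {
      excluded <- excluded + 1L
      next
    }
    band <- function(x, floor_at) {
      q <- quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
      if (q[1] < floor_at) q[1] <- 0
      q
    }
    ba_band <- band(matched$ba_live, 1)
    tph_band <- band(matched$tph_live, 5)
    in_range <- function(met, obs) {
      rng <- ranges[ranges$forest == rec$forest &
        ranges$forest_type == rec$forest_type &
        ranges$metric == met & ranges$threshold == 0.75, ]
      if (nrow(rng) != 1 || rng$empty) {
        return(c(pred = FALSE, obs_in = NA))
      }
      b <- hrv_bounds(ref, met)
      c(
        pred = sev >= rng$lo & sev <= rng$hi,
        obs_in = obs >= b[[1]] & obs <= b[[2]]
      )
    }
    cb <- in_range("basal_area", rec$ba_obs)
    ct <- in_range("density", rec$tph_obs)
    rows[[i]] <- tibble::tibble(
      ba_obs = rec$ba_obs, tph_obs = rec$tph_obs,
      ba_mod = mean(matched$ba_live), tph_mod = mean(matched$tph_live),
      ba_cov = rec$ba_obs >= ba_band[1] & rec$ba_obs <= ba_band[2],
      tph_cov = rec$tph_obs >= tph_band[1] & rec$tph_obs <= tph_band[2],
      ba_agree = unname(cb["pred"] == cb["obs_in"]),
      tph_agree = unname(ct["pred"] == ct["obs_in"])
    )
  }
  if (excluded > 0) {
    warn(paste0(excluded, " validation record(s) could not be matched and were excluded."))
  }
  d <- dplyr::bind_rows(rows)
  if (nrow(d) == 0) abort("no validation records could be matched.")
  tibble::tibble(
    mbe_ba = mean(d$ba_obs - d$ba_mod),
    mbe_tph = mean(d$tph_obs - d$tph_mod),
    coverage_ba = mean(d$ba_cov),
    coverage_tph = mean(d$tph_cov),
    accuracy_ba = mean(d$ba_agree, na.rm = TRUE),
    accuracy_tph = mean(d$tph_agree, na.rm = TRUE),
    n_used = nrow(d),
    n_excluded = excluded
  )
}
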