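# Monte Carlo propagation of coefficient uncertainty --------------------
#
# Each fixed-effect point estimate is replaced by a draw from
# Normal(estimate, SE), independently per coefficient; probabilities are the
# inverse-logit of the resulting linear predictor with the plot random
# intercept held at 0 (a population-level prediction).

#' Sample coefficient vectors from a fitted mortality model
#'
#' Draws each fixed-effect coefficient independently from a normal
#' distribution centred on its point estimate with SD equal to its standard
#' error. Estimator covariance is deliberately ignored (independent
#' marginals).
#'
#' @param model A [mortality_model()] with standard errors.
#' @param n Number of draws.
#' @return Tibble with one row per draw: `.draw`, `species_group`, and one
#'   column per coefficient (`intercept`, `dbh`, `severity`, `years`, and
#'   `dbh_severity` for interaction models).
#' @export
#' @examples
#' m <- mortality_model("white_fir",
#'   coefficients = c(intercept = -4, dbh = -0.02, severity = 0.008, years = 0.15),
#'   std_errors = c(intercept = 0.2, dbh = 0.002, severity = 0.0004, years = 0.02)
#' )
#' draw_coefficients(m, n = 3)
draw_coefficients <- function(model, n = 1) {
  b <- model$coefficients
  se <- model$std_errors
  if (is.null(se) || anyNA(se)) abort("model has missing standard errors.")
  draws <- lapply(names(b), function(nm) rnorm(n, b[[nm]], se[[nm]]))
  names(draws) <- names(b)
  tibble::tibble(
    .draw = seq_len(n),
    species_group = model$species_group,
    !!!draws
  )
}

#' Probability of mortality from sampled coefficients
#'
#' Inverse-logit of the linear predictor
#' `intercept + dbh_coef * DBH + severity_coef * RdNBR + years_coef * years
#' (+ interaction * DBH * RdNBR)` with the plot random intercept fixed at 0.
#'
#' @param draw A one-or-more-row tibble from [draw_coefficients()], or a named
#'   numeric coefficient vector.
#' @param dbh Tree DBH in cm (> 0); recycled against the draws.
#' @param severity Burn severity in RdNBR units.
#' @param years Years post-fire.
#' @return Numeric vector of probabilities strictly in (0, 1).
#' @export
#' @examples
#' mortality_probability(
#'   c(intercept = -3, dbh = -0.05, severity = 0.006, years = 0.2),
#'   dbh = 40, severity = 500, years = 3
#' )
mortality_probability <- function(draw, dbh, severity, years = 3) {
  if (any(dbh <= 0)) abort("`dbh` must be positive.")
  if (is.data.frame(draw)) {
    co <- list(
      intercept = draw$intercept, dbh = draw$dbh, severity = draw$severity,
      years = draw$years
    )
    if ("dbh_severity" %in% names(draw)) co$dbh_severity <- draw$dbh_severity
  } else {
    co <- as.list(draw)
  }
  lp <- co$intercept + co$dbh * dbh + co$severity * severity + co$years * years
  if (!is.null(co$dbh_severity)) lp <- lp + co$dbh_severity * dbh * severity
  plogis(lp)
}

# Shared smoother: tri-cube weighted local linear regression, the
# conventional LOESS with degree-1 polynomial; span 0.25 throughout the
# package unless overridden.
smooth_loess <- function(x, y, span = 0.25, degree = 1) {
  keep <- is.finite(y)
  n <- sum(keep)
  if (n < 5) {
    return(y) # too few points to smooth; pass through
  }
  # widen the span on short series so each local fit keeps enough points
  span <- max(span, (degree + 2) / n)
  # collinearity warnings from constant stretches are numerical noise
  fit <- suppressWarnings(loess(y ~ x,
    data = data.frame(x = x[keep], y = y[keep]),
    span = span, degree = degree, family = "gaussian",
    control = loess.control(surface = "direct")
  ))
  out <- rep(NA_real_, length(x))
  out[keep] <- suppressWarnings(predict(fit, newdata = data.frame(x = x[keep])))
  out
}

#' @importFrom stats loess.control
NULL

#' Size-class mortality probability curves across the severity gradient
#'
#' For each DBH size class and each severity on the grid, samples
#' `draws_per_point` coefficient vectors ([draw_coefficients()]) and converts
#' them to mortality probabilities at the stated years post-fire. Per-severity
#' sample means and SDs are then smoothed with tri-cube weighted local linear
#' regression (degree 1, span 0.25). Size classes above the largest DBH seen
#' in the fitting data are omitted.
#'
#' @param model A [mortality_model()].
#' @param dbh_classes DBH size classes in cm (default 10, 20, 60).
#' @param severity_grid Nondecreasing RdNBR grid (default -50..1350 by 10).
#' @param draws_per_point Coefficient draws per class-by-severity point
#'   (default 75).
#' @param years Years post-fire (default 3, capturing delayed mortality).
#' @param seed Optional integer seed for reproducible draws.
#' @param span LOESS span (default 0.25).
#' @param keep_draws Attach all sampled probabilities as a `samples`
#'   list-column?
#' @return Tibble with columns `species_group`, `dbh_class`, `severity`,
#'   `mean_p`, `sd_p`, `smooth_mean`, `smooth_sd` (and optionally `samples`).
#' @export
species_curves <- function(model, dbh_classes = c(10, 20, 60),
                           severity_grid = seq(-50, 1350, by = 10),
                           draws_per_point = 75, years = 3, seed = NULL,
                           span = 0.25, keep_draws = FALSE) {
  if (length(dbh_classes) == 0) abort("`dbh_classes` must be nonempty.")
  if (is.unsorted(severity_grid)) abort("`severity_grid` must be nondecreasing.")
  if (!is.null(seed)) set.seed(seed)
  if (!is.na(model$max_dbh)) {
    drop <- dbh_classes > model$max_dbh
    if (any(drop)) {
      inform(paste0(
        "omitting size classes beyond max observed DBH (", model$max_dbh,
        " cm): ", paste(dbh_classes[drop], collapse = ", ")
      ))
      dbh_classes <- dbh_classes[!drop]
    }
    if (length(dbh_classes) == 0) abort("all size classes exceed the observed DBH range.")
  }
  m <- length(severity_grid)
  purrr::map_dfr(dbh_classes, function(cls) {
    draws <- draw_coefficients(model, n = m * draws_per_point)
    sev <- rep(severity_grid, each = draws_per_point)
    p <- mortality_probability(draws, dbh = cls, severity = sev, years = years)
    pm <- matrix(p, nrow = draws_per_point) # columns = severities
    mean_p <- colMeans(pm)
    sd_p <- apply(pm, 2, sd)
    out <- tibble::tibble(
      species_group = model$species_group,
      dbh_class = cls,
      severity = severity_grid,
      mean_p = mean_p,
      sd_p = sd_p,
      smooth_mean = smooth_loess(severity_grid, mean_p, span = span),
      smooth_sd = smooth_loess(severity_grid, sd_p, span = span)
    )
    if (keep_draws) out$samples <- lapply(seq_len(m), function(j) pm[, j])
    out
  })
}
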