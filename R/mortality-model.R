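# Species-level mortality models ----------------------------------------
#
# Binomial (live/dead) mixed models on the logit scale with a Gaussian plot
# random intercept:
#
#   logit p = b0 + b1 DBH + b2 Severity + b3 Years [+ b4 DBH*Severity] + u_plot
#
# Fitting is delegated to lme4::glmer. Predictors are z-scored internally for
# numerical stability and the coefficient vector and covariance matrix are
# mapped back to the raw scale, so reported estimates and standard errors are
# on natural units (per cm, per RdNBR unit, per year).

#' Construct a mortality model object
#'
#' Builds a `mortality_model` from known coefficients, e.g. for simulation
#' with a ground-truth model or for tests. [fit_mortality_model()] returns
#' the same class from data.
#'
#' @param species_group Species group label.
#' @param coefficients Named numeric vector with elements `intercept`, `dbh`,
#'   `severity`, `years` and optionally `dbh_severity` (logit scale).
#' @param std_errors Standard errors matching `coefficients` (>= 0). Defaults
#'   to all zero (a degenerate, point-mass model).
#' @param random_intercept_sd Plot random-intercept SD on the logit scale.
#' @param n_trees,n_plots Sample sizes behind the fit (may be `NA` for
#'   constructed models).
#' @param log_likelihood Maximised marginal log-likelihood.
#' @param r2_marginal,r2_conditional Variance explained on the link scale.
#' @param max_dbh Largest DBH observed in the fitting data (cm); used to drop
#'   out-of-range size classes from prediction curves.
#' @param std_coefficients,std_std_errors Optional coefficients/SEs from the
#'   z-scored fit (for effect-size display).
#' @param scaling Optional list of predictor centers/scales from the fit.
#' @return An object of class `mortality_model`.
#' @export
mortality_model <- function(species_group, coefficients, std_errors = NULL,
                            random_intercept_sd = 0,
                            n_trees = NA_integer_, n_plots = NA_integer_,
                            log_likelihood = NA_real_,
                            r2_marginal = NA_real_, r2_conditional = NA_real_,
                            max_dbh = NA_real_,
                            std_coefficients = NULL, std_std_errors = NULL,
                            scaling = NULL) {
  need <- c("intercept", "dbh", "severity", "years")
  if (!all(need %in% names(coefficients))) {
    abort(paste0(
      "`coefficients` must be named with at least: ",
      paste(need, collapse = ", ")
    ))
  }
  has_interaction <- "dbh_severity" %in% names(coefficients)
  ord <- c(need, if (has_interaction) "dbh_severity")
  coefficients <- coefficients[ord]
  if (is.null(std_errors)) std_errors <- setNames(rep(0, length(ord)), ord)
  std_errors <- std_errors[ord]
  if (length(std_errors) != length(coefficients) || anyNA(std_errors)) {
    abort("`std_errors` must match `coefficients` and contain no missing values.")
  }
  if (any(std_errors < 0)) abort("`std_errors` must be >= 0.")
  if (is.na(random_intercept_sd) || random_intercept_sd < 0) {
    abort("`random_intercept_sd` must be >= 0.")
  }
  k <- length(coefficients) + 1L # fixed effects + RE SD
  aicc_val <- if (!is.na(log_likelihood) && !is.na(n_trees) && n_trees > k + 1) {
    aicc(log_likelihood, k = k, n = n_trees)
  } else {
    NA_real_
  }
  structure(
    list(
      species_group = species_group,
      has_interaction = has_interaction,
      coefficients = coefficients,
      std_errors = std_errors,
      random_intercept_sd = random_intercept_sd,
      n_trees = n_trees,
      n_plots = n_plots,
      log_likelihood = log_likelihood,
      aicc = aicc_val,
      r2_marginal = r2_marginal,
      r2_conditional = r2_conditional,
      max_dbh = max_dbh,
      std_coefficients = std_coefficients,
      std_std_errors = std_std_errors,
      scaling = scaling
    ),
    class = "mortality_model"
  )
}

#' @export
print.mortality_model <- function(x, ...) {
  cat(
    "<mortality_model> ", x$species_group,
    if (x$has_interaction) " (DBH x severity interaction)" else "", "\n",
    sep = ""
  )
  est <- rbind(estimate = x$coefficients, std_error = x$std_errors)
  print(round(est, 6))
  cat(
    "plot RE SD: ", signif(x$random_intercept_sd, 4),
    " | trees: ", x$n_trees, " | plots: ", x$n_plots, "\n",
    sep = ""
  )
  if (!is.na(x$aicc)) {
    cat(
      "logLik: ", round(x$log_likelihood, 2), " | AICc: ", round(x$aicc, 2),
      " | R2m: ", round(x$r2_marginal, 3), " | R2c: ", round(x$r2_conditional, 3), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @method tidy mortality_model
#' @export
tidy.mortality_model <- function(x, ...) {
  tibble::tibble(
    species_group = x$species_group,
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors)
  )
}

#' @method glance mortality_model
#' @export
glance.mortality_model <- function(x, ...) {
  tibble::tibble(
    species_group = x$species_group,
    has_interaction = x$has_interaction,
    n_trees = x$n_trees,
    n_plots = x$n_plots,
    random_intercept_sd = x$random_intercept_sd,
    logLik = x$log_likelihood,
    AICc = x$aicc,
    r2_marginal = x$r2_marginal,
    r2_conditional = x$r2_conditional
  )
}

# Validate a tree-record table for fitting.
check_tree_records <- function(records) {
  need <- c("plot_id", "dbh", "severity", "years_post_fire", "status")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("tree records are missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!all(records$status %in% c("live", "dead"))) {
    abort('`status` must be "live" or "dead".')
  }
  if (any(records$dbh <= 0 | records$dbh > 300)) {
    abort("`dbh` must lie in (0, 300] cm.")
  }
  if (any(!is.finite(records$severity))) abort("`severity` must be finite.")
  invisible(records)
}

# Linear map from coefficients of the z-scored fit to raw-scale coefficients.
# Order: intercept, dbh, severity, years [, dbh:severity]. Returns the matrix
# T with raw = T %*% scaled.
.unscale_transform <- function(center, scale, has_interaction) {
  md <- center["dbh"]; ms <- center["severity"]; my <- center["years"]
  sd_d <- scale["dbh"]; sd_s <- scale["severity"]; sd_y <- scale["years"]
  p <- if (has_interaction) 5L else 4L
  tr <- matrix(0, p, p)
  tr[1, 1] <- 1
  tr[1, 2] <- -md / sd_d
  tr[1, 3] <- -ms / sd_s
  tr[1, 4] <- -my / sd_y
  tr[2, 2] <- 1 / sd_d
  tr[3, 3] <- 1 / sd_s
  tr[4, 4] <- 1 / sd_y
  if (has_interaction) {
    tr[1, 5] <- md * ms / (sd_d * sd_s)
    tr[2, 5] <- -ms / (sd_d * sd_s)
    tr[3, 5] <- -md / (sd_d * sd_s)
    tr[5, 5] <- 1 / (sd_d * sd_s)
  }
  tr
}

#' Fit a species-level mortality mixed model
#'
#' Fits a binomial-logit GLMM of individual-tree mortality on DBH, burn
#' severity (RdNBR), and years surveyed post-fire, with a Gaussian plot
#' random intercept, for the tree records of a single species group.
#'
#' The plot intercept is integrated out of the Bernoulli likelihood by
#' adaptive Gauss-Hermite quadrature (`nAGQ` nodes; the default 1 is the
#' Laplace approximation). Predictors are z-scored internally before fitting
#' and the estimates and covariance are mapped back to natural units, which
#' keeps the optimisation well-conditioned despite DBH, RdNBR, and years
#' living on very different scales.
#'
#' @param records Tibble of tree records for one species group with columns
#'   `plot_id`, `dbh` (cm), `severity` (RdNBR), `years_post_fire`, `status`
#'   (`"live"`/`"dead"`).
#' @param include_interaction Add a DBH-by-severity interaction term?
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature nodes (1 =
#'   Laplace).
#' @param min_trees Refuse to fit below this many trees (default 50).
#' @param scale_predictors Z-score predictors internally (recommended); the
#'   returned coefficients are always on the raw scale either way.
#' @return A [mortality_model()] with raw-scale coefficients and SEs, the
#'   plot random-intercept SD, log-likelihood, AICc, and Nakagawa marginal /
#'   conditional R^2 on the link scale.
#' @export
#' @examples
#' truth <- synth_truth("default")
#' recs <- gen_burned_plots(truth, n_plots = 40, trees_per_plot = 30, seed = 1)
#' fit <- fit_mortality_model(dplyr::filter(recs, species_group == "white_fir"))
#' glance(fit)
fit_mortality_model <- function(records, include_interaction = FALSE,
                                nAGQ = 1, min_trees = 50,
                                scale_predictors = TRUE) {
  check_tree_records(records)
  n <- nrow(records)
  if (n < min_trees) {
    abort(paste0(
      "refusing to fit: ", n, " trees < minimum of ", min_trees,
      " (lower `min_trees` to override)"
    ))
  }
  n_plots <- length(unique(records$plot_id))
  if (n_plots < 2) abort("need at least 2 plots to estimate a plot random effect.")
  y <- as.integer(records$status == "dead")
  if (length(unique(y)) < 2) {
    abort("inestimable: all trees share one outcome class (no live/dead contrast).")
  }
  grp <- if ("species_group" %in% names(records)) records$species_group[1] else "unknown"

  d <- data.frame(
    y = y,
    dbh = records$dbh,
    severity = records$severity,
    years = as.numeric(records$years_post_fire),
    plot = factor(records$plot_id)
  )
  for (v in c("dbh", "severity", "years")) {
    if (sd(d[[v]]) == 0) abort(paste0("predictor `", v, "` has zero variance."))
  }
  center <- c(dbh = 0, severity = 0, years = 0)
  scl <- c(dbh = 1, severity = 1, years = 1)
  if (scale_predictors) {
    center <- c(dbh = mean(d$dbh), severity = mean(d$severity), years = mean(d$years))
    scl <- c(dbh = sd(d$dbh), severity = sd(d$severity), years = sd(d$years))
    d$dbh <- (d$dbh - center["dbh"]) / scl["dbh"]
    d$severity <- (d$severity - center["severity"]) / scl["severity"]
    d$years <- (d$years - center["years"]) / scl["years"]
  }
  form <- if (include_interaction) {
    y ~ dbh + severity + years + dbh:severity + (1 | plot)
  } else {
    y ~ dbh + severity + years + (1 | plot)
  }
  fit <- withCallingHandlers(
    lme4::glmer(form, data = d, family = binomial(link = "logit"), nAGQ = nAGQ),
    message = function(m) invokeRestart("muffleMessage")
  )
  beta_s <- lme4::fixef(fit)
  vc_s <- as.matrix(vcov(fit))
  if (any(!is.finite(beta_s)) || any(!is.finite(diag(vc_s)))) {
    abort("inestimable: fit produced non-finite coefficients or variances (possible complete separation).")
  }
  tr <- .unscale_transform(center, scl, include_interaction)
  beta <- drop(tr %*% beta_s)
  vc <- tr %*% vc_s %*% t(tr)
  se <- sqrt(pmax(diag(vc), 0))
  nm <- c("intercept", "dbh", "severity", "years", if (include_interaction) "dbh_severity")
  names(beta) <- nm
  names(se) <- nm
  re_sd <- sqrt(unname(lme4::VarCorr(fit)$plot[1, 1]))
  ll <- as.numeric(logLik(fit))

  model <- mortality_model(
    species_group = grp,
    coefficients = beta,
    std_errors = se,
    random_intercept_sd = re_sd,
    n_trees = n,
    n_plots = n_plots,
    log_likelihood = ll,
    max_dbh = max(records$dbh),
    std_coefficients = beta_s,
    std_std_errors = sqrt(diag(vc_s)),
    scaling = list(center = center, scale = scl)
  )
  r2 <- nakagawa_r2(model, records)
  model$r2_marginal <- r2[["r2_marginal"]]
  model$r2_conditional <- r2[["r2_conditional"]]
  model
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1) / (n - k - 1)`. For a
#' [mortality_model()], `k` counts the fixed effects plus the random-intercept
#' SD and `n` is the number of trees.
#'
#' @param object A `mortality_model`, or a numeric log-likelihood.
#' @param k Number of estimated parameters (numeric method).
#' @param n Number of observations (numeric method).
#' @param ... Unused.
#' @return AICc as a single number.
#' @export
#' @examples
#' aicc(0, k = 2, n = 100) # 4 + 12/97
aicc <- function(object, ...) UseMethod("aicc")

#' @rdname aicc
#' @export
aicc.numeric <- function(object, k, n, ...) {
  if (n <= k + 1) abort("AICc undefined: need n > k + 1.")
  -2 * object + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
aicc.mortality_model <- function(object, ...) {
  k <- length(object$coefficients) + 1L
  aicc(object$log_likelihood, k = k, n = object$n_trees)
}

#' Select between main-effects and interaction mortality models
#'
#' Keeps the interaction model only when it improves AICc by at least 2
#' (`aicc(main) - aicc(interaction) >= 2`); otherwise the simpler
#' main-effects model is retained. Both models must be fit to the same
#' records. The comparison is conventionally offered only for species with
#' more than 2,000 observations; that gate is the caller's responsibility
#' (see [fit_species_models()]).
#'
#' @param main Main-effects `mortality_model`.
#' @param interaction Interaction `mortality_model`.
#' @return The selected `mortality_model`.
#' @export
select_mortality_model <- function(main, interaction) {
  if (!identical(main$n_trees, interaction$n_trees)) {
    abort("models were not fit on the same records (n_trees differ).")
  }
  delta <- aicc(main) - aicc(interaction)
  if (is.na(delta)) abort("AICc unavailable for one of the models.")
  if (delta >= 2) interaction else main
}

#' Nakagawa link-scale R-squared for a mortality model
#'
#' Marginal and conditional variance explained on the logit link scale using
#' the theoretical distribution-specific variance `pi^2 / 3`:
#' `R2m = s2_f / (s2_f + s2_a + pi^2/3)` and
#' `R2c = (s2_f + s2_a) / (s2_f + s2_a + pi^2/3)`, where `s2_f` is the
#' variance of the fixed-effect linear predictor over the fitting records and
#' `s2_a` the plot random-intercept variance.
#'
#' @param model A `mortality_model`.
#' @param records The tree records the model was fit on.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
nakagawa_r2 <- function(model, records) {
  lp <- linear_predictor(
    model$coefficients, records$dbh, records$severity,
    as.numeric(records$years_post_fire)
  )
  s2f <- var(lp)
  s2a <- model$random_intercept_sd^2
  s2d <- pi^2 / 3
  tot <- s2f + s2a + s2d
  c(r2_marginal = s2f / tot, r2_conditional = (s2f + s2a) / tot)
}

# Fixed-effect linear predictor on the logit scale (vectorised).
linear_predictor <- function(coefs, dbh, severity, years) {
  lp <- coefs[["intercept"]] + coefs[["dbh"]] * dbh +
    coefs[["severity"]] * severity + coefs[["years"]] * years
  if ("dbh_severity" %in% names(coefs)) {
    lp <- lp + coefs[["dbh_severity"]] * dbh * severity
  }
  lp
}

#' Standardized effect estimates for cross-species comparison
#'
#' Refits the mortality model with DBH, severity, and years z-scored within
#' the species, and returns the resulting coefficients with standard errors.
#' On this scale effect sizes are comparable across predictors and species
#' (per-SD changes in the log-odds of mortality).
#'
#' @inheritParams fit_mortality_model
#' @return Tibble with columns `species_group`, `predictor`, `estimate`,
#'   `std_error` (intercept excluded).
#' @export
standardized_effects <- function(records, include_interaction = FALSE,
                                 nAGQ = 1, min_trees = 50) {
  fit <- fit_mortality_model(records, include_interaction, nAGQ, min_trees,
    scale_predictors = TRUE
  )
  nm <- names(fit$std_coefficients)
  keep <- nm != "(Intercept)"
  pred <- sub("dbh:severity", "dbh_severity", nm[keep], fixed = TRUE)
  tibble::tibble(
    species_group = fit$species_group,
    predictor = pred,
    estimate = unname(fit$std_coefficients[keep]),
    std_error = unname(fit$std_std_errors[keep])
  )
}

#' Fit mortality models for every species group in a record table
#'
#' Convenience wrapper that fits one model per species group, considers the
#' DBH-by-severity interaction only for groups with more than
#' `interaction_min_trees` records, and applies the AICc selection rule of
#' [select_mortality_model()]. Groups with too few trees or a single outcome
#' class are skipped with a warning.
#'
#' @param records Tree-record tibble with a `species_group` column.
#' @param interaction_min_trees Minimum records before an interaction model
#'   is considered (default 2000).
#' @param ... Passed to [fit_mortality_model()].
#' @return Named list of `mortality_model` objects keyed by species group.
#' @export
fit_species_models <- function(records, interaction_min_trees = 2000, ...) {
  groups <- unique(records$species_group)
  models <- list()
  for (g in groups) {
    recs <- dplyr::filter(records, .data$species_group == g)
    main <- tryCatch(fit_mortality_model(recs, include_interaction = FALSE, ...),
      error = function(e) {
        warn(paste0("skipping ", g, ": ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(main)) next
    model <- main
    if (nrow(recs) > interaction_min_trees) {
      inter <- tryCatch(
        fit_mortality_model(recs, include_interaction = TRUE, ...),
        error = function(e) NULL
      )
      if (!is.null(inter)) model <- select_mortality_model(main, inter)
    }
    models[[g]] <- model
  }
  models
}
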