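# Builders shared across test files. Everything is generated in code; no
# stored fixtures.

# A point-mass mortality model (all SEs zero unless given).
toy_model <- function(species_group = "white_fir",
                      intercept = -4, dbh = -0.02, severity = 0.008,
                      years = 0.15, dbh_severity = NULL, se = 0,
                      re_sd = 0, ...) {
  co <- c(intercept = intercept, dbh = dbh, severity = severity, years = years)
  if (!is.null(dbh_severity)) co <- c(co, dbh_severity = dbh_severity)
  se_vec <- stats::setNames(rep(se, length(co)), names(co))
  mortality_model(species_group, co,
    std_errors = se_vec,
    random_intercept_sd = re_sd, ...
  )
}

# A model whose mortality probability is constant p everywhere.
constant_p_model <- function(p, species_group = "white_fir") {
  toy_model(species_group, intercept = stats::qlogis(p), dbh = 0, severity = 0, years = 0)
}

# A one-stand tibble of n identical trees.
toy_stand <- function(n = 100, dbh = 30, species_group = "white_fir",
                      expf = 1, stand_id = "s1", forest = "Malheur",
                      forest_type = "dry_mixed_conifer") {
  tibble::tibble(
    stand_id = stand_id, forest = forest, forest_type = forest_type,
    species_group = rep_len(species_group, n), dbh = rep_len(dbh, n),
    expf = rep_len(expf, n)
  )
}

# A truth whose burned plots contain a single species group.
single_species_truth <- function(group = "white_fir", re_sd = 0.5) {
  truth <- synth_truth("default", re_sd = re_sd)
  mix <- stats::setNames(rep(0, length(truth$mix_burned)), names(truth$mix_burned))
  mix[group] <- 1
  truth$mix_burned <- mix
  truth
}

# Longest contiguous >= threshold run by brute-force O(n^2) scan; ties to the
# lowest severity. Independent of the package's rle-based implementation.
brute_force_range <- function(severity, fraction, threshold) {
  n <- length(severity)
  best <- c(NA_real_, NA_real_)
  best_len <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(fraction[i:j] >= threshold)) {
        if (j - i + 1L > best_len) {
          best_len <- j - i + 1L
          best <- c(severity[i], severity[j])
        }
      } else {
        break
      }
    }
  }
  best
}

# Random unimodal proportion map on a severity grid (rises then falls), the
# shape severity-response curves take; guarantees single-interval threshold
# sets.
random_unimodal_map <- function(grid, seed) {
  set.seed(seed)
  n <- length(grid)
  peak <- sample(seq(2, n - 1), 1)
  up <- sort(runif(peak))
  down <- sort(runif(n - peak), decreasing = TRUE)
  tibble::tibble(severity = grid, fraction = c(up, down))
}
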