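# HRV comparison, restorative severity windows, their generalisation, and
# the validation metrics.

test_that("HRV bounds are mean +/- 1 SD floored at zero", {
  expect_equal(
    hrv_bounds(list(ba_mean = 60, ba_sd = 20), "basal_area"),
    c(lo = 40, hi = 80)
  )
  expect_equal(
    hrv_bounds(list(ba_mean = 5, ba_sd = 10), "basal_area"),
    c(lo = 0, hi = 15)
  )
  expect_equal(
    hrv_bounds(list(tph_mean = 100, tph_sd = 0), "density"),
    c(lo = 100, hi = 100)
  )
})

test_that("proportion_within counts inclusively and matches a recount", {
  outc <- tibble::tibble(ba_live = c(39.9, 40, 80, 80.1), tph_live = 0)
  expect_equal(proportion_within(outc, c(40, 80), "basal_area"), 0.5)
  expect_equal(proportion_within(outc, c(0, 100), "basal_area"), 1)

  set.seed(3)
  big <- tibble::tibble(ba_live = runif(1000, 0, 100), tph_live = 0)
  got <- proportion_within(big, c(30, 70), "basal_area")
  recount <- sum(vapply(
    big$ba_live,
    function(x) x >= 30 && x <= 70, TRUE
  )) / 1000
  expect_equal(got, recount, tolerance = 1e-12)
  # order invariance
  expect_equal(
    proportion_within(big[sample(1000), ], c(30, 70), "basal_area"), got
  )
})

test_that("restorative_range finds the longest contiguous qualifying run", {
  toy <- tibble::tibble(
    severity = c(400, 405, 410, 415, 420),
    fraction = c(0.6, 0.8, 0.9, 0.8, 0.4)
  )
  r <- restorative_range(toy, 0.75)
  expect_equal(c(r$lo, r$hi), c(405, 415))

  none <- restorative_range(toy, 0.95)
  expect_true(none$empty)
  expect_true(is.na(none$lo))

  # equal-length runs break toward lower severity
  tie <- tibble::tibble(severity = c(0, 5, 10), fraction = c(1, 0, 1))
  r <- restorative_range(tie, 0.9)
  expect_equal(c(r$lo, r$hi), c(0, 0))
})

test_that("ranges agree with a brute-force scan and nest across thresholds", {
  grid <- seq(-50, 1000, by = 25)
  for (s in 1:25) {
    # arbitrary fraction curves: oracle equivalence of the run finder
    set.seed(s)
    rough <- tibble::tibble(severity = grid, fraction = runif(length(grid)))
    for (th in c(0.5, 0.75, 0.9)) {
      got <- restorative_range(rough, th)
      exp <- brute_force_range(rough$severity, rough$fraction, th)
      expect_equal(c(got$lo, got$hi), exp)
    }

    # unimodal curves (the shape severity responses take): nested windows
    uni <- random_unimodal_map(grid, seed = 1000 + s)
    r90 <- restorative_range(uni, 0.9)
    r75 <- restorative_range(uni, 0.75)
    r50 <- restorative_range(uni, 0.5)
    if (!r90$empty) {
      expect_true(!r75$empty && r75$lo <= r90$lo && r90$hi <= r75$hi)
    }
    if (!r75$empty) {
      expect_true(!r50$empty && r50$lo <= r75$lo && r75$hi <= r50$hi)
    }
  }
})

test_that("average_range is the unweighted endpoint mean", {
  rngs <- tibble::tibble(
    metric = "basal_area", threshold = 0.9, forest = c("A", "B"),
    forest_type = "dry_mixed_conifer", lo = c(300, 400), hi = c(500, 600),
    empty = FALSE
  )
  expect_equal(average_range(rngs)[, c("lo", "hi")], tibble::tibble(lo = 350, hi = 550))

  same <- rngs
  same$lo <- 420
  same$hi <- 510
  expect_equal(average_range(same)$lo, 420)
  expect_equal(average_range(same)$hi, 510)

  with_empty <- rngs
  with_empty$empty[2] <- TRUE
  expect_warning(avg <- average_range(with_empty), "excluding")
  expect_equal(avg$lo, 300)

  # independent summation oracle
  set.seed(9)
  many <- tibble::tibble(
    metric = "x", threshold = 0.75, forest = letters[1:10],
    forest_type = "t", lo = runif(10, 0, 400), hi = runif(10, 500, 900),
    empty = FALSE
  )
  avg <- average_range(many)
  expect_equal(avg$lo, sum(many$lo) / 10, tolerance = 1e-12)
  expect_equal(avg$hi, sum(many$hi) / 10, tolerance = 1e-12)
})

test_that("generalized_range is the IQR of pooled in-range grid severities", {
  grid <- seq(-50, 1000, by = 5)
  one <- tibble::tibble(
    metric = "basal_area", threshold = 0.75, forest = "A",
    forest_type = "t", lo = 400, hi = 500, empty = FALSE
  )
  # 21 grid values 400..500: quartiles at 425 and 475
  expect_equal(generalized_range(one, grid), c(lo = 425, hi = 475))

  # identical member ranges: IQR stays within the shared range
  four <- dplyr::bind_rows(one, one, one, one)
  g <- generalized_range(four, grid)
  expect_true(g[["lo"]] >= 400 && g[["hi"]] <= 500)

  # explicit-enumeration oracle on random range sets
  set.seed(11)
  for (i in 1:10) {
    lo <- sort(sample(grid, 3))
    rngs <- tibble::tibble(
      metric = "x", threshold = 0.75, forest = letters[1:3],
      forest_type = "t", lo = lo, hi = pmin(lo + sample(50:300, 3), 1000),
      empty = FALSE
    )
    pool <- unlist(mapply(function(l, h) grid[grid >= l & grid <= h],
      rngs$lo, rngs$hi,
      SIMPLIFY = FALSE
    ))
    expect_equal(
      generalized_range(rngs, grid),
      c(
        lo = unname(stats::quantile(pool, 0.25)),
        hi = unname(stats::quantile(pool, 0.75))
      )
    )
  }
  empty <- one
  empty$empty <- TRUE
  expect_error(generalized_range(empty, grid), "empty pool")
})

test_that("window_fraction reproduces the printed percentages", {
  span <- c(-52, 1394)
  expect_equal(window_fraction(list(lo = 280, hi = 593), span), 22L)
  expect_equal(window_fraction(list(lo = 444, hi = 624), span), 12L)
  expect_equal(window_fraction(list(lo = 499, hi = 581), span), 6L)
  expect_equal(window_fraction(list(lo = -52, hi = 1394), span), 100L)
  expect_error(window_fraction(list(lo = 100, hi = 200), c(300, 300)), "positive width")
  expect_error(window_fraction(list(lo = NA, hi = NA), span), "empty")
})

test_that("validation metrics follow the stated formulas", {
  # degenerate sweep: outcomes constant at the modeled means
  sweep <- dplyr::bind_rows(
    tibble::tibble(
      stand_id = "s1", forest = "A", forest_type = "dry_mixed_conifer",
      severity = 100, iteration = 1:20, ba_live = 12, tph_live = 110
    ),
    tibble::tibble(
      stand_id = "s1", forest = "A", forest_type = "dry_mixed_conifer",
      severity = 200, iteration = 1:20, ba_live = 19, tph_live = 90
    )
  )
  refs <- tibble::tibble(
    forest = "A", forest_type = "dry_mixed_conifer",
    ba_mean = 15, ba_sd = 5, tph_mean = 100, tph_sd = 30
  )
  ranges <- tidyr::crossing(
    metric = c("basal_area", "density"),
    tibble::tibble(
      threshold = 0.75, forest = "A",
      forest_type = "dry_mixed_conifer",
      lo = 50, hi = 150, empty = FALSE
    )
  )
  records <- tibble::tibble(
    severity = c(101, 199), forest = "A", forest_type = "dry_mixed_conifer",
    ba_obs = c(10, 20), tph_obs = c(110, 90)
  )
  v <- validate_predictions(records, sweep, ranges, refs)
  # MBE = mean(observed - modeled): (10-12, 20-19) -> -0.5
  expect_equal(v$mbe_ba, -0.5)
  expect_equal(v$mbe_tph, 0)
  # degenerate bands contain exactly the matching observations
  expect_equal(v$coverage_tph, 1)
  expect_equal(v$coverage_ba, 0)
  # record 1: sev 100 in range, ba 10 in HRV [10,20] -> agree;
  # record 2: sev 200 outside, ba 20 in HRV -> disagree
  expect_equal(v$accuracy_ba, 0.5)
  expect_equal(v$n_used, 2)

  # unmatched records are excluded with a warning, not fatal
  odd <- dplyr::bind_rows(
    records,
    tibble::tibble(
      severity = 100, forest = "B", forest_type = "dry_mixed_conifer",
      ba_obs = 1, tph_obs = 1
    )
  )
  expect_warning(v2 <- validate_predictions(odd, sweep, ranges, refs), "excluded")
  expect_equal(v2$n_excluded, 1)
  expect_equal(v2$mbe_ba, v$mbe_ba)
})
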