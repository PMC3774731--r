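# Eccentricity, rates, lagged correlation, stagnations, normalization.

test_that("eccentricity is 1 for regular hexagons and scales affinely", {
  hx <- regular_hexagon(1)
  expect_equal(eccentricity(hx), 1, tolerance = 1e-12)
  wide <- hx; wide[, 1] <- 2 * wide[, 1]
  expect_equal(eccentricity(wide), 2, tolerance = 1e-12)
  tall <- hx; tall[, 2] <- 4 * tall[, 2]
  expect_equal(eccentricity(tall), 0.25, tolerance = 1e-12)
  # translation and uniform-scale invariance
  moved <- 3 * hx + matrix(rep(c(17, -4), each = 6), ncol = 2)
  expect_equal(eccentricity(moved), 1, tolerance = 1e-12)
  expect_error(eccentricity(hx[1:2, ]), "degenerate")
})

test_that("polygon second moments match a fan-triangulation oracle", {
  set.seed(13)
  for (rep in 1:5) {
    ang <- sort(runif(8, 0, 2 * pi))
    poly <- cbind(2.5 * cos(ang) + rnorm(1), 1.3 * sin(ang) + rnorm(1))
    fm <- fan_moments(poly)
    expect_equal(eccentricity(poly), sqrt(fm$mu_xx / fm$mu_yy),
                 tolerance = 1e-6)
  }
})

test_that("series rates recover linear slopes and sinusoid derivatives", {
  t <- seq(0, 10, by = 0.1)
  expect_equal(series_rate(3 * t - 2, t, 5), rep(3, length(t)),
               tolerance = 1e-9)
  expect_equal(series_rate(rep(7, length(t)), t, 5), rep(0, length(t)))
  y <- sin(t)
  r <- series_rate(y, t, smoothing_window = 3)
  keep <- 5:(length(t) - 5)
  expect_equal(r[keep], cos(t)[keep], tolerance = 0.02)
  expect_error(series_rate(y, t, length(t) + 1), "longer than")
  expect_error(series_rate(y, t, 0), ">= 1")
})

test_that("lagged correlation finds constructed shifts and null bounds", {
  set.seed(17)
  a <- rnorm(500)
  ident <- lagged_correlation(a, a, 0:10)
  expect_equal(ident$best_offset, 0L)
  expect_equal(ident$best_correlation, 1)
  # b delayed by k samples: best offset k
  k <- 7L
  b <- c(rep(0, k), a[1:(500 - k)])
  del <- lagged_correlation(a, b, 0:15)
  expect_equal(del$best_offset, k)
  # independent white noise: all |r| small
  null <- lagged_correlation(rnorm(500), rnorm(500), 0:10)
  expect_lt(max(abs(null$correlation)), 0.15)
  expect_error(lagged_correlation(a[1:5], a[1:5], 4), "fewer than 3")
})

test_that("stagnation periods are detected by construction and exclusions hold", {
  t <- seq(0, 100, by = 1)
  # strictly decreasing ramp: none
  expect_equal(nrow(stagnation_periods(100 - t, t, tol_rate = 0.5,
                                       min_duration = 5)), 0L)
  # fall, plateau, fall: exactly one interval covering the plateau
  a <- c(seq(50, 30, length.out = 31), rep(30, 40),
         seq(30, 10, length.out = 30))
  res <- stagnation_periods(a, t, tol_rate = 0.3, min_duration = 20,
                            smoothing_window = 1)
  expect_equal(nrow(res), 1L)
  expect_gte(res$start, 29)
  expect_lte(res$end, 72)
  # pre-onset plateau excluded: flat start, then fall
  b <- c(rep(50, 40), seq(50, 10, length.out = 61))
  expect_equal(nrow(stagnation_periods(b, t, 0.3, 20,
                                       smoothing_window = 1)), 0L)
  # terminal plateau (no recommencement) excluded
  d <- c(seq(50, 20, length.out = 41), rep(20, 60))
  expect_equal(nrow(stagnation_periods(d, t, 0.3, 20,
                                       smoothing_window = 1)), 0L)
})

test_that("unit normalization maps the run span to 600 s and scales areas", {
  cfg <- preset_config("gradient", master_seed = 1)
  arch <- suppressWarnings(run_simulation(cfg))
  expect_true(arch$completed)
  rule <- normalization_rule(total_seconds = 600, area_scale = 35 / hex_area(1))
  df <- normalize_units(arch, rule)
  expect_equal(max(df$t), 600)
  expect_equal(df$area[df$step == 0][1], 35, tolerance = 1e-9)
  # half the steps ~ 300 s
  half <- max(df$step) %/% 2
  expect_equal(unique(df$t[df$step == half]), 300, tolerance = 600 / max(df$step))
  # incomplete run with a completion-based rule errors
  cfg2 <- preset_config("twi", master_seed = 1, max_steps = 30)
  arch2 <- run_simulation(cfg2)
  expect_false(arch2$completed)
  expect_error(normalize_units(arch2, rule), "completion")
})

test_that("rescaling time preserves the order of best lags", {
  set.seed(23)
  a <- as.vector(stats::filter(rnorm(300), rep(1, 10), sides = 1))
  a[is.na(a)] <- 0
  k <- 5L
  b <- c(rep(0, k), a[1:(300 - k)])
  l1 <- lagged_correlation(a, b, 0:10)
  # offsets in samples are invariant under linear time rescaling, so the
  # best offset in rescaled units is the sample offset times the new spacing
  expect_equal(l1$best_offset, k)
  expect_equal(l1$best_offset * 2.5, 12.5)
})
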