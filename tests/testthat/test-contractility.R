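# Contractility programs: spatial profiles, ramps, noise, variants.

test_that("gradient spatial profile is Gaussian in row distance with peak 1", {
  s <- build_hex_sheet(15, 24, 1)
  pg <- contractility_program("gradient_static")
  w <- spatial_profile(pg, s)
  mid <- which(s$cell_row == s$midline & !s$cell_margin)
  expect_true(all(w[mid] == 1))
  one_sigma <- which(abs(s$cell_row - s$midline) == pg$sigma_width &
                       !s$cell_margin)
  expect_equal(unique(w[one_sigma]), exp(-1 / 2), tolerance = 1e-12)
  far <- which(abs(s$cell_row - s$midline) == 7 & !s$cell_margin)
  expect_lt(max(w[far]), 0.003)
  expect_true(all(w[s$cell_margin] == 0))
  # midline contractility equals the printed peak
  expect_equal(unique(contractility_at(pg, s, 0)[mid]), 15)
})

test_that("cutoff profile is an indicator over the five central rows", {
  s <- build_hex_sheet(15, 24, 1)
  pc <- contractility_program("cutoff")
  g <- contractility_at(pc, s, 0)
  band <- abs(s$cell_row - s$midline) <= 2 & !s$cell_margin
  expect_true(all(g[band] == 10))
  expect_true(all(g[!band] == 0))
})

test_that("temporal ramp rises linearly from zero and caps at gamma_max", {
  pg <- contractility_program("gradient_timed")
  expect_equal(temporal_ramp(pg, 0), 0)
  expect_equal(temporal_ramp(pg, 100), 15)
  expect_equal(temporal_ramp(pg, 1000), 25)
  expect_error(temporal_ramp(pg, -1), "non-negative")
})

test_that("stochastic gradient collapses to the deterministic ramp when noise is off", {
  s <- build_hex_sheet(9, 10, 1)
  p0 <- contractility_program("gradient_stochastic", sigma_wiener = 0)
  pt <- contractility_program("gradient_timed")
  noise <- sample_noise(5, s, 50, 0.5)
  for (tt in c(0, 7.5, 40, 400)) {
    expect_identical(contractility_at(p0, s, tt, noise),
                     contractility_at(pt, s, tt))
  }
})

test_that("twi attenuation bounds every cell at half its wildtype value", {
  s <- build_hex_sheet(9, 10, 1)
  ptwi <- contractility_program("twi")
  pwt <- contractility_program("gradient_stochastic")
  noise <- sample_noise(7, s, 100, 0.5)
  g_twi <- contractility_at(ptwi, s, 30, noise)
  g_wt <- contractility_at(pwt, s, 30, noise)
  nz <- g_wt > 0
  expect_true(all(g_twi[nz] <= 0.5 * g_wt[nz]))
  expect_true(all(g_twi[nz] / g_wt[nz] >= 0))
  # U is drawn once per cell: same factor at different times
  g_twi2 <- contractility_at(ptwi, s, 60, noise)
  g_wt2 <- contractility_at(pwt, s, 60, noise)
  expect_equal(g_twi[nz] / g_wt[nz], (g_twi2 / g_wt2)[nz], tolerance = 1e-12)
})

test_that("contractility is non-negative everywhere and zero in margins", {
  s <- build_hex_sheet(9, 12, 1)
  noise <- sample_noise(11, s, 200, 0.5)
  for (variant in c("cutoff", "cutoff_timed", "gradient_static",
                    "gradient_timed", "gradient_stochastic", "twi")) {
    p <- contractility_program(variant, sigma_wiener = 3)  # exaggerated noise
    for (tt in c(0, 5, 50)) {
      g <- contractility_at(p, s, tt, noise)
      expect_true(all(g >= 0), label = paste(variant, "non-negative"))
      expect_true(all(g[s$cell_margin] == 0), label = paste(variant, "margin"))
    }
  }
})

test_that("expected gradient contractility decays with row distance", {
  s <- build_hex_sheet(15, 24, 1)
  p <- contractility_program("gradient_stochastic")
  noise <- sample_noise(3, s, 100, 0.5)
  g <- contractility_at(p, s, 50, noise)
  d <- abs(s$cell_row - s$midline)
  med <- vapply(0:6, function(k) mean(g[d == k & !s$cell_margin]), 0)
  expect_true(all(diff(med) <= 0))
})

test_that("alternative gradient weight follows the current centroid distance", {
  p <- contractility_program("gradient_alternative")
  pitch <- sqrt(3)
  expect_equal(alternative_gradient_weight(p, 5, 5, pitch), 1)
  expect_equal(alternative_gradient_weight(p, 5 + 1.3, 5, pitch),
               alternative_gradient_weight(p, 5 - 1.3, 5, pitch))
  # weight strictly increases as a cell approaches the midline
  dists <- seq(2 * p$sigma_width * pitch, p$sigma_width * pitch,
               length.out = 20)
  w <- alternative_gradient_weight(p, 5 + dists, 5, pitch)
  expect_true(all(diff(w) > 0))
})

test_that("noise paths are reproducible, independent and correctly scaled", {
  s <- build_hex_sheet(5, 6, 1)
  n1 <- sample_noise(42, s, 100, 0.5)
  n2 <- sample_noise(42, s, 100, 0.5)
  expect_identical(n1, n2)
  expect_false(identical(n1$dW, sample_noise(43, s, 100, 0.5)$dW))
  # W(0) = 0 by construction; increment variance = dt (Monte Carlo, 3%)
  big <- sample_noise(1, build_hex_sheet(10, 10, 1), 1000, 0.5)
  expect_equal(var(as.vector(big$dW)), 0.5, tolerance = 0.03)
  # a cell keeps its path when the sheet grows (streams keyed on row/col)
  s2 <- build_hex_sheet(7, 6, 1)
  n3 <- sample_noise(42, s2, 100, 0.5)
  c_in_s <- which(s$cell_row == 3 & s$cell_col == 4)
  c_in_s2 <- which(s2$cell_row == 3 & s2$cell_col == 4)
  expect_identical(n1$dW[c_in_s, ], n3$dW[c_in_s2, ])
})

test_that("program constructor enforces its invariants", {
  expect_error(contractility_program(n_central_rows = 4), "odd")
  expect_error(contractility_program(sigma_width = 0))
  expect_error(contractility_program(gamma_mid = -1))
  expect_error(run_config(n_rows = 3,
                          program = contractility_program(n_central_rows = 5)),
               "band wider")
})
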