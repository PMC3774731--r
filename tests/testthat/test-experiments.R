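# Preset experiments: reduced model, equilibrium sweep, variant summaries.

test_that("isolated-cell relaxation hits the analytic equilibrium area", {
  sw <- equilibrium_area_sweep(c(0, 2.5, 10, 25))
  expect_equal(sw$area[1], hex_area(1), tolerance = 1e-9)       # Gamma = 0
  expect_equal(sw$area[2], hex_area(1) / 2, tolerance = 1e-3)   # Gamma = K
  expect_equal(sw$area[3], 0.2 * hex_area(1), tolerance = 1e-3) # K=2.5, G=10
  expect_equal(sw$area / sw$predicted, rep(1, 4), tolerance = 1e-3)
  expect_true(all(diff(sw$area) < 0))
})

test_that("rosette geometry isolates a free central cell", {
  r <- build_hex_rosette()
  expect_length(r$cells, 7L)
  expect_length(validate_topology(r), 0L)
  center <- rosette_center(r)
  expect_length(center, 1L)
  expect_true(all(!r$fixed[r$cells[[center]]]))
  outer <- setdiff(unique(unlist(r$cells)), r$cells[[center]])
  expect_true(all(r$fixed[outer]))
})

test_that("halting the central ramp produces a stagnation inside the halt window", {
  halt <- function(t) 0.3 * ifelse(t < 10, t, ifelse(t < 60, 10, t - 50))
  r <- reduced_seven_cell(halt)
  # area reduction pauses soon after the ramp halts and resumes after t = 60
  st <- stagnation_periods(r$center$area, r$center$t, tol_rate = 0.026,
                           min_duration = 20)
  expect_gte(nrow(st), 1L)
  expect_gte(st$start[1], 10)
  expect_lte(st$start[1], 60)
  # constriction recommences: final area below the pre-halt plateau level
  plateau <- r$center$area[which.min(abs(r$center$t - 40))]
  expect_lt(r$center$area[nrow(r$center)], plateau - 0.2)
})

test_that("a steady central ramp constricts without stagnation", {
  r <- reduced_seven_cell(function(t) 0.3 * t)
  st <- stagnation_periods(r$center$area, r$center$t, tol_rate = 0.026,
                           min_duration = 20)
  expect_equal(nrow(st), 0L)
  # essentially monotone decline
  expect_lt(max(diff(r$center$area)), 1e-3)
})

test_that("a strong neighbour ramp transiently dilates the central cell", {
  nb <- function(t) ifelse(t < 30, 0, ifelse(t < 50, 1.2 * (t - 30), 24))
  r <- reduced_seven_cell(function(t) 0.3 * t, neighbor_schedule = nb)
  dil <- diff(r$center$area)
  expect_gt(max(dil), 0.01)  # temporary area increase
  window <- r$center$t[-1][which.max(dil)]
  expect_gte(window, 30)     # during the neighbour ramp
  expect_lte(window, 60)
})

test_that("tension variants order band T1 counts and eccentricity as expected", {
  sym <- tension_variant_run("symmetric", master_seed = 4)
  std <- tension_variant_run("transverse_high", master_seed = 4)
  expect_gt(std$mean_ventral_eccentricity, 1.3)
  expect_gt(std$mean_ventral_eccentricity, sym$mean_ventral_eccentricity)
  expect_gt(sym$t1_count, std$t1_count)
})

test_that("geometry controls anisotropy under constant contractility", {
  g1 <- suppressWarnings(geometry_variant_run("square_constant",
                                              master_seed = 1))
  g2 <- suppressWarnings(geometry_variant_run("square_gradient",
                                              master_seed = 1))
  g3 <- suppressWarnings(geometry_variant_run("rect_constant",
                                              master_seed = 1))
  expect_lt(abs(g1$mean_central_eccentricity - 1), 0.15)
  expect_gt(g2$mean_central_eccentricity, g1$mean_central_eccentricity + 0.3)
  expect_gt(g3$mean_central_eccentricity, g1$mean_central_eccentricity)
})

test_that("identity attenuation reduces the twi variant to the wildtype run", {
  cfg_twi <- preset_config("twi", master_seed = 6, max_steps = 60)
  cfg_twi$integration$furrow_threshold <- NA
  sheet <- build_hex_sheet(cfg_twi$n_rows, cfg_twi$n_cols,
                           cfg_twi$edge_length,
                           margin_cols = cfg_twi$margin_cols)
  noise <- sample_noise(6, sheet, 60, cfg_twi$integration$dt)
  noise$U[] <- 1
  a_twi <- run_simulation(cfg_twi, noise = noise)
  cfg_wt <- preset_config("gradient_stochastic", master_seed = 6,
                          max_steps = 60)
  cfg_wt$integration$furrow_threshold <- NA
  a_wt <- run_simulation(cfg_wt, noise = noise)
  expect_identical(a_twi$traces$area, a_wt$traces$area)
  expect_identical(a_twi$traces$gamma, a_wt$traces$gamma)
})

test_that("every preset yields a runnable configuration", {
  for (nm in preset_names()) {
    cfg <- preset_config(nm, master_seed = 1, max_steps = 2)
    arch <- suppressWarnings(run_simulation(cfg))
    expect_s3_class(arch, "vf_archive")
    expect_equal(arch$n_steps_run, 2L)
  }
})
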