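# Preset configurations reproducing the in-silico experiments: cutoff vs
# gradient furrows, tension and geometry variants, twi attenuation, and the
# reduced seven-cell model of stagnation mechanics.

#' Available preset names
#' @return Character vector.
#' @export
preset_names <- function() {
  c("cutoff", "cutoff_timed", "gradient", "gradient_timed",
    "gradient_stochastic", "gradient_alternative", "twi", "twi_wide",
    "narrow_gradient", "wide_gradient", "reduced_contractility",
    "tension_symmetric", "tension_vertical_high",
    "square_constant", "square_gradient", "rect_constant")
}

#' Preset run configuration
#'
#' Named configurations for the figure-level experiments. The standard sheet
#' is 15 x 24 cells with two non-contractile margin columns per side; the
#' geometry variants (`square_*`, `rect_constant`) use a one-cell
#' non-contractile frame around the whole sheet. `reduced_contractility`
#' lowers the ramp cap and midline peak to half the standard values; the
#' parameterisation of that variant is not fully pinned down, so treat it
#' as a user-tunable illustration rather than a calibrated preset.
#'
#' @param name One of [preset_names()].
#' @param master_seed Integer seed.
#' @param margin_cols Margin width for the band presets (default 2).
#' @param max_steps Sub-step budget (default 1200, i.e. 300 model-time
#'   units; completion typically occurs near 100).
#' @return A `vf_config`.
#' @export
preset_config <- function(name, master_seed = 1L, margin_cols = 2L,
                          max_steps = 1200L) {
  name <- match.arg(name, preset_names())
  ip <- integration_params(max_steps = max_steps)
  std <- function(program, ...) {
    run_config(program = program, integration = ip,
               master_seed = master_seed, margin_cols = margin_cols, ...)
  }
  frame_sheet <- function(n_rows, n_cols) {
    sheet <- build_hex_sheet(n_rows, n_cols, margin_cols = 0L)
    sheet$cell_margin <- sheet$cell_row == 1L | sheet$cell_row == n_rows |
      sheet$cell_col == 1L | sheet$cell_col == n_cols
    sheet
  }
  switch(name,
    cutoff = std(contractility_program("cutoff")),
    cutoff_timed = std(contractility_program("cutoff_timed")),
    gradient = std(contractility_program("gradient_static")),
    gradient_timed = std(contractility_program("gradient_timed")),
    gradient_stochastic = std(contractility_program("gradient_stochastic")),
    gradient_alternative = std(contractility_program("gradient_alternative")),
    twi = std(contractility_program("twi")),
    twi_wide = std(contractility_program("twi", sigma_width = 4.25)),
    narrow_gradient = std(contractility_program("gradient_stochastic",
                                                sigma_width = 1.25)),
    wide_gradient = std(contractility_program("gradient_stochastic",
                                              sigma_width = 3.00)),
    reduced_contractility = std(contractility_program("gradient_stochastic",
                                                      gamma_mid = 7.5,
                                                      gamma_max = 12.5)),
    tension_symmetric = std(contractility_program("gradient_stochastic"),
                            mech = mech_params(lambda_vertical = 0.2)),
    tension_vertical_high = std(contractility_program("gradient_stochastic"),
                                mech = mech_params(lambda_transverse = 0.075,
                                                   lambda_vertical = 0.2)),
    square_constant = run_config(
      sheet = frame_sheet(15L, 15L), n_rows = 15L, n_cols = 15L,
      margin_cols = 0L,
      program = contractility_program("cutoff", n_central_rows = 15L),
      integration = ip, master_seed = master_seed),
    square_gradient = run_config(
      sheet = frame_sheet(15L, 15L), n_rows = 15L, n_cols = 15L,
      margin_cols = 0L,
      program = contractility_program("gradient_static"),
      integration = ip, master_seed = master_seed),
    rect_constant = run_config(
      sheet = frame_sheet(15L, 24L), n_rows = 15L, n_cols = 24L,
      margin_cols = 0L,
      program = contractility_program("cutoff", n_central_rows = 15L),
      integration = ip, master_seed = master_seed)
  )
}

#' Run a named preset
#' @inheritParams preset_config
#' @param ... Passed to [preset_config()].
#' @return A `vf_archive`.
#' @export
run_preset <- function(name, master_seed = 1L, ...) {
  run_simulation(preset_config(name, master_seed = master_seed, ...))
}

#' Ventral cells of a sheet
#'
#' The five central rows, margin cells excluded. `exclude_border_cols` drops
#' that many additional columns flanking each margin: the stiff non-contractile
#' margin distorts its immediate neighbours (display panels of such sheets
#' conventionally crop this border zone), so trace analytics use the core band.
#'
#' @param sheet A `vf_sheet`.
#' @param exclude_border_cols Columns next to each margin to drop (default 0).
#' @return Integer cell indices.
#' @export
ventral_cells <- function(sheet, exclude_border_cols = 0L) {
  sel <- abs(sheet$cell_row - sheet$midline) <= 2L & !sheet$cell_margin
  if (exclude_border_cols > 0L) {
    margin_cols <- unique(sheet$cell_col[sheet$cell_margin])
    lo <- if (length(margin_cols)) max(margin_cols[margin_cols <=
            sheet$n_cols / 2], 0L) else 0L
    hi <- if (length(margin_cols)) min(margin_cols[margin_cols >
            sheet$n_cols / 2], sheet$n_cols + 1L) else sheet$n_cols + 1L
    sel <- sel & sheet$cell_col > lo + exclude_border_cols &
      sheet$cell_col < hi - exclude_border_cols
  }
  which(sel)
}

## Reduced model ---------------------------------------------------------------

#' Reduced seven-cell model
#'
#' One contractile central cell surrounded by six non-contractile (or
#' independently scheduled) neighbours, outer boundary fixed. Used to study
#' how stagnation periods arise from force balance: a halted contractility
#' ramp makes the central area plateau; a strong neighbour ramp can
#' transiently dilate the centre.
#'
#' @param center_schedule `function(t)` giving the central cell's Gamma.
#' @param neighbor_schedule `function(t)` for the six neighbours (default 0).
#' @param mech A [mech_params()] set.
#' @param int_params An [integration_params()] set; the default runs to
#'   model time 75 (150 sub-steps) with no furrow criterion.
#' @return List: `archive`, `center` (data frame t/area/gamma for the central
#'   cell), `neighbors` (mean neighbour area trace).
#' @export
reduced_seven_cell <- function(center_schedule,
                               neighbor_schedule = function(t) 0,
                               mech = mech_params(),
                               int_params = integration_params(
                                 max_steps = 150L, furrow_threshold = NA)) {
  sheet <- build_hex_rosette()
  center <- rosette_center(sheet)
  gamma_fn <- function(sh, t) {
    g <- rep(neighbor_schedule(t), length(sh$cells))
    g[center] <- center_schedule(t)
    g
  }
  config <- run_config(sheet = sheet, custom_gamma = gamma_fn, program = NULL,
                       mech = mech, integration = int_params,
                       normalization = normalization_rule(
                         require_completion = FALSE))
  arch <- run_simulation(config)
  tr <- arch$traces
  list(
    archive = arch,
    center = data.frame(t = tr$t, area = tr$area[center, ],
                        gamma = tr$gamma[center, ]),
    neighbors = data.frame(t = tr$t,
                           area = colMeans(tr$area[-center, , drop = FALSE]),
                           gamma = colMeans(tr$gamma[-center, , drop = FALSE]))
  )
}

#' Equilibrium area of an isolated contractile cell
#'
#' Relaxes a single free hexagon (no line tension) to force balance for each
#' contractility value and compares with the analytic minimum of
#' `K/2 (A - A0)^2 + Gamma/2 A^2`, namely `A* = K A0 / (K + Gamma)`: the
#' constriction achieved at force balance depends on the ratio of
#' contractility to area elasticity.
#'
#' @param gamma_values Non-negative contractility values.
#' @param mech A [mech_params()] set; tensions are forced to zero.
#' @param n_steps,dt Relaxation schedule (defaults converge well below 0.1
#'   percent).
#' @return Data frame: `gamma`, `area` (relaxed), `predicted` (analytic A*).
#' @export
equilibrium_area_sweep <- function(gamma_values, mech = mech_params(),
                                   n_steps = 3000L, dt = 0.02) {
  # unit friction here: only the relaxed end state matters
  mech$lambda_transverse <- 0
  mech$lambda_vertical <- 0
  mech$lambda_margin <- 0
  area <- vapply(gamma_values, function(g) {
    sheet <- build_hex_sheet(1L, 1L, margin_cols = 0L, fix_boundary = FALSE)
    ip <- integration_params(dt = dt, friction_eta = 1,
                             max_steps = n_steps, furrow_threshold = NA)
    config <- run_config(sheet = sheet, program = NULL,
                         custom_gamma = function(sh, t) rep(g, 1L),
                         mech = mech, integration = ip,
                         normalization = normalization_rule(
                           require_completion = FALSE))
    arch <- run_simulation(config)
    arch$traces$area[1L, ncol(arch$traces$area)]
  }, 0)
  data.frame(gamma = gamma_values, area = area,
             predicted = mech$K * mech$A0 / (mech$K + gamma_values))
}

## Variant runs ----------------------------------------------------------------

variant_summary <- function(arch) {
  sheet <- arch$final_sheet
  v <- ventral_cells(sheet)
  last <- ncol(arch$traces$area)
  ev <- arch$t1_events[arch$t1_events$type == "swap", , drop = FALSE]
  band <- abs(sheet$cell_row - sheet$midline) <= 2L
  # swaps within the furrow (both cells losing adjacency in the central band);
  # stretched lateral tissue can also swap, which the furrow panels do not show
  ventral_swaps <- if (nrow(ev)) {
    sum(band[ev$cell_lost_1] & band[ev$cell_lost_2])
  } else 0L
  list(
    archive = arch,
    mean_ventral_eccentricity = mean(arch$traces$eccentricity[v, last]),
    sd_ventral_eccentricity = stats::sd(arch$traces$eccentricity[v, last]),
    var_ventral_area = stats::var(arch$traces$area[v, last]),
    mean_ventral_area = mean(arch$traces$area[v, last]),
    t1_count = ventral_swaps,
    t1_count_total = nrow(ev),
    completed = arch$completed
  )
}

#' Line-tension symmetry variants
#'
#' Runs the stochastic gradient model with symmetric tension (0.2/0.2), the
#' standard asymmetry (transverse 0.2 / vertical 0.075) or the inverted
#' asymmetry (0.075/0.2), and reports mean ventral eccentricity and T1 count.
#' Symmetric and vertical-high tensions channel latero-ventral compression
#' into neighbour exchanges, so cells stay round; the standard asymmetry
#' suppresses T1s and cells grow AP-eccentric.
#'
#' @param mode `"symmetric"`, `"transverse_high"` (standard) or
#'   `"vertical_high"`.
#' @param master_seed Integer seed (use the same seed across modes to
#'   compare).
#' @param max_steps Step budget.
#' @return A summary list (see value of [twi_run()]).
#' @export
tension_variant_run <- function(mode = c("transverse_high", "symmetric",
                                         "vertical_high"),
                                master_seed = 1L, max_steps = 1200L) {
  mode <- match.arg(mode)
  name <- switch(mode, transverse_high = "gradient_stochastic",
                 symmetric = "tension_symmetric",
                 vertical_high = "tension_vertical_high")
  arch <- run_preset(name, master_seed = master_seed, max_steps = max_steps)
  c(variant_summary(arch), mode = mode)
}

#' Sheet-geometry variants
#'
#' Constant contractility on a square sheet constricts isotropically; a
#' gradient on the same square, or constant contractility on an AP-elongated
#' rectangle, produces eccentric central cells. Reports mean and s.d. of the
#' final eccentricity of the designated central block (within two rows and
#' two columns of the sheet centre, frame excluded).
#'
#' @param mode `"square_constant"`, `"square_gradient"` or `"rect_constant"`.
#' @param master_seed Integer seed.
#' @param max_steps Step budget.
#' @return List with `mean_central_eccentricity`, `sd_central_eccentricity`,
#'   the central-cell indices and the archive.
#' @export
geometry_variant_run <- function(mode = c("square_constant", "square_gradient",
                                          "rect_constant"),
                                 master_seed = 1L, max_steps = 1200L) {
  mode <- match.arg(mode)
  arch <- run_preset(mode, master_seed = master_seed, max_steps = max_steps)
  sheet <- arch$final_sheet
  mid_col <- ceiling(sheet$n_cols / 2)
  central <- which(abs(sheet$cell_row - sheet$midline) <= 2L &
                     abs(sheet$cell_col - mid_col) <= 2L & !sheet$cell_margin)
  last <- ncol(arch$traces$eccentricity)
  list(mode = mode,
       mean_central_eccentricity = mean(arch$traces$eccentricity[central, last]),
       sd_central_eccentricity = stats::sd(arch$traces$eccentricity[central, last]),
       central_cells = central,
       archive = arch)
}

#' twi-mutant attenuation run
#'
#' Scales every cell's stochastic-gradient contractility by a fixed uniform
#' factor U(i,j) in \[0, 0.5\], drawn once per cell: apical myosin recruitment
#' is weak and patchy in twi mutants, so constriction becomes spatially
#' random and the furrow fails. `widened = TRUE` additionally widens the
#' gradient (sigma = 4.25).
#'
#' @param widened Widen the contractility gradient (default FALSE).
#' @param master_seed Integer seed.
#' @param max_steps Step budget.
#' @return Summary list: archive, mean/sd ventral eccentricity, ventral-area
#'   variance, T1 count, completion flag.
#' @export
twi_run <- function(widened = FALSE, master_seed = 1L, max_steps = 1200L) {
  arch <- run_preset(if (widened) "twi_wide" else "twi",
                     master_seed = master_seed, max_steps = max_steps)
  variant_summary(arch)
}
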