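# Contractility programs Gamma_i(t): spatial profile x temporal ramp x
# per-cell Wiener noise, with variant dispatch.
#
# Spatial weight (gradient variants): w(i) = exp(-(i - Z)^2 / (2 sigma^2)),
# peaking at 1 on the midline row Z. Cutoff variants use an indicator over
# the central band. Margin cells are always non-contractile.
#
# The temporal-stochastic scalar shared by a cell is
#   clamp(gamma_init + alpha_rate * t + sigma_wiener * W_ij(t), 0, gamma_max)
# i.e. the cap applies to the midline-equivalent scalar before spatial
# weighting; the clamp at 0 keeps early noise from producing expansile cells.

#' Contractility program
#'
#' @param variant One of `"cutoff"`, `"cutoff_timed"`, `"gradient_static"`,
#'   `"gradient_timed"`, `"gradient_stochastic"`, `"gradient_alternative"`,
#'   `"twi"`.
#' @param gamma_cutoff Contractility inside the cutoff band (default 10).
#' @param gamma_mid Midline peak contractility for the static gradient
#'   (default 15).
#' @param sigma_width Gradient width parameter sigma in cell rows
#'   (default 2.0; presets 1.25 narrow, 3.00 wide, 4.25 widened twi).
#' @param gamma_init Contractility at t = 0 for timed variants (default 0).
#' @param alpha_rate Linear rise rate (default 0.15 per model time unit).
#' @param gamma_max Cap on the ramped scalar (default 25).
#' @param sigma_wiener Amplitude of the per-cell Wiener term (default 0.3;
#'   0 recovers the deterministic timed model exactly).
#' @param n_central_rows Width of the contractile band for cutoff variants
#'   (odd, default 5).
#' @param twi_umax Upper bound of the per-cell uniform attenuation factor
#'   U(i,j) for the twi variant (default 0.5).
#' @return A `vf_program` list.
#' @export
contractility_program <- function(variant = c("gradient_stochastic", "cutoff",
                                              "cutoff_timed", "gradient_static",
                                              "gradient_timed",
                                              "gradient_alternative", "twi"),
                                  gamma_cutoff = 10, gamma_mid = 15,
                                  sigma_width = 2.0, gamma_init = 0,
                                  alpha_rate = 0.15, gamma_max = 25,
                                  sigma_wiener = 0.3, n_central_rows = 5L,
                                  twi_umax = 0.5) {
  variant <- match.arg(variant)
  stopifnot(gamma_cutoff >= 0, gamma_mid >= 0, sigma_width > 0,
            gamma_init >= 0, alpha_rate >= 0, gamma_max >= 0,
            sigma_wiener >= 0, twi_umax >= 0)
  n_central_rows <- as.integer(n_central_rows)
  if (n_central_rows %% 2L != 1L) {
    stop("n_central_rows must be odd (band centred on the midline)")
  }
  structure(list(variant = variant, gamma_cutoff = gamma_cutoff,
                 gamma_mid = gamma_mid, sigma_width = sigma_width,
                 gamma_init = gamma_init, alpha_rate = alpha_rate,
                 gamma_max = gamma_max, sigma_wiener = sigma_wiener,
                 n_central_rows = n_central_rows, twi_umax = twi_umax),
            class = "vf_program")
}

#' Spatial contractility weight of each cell
#'
#' Dimensionless weight in \[0, 1\]: Gaussian in the row distance to the
#' midline for gradient variants, an indicator over the central band for
#' cutoff variants; 0 for margin cells.
#'
#' @param program A [contractility_program()].
#' @param sheet A `vf_sheet`.
#' @param cell Optional cell indices (default all).
#' @return Numeric weights.
#' @export
spatial_profile <- function(program, sheet, cell = NULL) {
  if (is.null(cell)) cell <- seq_along(sheet$cells)
  d <- abs(sheet$cell_row[cell] - sheet$midline)
  w <- if (program$variant %in% c("cutoff", "cutoff_timed")) {
    as.numeric(d <= (program$n_central_rows - 1L) %/% 2L)
  } else {
    exp(-d^2 / (2 * program$sigma_width^2))
  }
  w[sheet$cell_margin[cell]] <- 0
  w
}

#' Gaussian weight from current centroid distance to the midline
#'
#' The non-cell-autonomous ("alternative") gradient: contractility is read off
#' the cell's current centroid y-distance from the fixed midline coordinate
#' `y_mid` (set once, at simulation start), with the same width sigma. A cell
#' moving towards the midline grows more contractile.
#'
#' @param program A [contractility_program()].
#' @param centroid_y Current centroid y-coordinates.
#' @param y_mid Midline y-coordinate (mean centroid y of the midline row at
#'   the first step).
#' @param row_pitch Lattice row pitch used to express sigma (in length units
#'   per row); the sheet row spacing `sqrt(3) * edge_length`.
#' @return Numeric weights in \[0, 1\].
#' @export
alternative_gradient_weight <- function(program, centroid_y, y_mid,
                                        row_pitch) {
  sig <- program$sigma_width * row_pitch
  exp(-(centroid_y - y_mid)^2 / (2 * sig^2))
}

#' Temporal ramp of the contractility scalar
#'
#' `min(gamma_init + alpha_rate * t, gamma_max)`.
#'
#' @param program A [contractility_program()].
#' @param t Model time (>= 0), vectorised.
#' @return Gamma-scale values.
#' @export
temporal_ramp <- function(program, t) {
  if (any(t < 0)) stop("model time must be non-negative")
  pmin(program$gamma_init + program$alpha_rate * t, program$gamma_max)
}

## Noise -----------------------------------------------------------------------

# Per-cell RNG substream seed: keyed on (row, col) so a sheet-size change
# does not reshuffle the paths of cells that keep their indices.
cell_stream_seed <- function(master_seed, i, j) {
  (as.numeric(master_seed) * 1000003 + i * 7919 + j * 7) %% 2147483647
}

#' Sample per-cell Wiener paths and twi attenuation factors
#'
#' Increments for a step `dt` are iid Gaussian with mean 0 and variance `dt`,
#' drawn independently per cell from a substream derived from `master_seed`
#' and the cell's (row, col) index. `W(0) = 0` for every cell. The result is
#' stored in the run archive, which makes replays bit-exact.
#'
#' @param master_seed Integer master seed.
#' @param sheet A `vf_sheet`.
#' @param n_steps Number of Euler steps to cover.
#' @param dt Step size (model time).
#' @param twi_umax Upper bound for the per-cell uniform attenuation factor
#'   (drawn once per cell; used only by the twi variant).
#' @return A `vf_noise` list: `dW` (n_cells x n_steps increments), `U`
#'   (attenuation factors), `master_seed`, `dt`.
#' @export
sample_noise <- function(master_seed, sheet, n_steps, dt, twi_umax = 0.5) {
  n_c <- length(sheet$cells)
  dW <- matrix(0, n_c, max(n_steps, 0L))
  U <- numeric(n_c)
  sdev <- sqrt(dt)
  for (c in seq_len(n_c)) {
    seed_c <- cell_stream_seed(master_seed, sheet$cell_row[c], sheet$cell_col[c])
    set.seed(seed_c)
    U[c] <- stats::runif(1, 0, twi_umax)
    if (n_steps > 0L) dW[c, ] <- stats::rnorm(n_steps, 0, sdev)
  }
  structure(list(dW = dW, U = U, master_seed = master_seed, dt = dt),
            class = "vf_noise")
}

## Evaluation ------------------------------------------------------------------

# Internal vectorised evaluation of Gamma for all cells at model time t.
# `W` is the vector of current Wiener values (0 when absent); `weight`
# the spatial weight vector (for the alternative variant the caller passes
# the centroid-based weight).
program_gamma <- function(program, sheet, t, W = NULL, U = NULL,
                          weight = NULL) {
  if (is.null(weight)) weight <- spatial_profile(program, sheet)
  g <- switch(program$variant,
    cutoff = program$gamma_cutoff * weight,
    gradient_static = program$gamma_mid * weight,
    cutoff_timed = temporal_ramp(program, t) * weight,
    gradient_timed = temporal_ramp(program, t) * weight,
    gradient_stochastic = ,
    gradient_alternative = ,
    twi = {
      if (is.null(W)) W <- numeric(length(weight))
      scalar <- program$gamma_init + program$alpha_rate * t +
        program$sigma_wiener * W
      scalar <- pmin(pmax(scalar, 0), program$gamma_max)
      g0 <- scalar * weight
      if (program$variant == "twi") {
        if (is.null(U)) stop("twi variant requires attenuation factors U")
        g0 <- U * g0
      }
      g0
    },
    stop("unknown contractility variant: ", program$variant)
  )
  g[sheet$cell_margin] <- 0
  g
}

#' Contractility of cells at a given time
#'
#' Variant dispatch for Gamma_i(t). Stochastic variants read the cell's Wiener
#' path from `noise` (`W(t)` is the cumulative sum of increments up to the
#' enclosing step); the twi variant additionally applies the per-cell
#' attenuation factor U(i,j). The result is non-negative everywhere and zero
#' in margin cells.
#'
#' @param program A [contractility_program()].
#' @param sheet A `vf_sheet`.
#' @param t Model time.
#' @param noise A `vf_noise` from [sample_noise()] (required for stochastic
#'   variants; `W(t)` is interpolated at whole steps `floor(t/dt)`).
#' @param cell Optional cell indices (default all).
#' @param y_mid Midline y-coordinate for the alternative gradient; when NULL
#'   it is taken from the current centroids of the midline row (inside
#'   [run_simulation()] it is frozen at the first step instead).
#' @return Numeric vector of Gamma values.
#' @export
contractility_at <- function(program, sheet, t, noise = NULL, cell = NULL,
                             y_mid = NULL) {
  if (t < 0) stop("model time must be non-negative")
  W <- NULL; U <- NULL
  if (program$variant %in% c("gradient_stochastic", "gradient_alternative",
                             "twi")) {
    if (is.null(noise)) {
      W <- numeric(length(sheet$cells))
    } else {
      k <- min(floor(t / noise$dt + 1e-9), ncol(noise$dW))
      W <- if (k >= 1) rowSums(noise$dW[, seq_len(k), drop = FALSE])
           else numeric(length(sheet$cells))
      U <- noise$U
    }
  }
  weight <- NULL
  if (program$variant == "gradient_alternative") {
    cen <- cell_centroids(sheet)
    if (is.null(y_mid)) {
      y_mid <- mean(cen[sheet$cell_row == sheet$midline &
                          !sheet$cell_margin, 2L])
    }
    weight <- alternative_gradient_weight(program, cen[, 2L], y_mid,
                                          sqrt(3) * sheet$edge_length)
    weight[sheet$cell_margin] <- 0
  }
  g <- program_gamma(program, sheet, t, W = W, U = U, weight = weight)
  if (is.null(cell)) g else g[cell]
}

#' @export
print.vf_program <- function(x, ...) {
  cat(sprintf("<vf_program> variant %s\n", x$variant))
  cat(sprintf(
    "  gamma_mid %g, sigma %g, ramp %g + %g t (cap %g), wiener sigma %g\n",
    x$gamma_mid, x$sigma_width, x$gamma_init, x$alpha_rate, x$gamma_max,
    x$sigma_wiener))
  invisible(x)
}
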