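# Potential energy of the sheet and analytic per-vertex forces.
#
# E = sum_cells K/2 (A_i - A0)^2            (area elasticity)
#   + sum_edges Lambda_e * l_e              (line tension)
#   + sum_cells Gamma_i/2 * A_i^2           (area contractility, preferred area 0)
#
# Lambda_e is chosen by the edge's current orientation class (transverse if
# within 45 degrees of the AP axis, else vertical), overridden by the margin
# tension for any edge touching a margin cell. Forces are -dE/dx_v.

#' Mechanical parameter set
#'
#' @param K Area-elasticity constant (default 2.5).
#' @param A0 Preferred apical area; default the initial regular-hexagon area
#'   for unit edge length.
#' @param lambda_transverse Line tension on transverse boundaries
#'   (angle 0-45 degrees to the AP axis), default 0.2.
#' @param lambda_vertical Line tension on vertical boundaries (45-90 degrees),
#'   default 0.075.
#' @param lambda_margin Line tension on boundaries of non-contractile margin
#'   cells, default 6.0 (suppresses border artefacts).
#' @param kappa_edge Optional quadratic edge elasticity (energy per length^2
#'   about the rest length); 0 (default) disables the term, matching the pure
#'   tension model.
#' @param rest_length Rest length for `kappa_edge` (defaults to the hexagon
#'   edge length at build time when left NA).
#' @return A `vf_mech_params` list.
#' @export
mech_params <- function(K = 2.5, A0 = hex_area(1),
                        lambda_transverse = 0.2, lambda_vertical = 0.075,
                        lambda_margin = 6.0, kappa_edge = 0,
                        rest_length = NA_real_) {
  stopifnot(is.finite(K), K > 0, is.finite(A0), A0 > 0,
            lambda_transverse >= 0, lambda_vertical >= 0, lambda_margin >= 0,
            kappa_edge >= 0)
  structure(list(K = K, A0 = A0,
                 lambda_transverse = lambda_transverse,
                 lambda_vertical = lambda_vertical,
                 lambda_margin = lambda_margin,
                 kappa_edge = kappa_edge,
                 rest_length = rest_length),
            class = "vf_mech_params")
}

# Per-edge line tension under the current geometry.
edge_tensions <- function(sheet, params) {
  geo <- edge_geometry(sheet)
  lam <- rep(params$lambda_vertical, nrow(geo$d))
  lam[abs(geo$d[, 2L]) <= abs(geo$d[, 1L])] <- params$lambda_transverse
  lam[sheet$edge_margin] <- params$lambda_margin
  list(lambda = lam, d = geo$d, len = geo$len)
}

check_gamma <- function(sheet, gamma) {
  if (length(gamma) != length(sheet$cells)) {
    stop("contractility must be given for every cell")
  }
  if (any(!is.finite(gamma)) || any(gamma < 0)) {
    stop("contractility must be finite and non-negative")
  }
  invisible(gamma)
}

# Energy from precomputed per-cell areas, per-edge tensions and lengths.
energy_from_state <- function(params, gamma, A, lambda, len, edge_length) {
  e <- sum(params$K / 2 * (A - params$A0)^2) +
    sum(lambda * len) +
    sum(gamma / 2 * A^2)
  if (params$kappa_edge > 0) {
    l0 <- if (is.na(params$rest_length)) edge_length else params$rest_length
    e <- e + sum(params$kappa_edge / 2 * (len - l0)^2)
  }
  e
}

#' Total potential energy of the sheet
#'
#' @param sheet A `vf_sheet`.
#' @param params A [mech_params()] set.
#' @param gamma Per-cell contractility values (all >= 0).
#' @return Scalar energy.
#' @export
total_energy <- function(sheet, params, gamma) {
  check_gamma(sheet, gamma)
  A <- cell_areas(sheet)
  et <- edge_tensions(sheet, params)
  e <- energy_from_state(params, gamma, A, et$lambda, et$len,
                         sheet$edge_length)
  if (!is.finite(e)) stop("non-finite energy")
  e
}

#' Analytic per-vertex forces
#'
#' Gradient of the energy with respect to each vertex position, negated
#' (force = -dE/dx). Area-term derivatives follow the shoelace formula
#' (dA/dx_v = (y_next - y_prev)/2 within each cell); tension derivatives are
#' unit tangents along each edge. Forces on fixed vertices are reported but
#' never applied by the integrator.
#'
#' @inheritParams total_energy
#' @return Numeric matrix (n_vertices x 2) of force components.
#' @export
vertex_forces <- function(sheet, params, gamma) {
  check_gamma(sheet, gamma)
  forces_from_state(sheet, params, gamma, cell_areas(sheet),
                    edge_tensions(sheet, params))
}

# Force computation sharing precomputed areas/tensions with the caller.
forces_from_state <- function(sheet, params, gamma, A, et) {
  p <- sheet$pos
  cv <- sheet$cv
  # dE/dA per cell: elasticity + contractility
  dEdA <- params$K * (A - params$A0) + gamma * A
  coef <- dEdA[cv$cell]
  dAdx <- (p[cv$vn, 2L] - p[cv$vp, 2L]) / 2
  dAdy <- (p[cv$vp, 1L] - p[cv$vn, 1L]) / 2
  f <- cbind(agg_verts(-coef * dAdx, sheet),
             agg_verts(-coef * dAdy, sheet))
  # line tension (+ optional edge elasticity): force pulls endpoints together
  if (any(et$len == 0)) {
    stop(sprintf("zero-length edge %d: tension derivative undefined",
                 which(et$len == 0)[1L]))
  }
  w <- et$lambda
  if (params$kappa_edge > 0) {
    l0 <- if (is.na(params$rest_length)) sheet$edge_length else params$rest_length
    w <- w + params$kappa_edge * (et$len - l0)
  }
  ux <- et$d[, 1L] / et$len
  uy <- et$d[, 2L] / et$len
  f[, 1L] <- f[, 1L] + agg_edge_ends(c(w * ux, -w * ux), sheet)
  f[, 2L] <- f[, 2L] + agg_edge_ends(c(w * uy, -w * uy), sheet)
  if (!all(is.finite(f))) {
    stop(sprintf("non-finite force on vertex %d",
                 which(!is.finite(f[, 1L]) | !is.finite(f[, 2L]))[1L]))
  }
  f
}
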