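# Independent oracles and shared fixtures.

# Central finite-difference gradient of the total energy; the analytic forces
# must match -dE/dx. Independent of the force code path.
numeric_forces <- function(sheet, params, gamma, h = 1e-6) {
  f <- matrix(0, nrow(sheet$pos), 2L)
  for (v in seq_len(nrow(sheet$pos))) {
    for (d in 1:2) {
      sp <- sheet; sp$pos[v, d] <- sp$pos[v, d] + h
      sm <- sheet; sm$pos[v, d] <- sm$pos[v, d] - h
      f[v, d] <- -(total_energy(sp, params, gamma) -
                     total_energy(sm, params, gamma)) / (2 * h)
    }
  }
  f
}

# Monte-Carlo polygon area by rejection sampling in the bounding box.
mc_polygon_area <- function(ring, n = 2e5, seed = 99) {
  set.seed(seed)
  xr <- range(ring[, 1L]); yr <- range(ring[, 2L])
  px <- runif(n, xr[1L], xr[2L]); py <- runif(n, yr[1L], yr[2L])
  # even-odd ray casting
  inside <- logical(n)
  m <- nrow(ring)
  j <- m
  for (i in seq_len(m)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  mean(inside) * diff(xr) * diff(yr)
}

# Fan-triangulation centroid and second central moments (independent of the
# shoelace-based implementation).
fan_moments <- function(ring) {
  m <- nrow(ring)
  p0 <- ring[1L, ]
  A <- 0; cx <- 0; cy <- 0; sxx <- 0; syy <- 0
  for (i in 2:(m - 1L)) {
    p1 <- ring[i, ]; p2 <- ring[i + 1L, ]
    a <- ((p1[1L] - p0[1L]) * (p2[2L] - p0[2L]) -
            (p2[1L] - p0[1L]) * (p1[2L] - p0[2L])) / 2
    cc <- (p0 + p1 + p2) / 3
    A <- A + a
    cx <- cx + a * cc[1L]; cy <- cy + a * cc[2L]
    # exact triangle second moments about the origin
    xs <- c(p0[1L], p1[1L], p2[1L]); ys <- c(p0[2L], p1[2L], p2[2L])
    sxx <- sxx + a * (sum(xs^2) + sum(xs * xs[c(2, 3, 1)])) / 6
    syy <- syy + a * (sum(ys^2) + sum(ys * ys[c(2, 3, 1)])) / 6
  }
  cx <- cx / A; cy <- cy / A
  list(area = A, cx = cx, cy = cy,
       mu_xx = sxx / A - cx^2, mu_yy = syy / A - cy^2)
}

# A small randomly perturbed sheet with random contractility, reproducible.
perturbed_sheet <- function(n_rows = 3, n_cols = 4, seed = 1, scale = 0.08,
                            margin_cols = 1L) {
  set.seed(seed)
  s <- build_hex_sheet(n_rows, n_cols, margin_cols = margin_cols)
  s$pos <- s$pos + matrix(rnorm(length(s$pos), 0, scale), ncol = 2L)
  s
}

regular_hexagon <- function(edge = 1, center = c(0, 0)) {
  ang <- (0:5) * pi / 3
  cbind(center[1L] + edge * cos(ang), center[2L] + edge * sin(ang))
}

# Euler characteristic V - E + F of a sheet (outer face excluded).
euler_vef <- function(sheet) {
  used <- length(unique(unlist(sheet$cells)))
  used - nrow(sheet$edges) + length(sheet$cells)
}

# Cache for full-size archives shared across test files.
.vf_cache <- new.env(parent = emptyenv())
cached_preset_run <- function(name, seed, ...) {
  key <- paste(name, seed, ...)
  if (is.null(.vf_cache[[key]])) {
    .vf_cache[[key]] <- suppressWarnings(
      run_preset(name, master_seed = seed, ...))
  }
  .vf_cache[[key]]
}

# Normalized time axis (600 s span) for an archive's traces.
norm_time <- function(arch) arch$traces$t / max(arch$traces$t) * 600

# Stagnation count with the package default thresholds on a normalized trace.
stag_count <- function(area, t_s) {
  nrow(stagnation_periods(area, t_s, tol_rate = 0.02 * hex_area(1) / 10,
                          min_duration = 30))
}
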