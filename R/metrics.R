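# Trace analytics: moment-ellipse eccentricity, smoothed rates, lagged
# rate correlation, stagnation periods and unit normalization.

## Eccentricity ----------------------------------------------------------------

# Second central area moments of a CCW polygon ring (matrix of positions).
polygon_second_moments <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(area = a, cx = cx, cy = cy,
       mu_xx = ixx / a - cx^2, mu_yy = iyy / a - cy^2,
       mu_xy = ixy / a - cx * cy)
}

#' Cell eccentricity from the moment-equivalent ellipse
#'
#' Fits the ellipse sharing the polygon's area-weighted second central
#' moments and returns the ratio of its antero-posterior (x) to latero-ventral
#' (y) extent, `sqrt(mu_xx / mu_yy)`. A regular hexagon gives 1; values above
#' 1 mean AP-elongated (anisotropically constricted) cells. Axis-aligned
#' extents are used (not principal axes): the measure is defined as the
#' AP-to-LV dimension ratio.
#'
#' @param ring Two-column matrix of vertex positions (simple CCW polygon).
#' @return Scalar eccentricity (>= 0).
#' @export
eccentricity <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  m <- polygon_second_moments(ring)
  if (!is.finite(m$area) || m$area <= 0 || m$mu_yy <= 0) {
    stop("degenerate polygon: cannot fit moment ellipse")
  }
  sqrt(m$mu_xx / m$mu_yy)
}

# Vectorised eccentricity of every cell of a sheet.
cell_eccentricity <- function(sheet) {
  p <- sheet$pos; cv <- sheet$cv
  x <- p[cv$v, 1L]; y <- p[cv$v, 2L]
  xn <- p[cv$vn, 1L]; yn <- p[cv$vn, 2L]
  cr <- x * yn - xn * y
  a <- agg_cells(cr, sheet) / 2
  cx <- agg_cells((x + xn) * cr, sheet) / (6 * a)
  cy <- agg_cells((y + yn) * cr, sheet) / (6 * a)
  ixx <- agg_cells((x^2 + x * xn + xn^2) * cr, sheet) / 12
  iyy <- agg_cells((y^2 + y * yn + yn^2) * cr, sheet) / 12
  sqrt((ixx / a - cx^2) / (iyy / a - cy^2))
}

## Rates -----------------------------------------------------------------------

# Centered moving average; the window shrinks symmetrically near the ends so
# a linear series passes through unchanged.
moving_average <- function(v, window) {
  n <- length(v)
  half <- (window - 1L) %/% 2L
  half_i <- pmin(half, seq_len(n) - 1L, n - seq_len(n))
  cs <- cumsum(c(0, v))
  lo <- seq_len(n) - half_i
  hi <- seq_len(n) + half_i
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smoothed rate of change of a series
#'
#' Applies a centered moving average of `smoothing_window` samples, then a
#' centered-difference derivative against `t` (one-sided at the ends). Output
#' has the same length as the input.
#'
#' @param values Numeric series.
#' @param t Sampling times (strictly increasing, same length).
#' @param smoothing_window Window in samples (>= 1; default 5).
#' @return Numeric rate series.
#' @export
series_rate <- function(values, t, smoothing_window = 5L) {
  n <- length(values)
  stopifnot(length(t) == n)
  if (smoothing_window < 1L) stop("smoothing window must be >= 1 sample")
  if (smoothing_window > n) stop("smoothing window longer than the series")
  if (n < 2L) stop("need at least 2 samples for a rate")
  s <- moving_average(values, smoothing_window)
  r <- numeric(n)
  if (n > 2L) {
    idx <- 2:(n - 1L)
    r[idx] <- (s[idx + 1L] - s[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  }
  r[1L] <- (s[2L] - s[1L]) / (t[2L] - t[1L])
  r[n] <- (s[n] - s[n - 1L]) / (t[n] - t[n - 1L])
  r
}

#' Lagged correlation between two rate series
#'
#' Shifts `rate_a` forward in time by each offset (in samples) and computes
#' the Pearson correlation with `rate_b` on the overlapping support. Matrix
#' input (cells x time) gives per-cell coefficients, aggregated by averaging
#' across cells at each offset. The best offset maximises the (mean)
#' correlation.
#'
#' @param rate_a,rate_b Numeric vectors, or matrices with one row per cell.
#' @param offsets Non-negative integer sample shifts (default 0:20).
#' @return List: `offsets`, `correlation` (mean over cells), `per_cell`
#'   (matrix cells x offsets), `best_offset`, `best_correlation`.
#' @export
lagged_correlation <- function(rate_a, rate_b, offsets = 0:20) {
  if (is.null(dim(rate_a))) rate_a <- matrix(rate_a, nrow = 1L)
  if (is.null(dim(rate_b))) rate_b <- matrix(rate_b, nrow = 1L)
  stopifnot(all(dim(rate_a) == dim(rate_b)), all(offsets >= 0),
            all(offsets == round(offsets)))
  n <- ncol(rate_a)
  per_cell <- matrix(NA_real_, nrow(rate_a), length(offsets))
  for (oi in seq_along(offsets)) {
    k <- offsets[oi]
    if (n - k < 3L) stop(sprintf("offset %d leaves fewer than 3 samples", k))
    ia <- seq_len(n - k)
    ib <- ia + k
    for (ci in seq_len(nrow(rate_a))) {
      per_cell[ci, oi] <- stats::cor(rate_a[ci, ia], rate_b[ci, ib])
    }
  }
  m <- colMeans(per_cell)
  best <- which.max(m)
  list(offsets = offsets, correlation = m, per_cell = per_cell,
       best_offset = offsets[best], best_correlation = m[best])
}

## Stagnation periods ----------------------------------------------------------

#' Detect stagnation periods in an area trace
#'
#' A stagnation period is a maximal interval during which the smoothed area
#' rate stays within `tol_rate` of zero for at least `min_duration`, occurring
#' after constriction has begun (the pre-onset plateau, before the first
#' significant negative rate, is excluded) and before it recommences
#' (area reduction must resume after the interval, so the terminal
#' approach to force balance at the end of a trace does not count).
#'
#' @param area Area series.
#' @param t Sampling times.
#' @param tol_rate Absolute rate tolerance (area units per time unit; e.g. 2
#'   percent of A0 per 10 normalized seconds).
#' @param min_duration Minimum interval duration (time units).
#' @param smoothing_window Samples for rate smoothing (default 5).
#' @return Data frame with columns `start`, `end` (times), `start_idx`,
#'   `end_idx`; zero rows when no stagnation occurs.
#' @export
stagnation_periods <- function(area, t, tol_rate, min_duration,
                               smoothing_window = 5L) {
  stopifnot(tol_rate > 0, min_duration > 0)
  r <- series_rate(area, t, smoothing_window)
  flat <- abs(r) < tol_rate
  onset <- which(r < -tol_rate)[1L]
  empty <- data.frame(start = numeric(), end = numeric(),
                      start_idx = integer(), end_idx = integer())
  if (is.na(onset)) return(empty)
  runs <- rle(flat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & starts >= onset
  starts <- starts[keep]; ends <- ends[keep]
  # constriction must recommence after the interval
  neg_idx <- which(r < -tol_rate)
  resumes <- vapply(ends, function(e) any(neg_idx > e), TRUE)
  starts <- starts[resumes]; ends <- ends[resumes]
  dur <- t[ends] - t[starts]
  sel <- dur >= min_duration
  if (!any(sel)) return(empty)
  data.frame(start = t[starts[sel]], end = t[ends[sel]],
             start_idx = starts[sel], end_idx = ends[sel])
}

## Unit normalization ----------------------------------------------------------

#' Normalization rule for model units
#'
#' Maps the run span to real time (furrow formation takes about 10 minutes in
#' live recordings, hence 600 s) and model areas to square micrometres.
#'
#' @param total_seconds Real-time span assigned to the whole run (default 600).
#' @param area_scale Square micrometres per model area unit (default 1).
#' @param require_completion Error when normalizing a run that did not reach
#'   the furrow-width completion criterion (default TRUE).
#' @return A `vf_norm_rule` list.
#' @export
normalization_rule <- function(total_seconds = 600, area_scale = 1,
                               require_completion = TRUE) {
  stopifnot(total_seconds > 0, area_scale > 0)
  structure(list(total_seconds = total_seconds, area_scale = area_scale,
                 require_completion = require_completion),
            class = "vf_norm_rule")
}

#' Normalize archived traces to seconds and square micrometres
#'
#' Rescales trace times so the run spans `total_seconds` and areas by
#' `area_scale` (centroid coordinates by its square root; eccentricity is
#' scale-invariant and untouched).
#'
#' @param archive A `vf_archive`.
#' @param rule A [normalization_rule()].
#' @return Long trace data frame (see [archive_traces()]) with `t` in seconds
#'   and `area` in square micrometres.
#' @export
normalize_units <- function(archive, rule = normalization_rule()) {
  if (rule$require_completion && !isTRUE(archive$completed)) {
    stop("run did not reach furrow completion; cannot apply the ",
         "completion-based time normalization")
  }
  df <- archive_traces(archive)
  t_end <- max(df$t)
  if (t_end <= 0) stop("zero-length run cannot be normalized")
  df$t <- df$t / t_end * rule$total_seconds
  df$area <- df$area * rule$area_scale
  df$centroid_x <- df$centroid_x * sqrt(rule$area_scale)
  df$centroid_y <- df$centroid_y * sqrt(rule$area_scale)
  df
}
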