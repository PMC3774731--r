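# Run configuration, YAML schema, archive serialization, summaries and
# SVG frame rendering.

#' Assemble a run configuration
#'
#' Bundles sheet geometry, mechanical parameters, the contractility program,
#' integration parameters, the unit-normalization rule and the master seed.
#' Everything a run needs is in this object (plus the seed-derived noise),
#' which is what makes archives replayable.
#'
#' @param n_rows,n_cols,edge_length,margin_cols Sheet spec (see
#'   [build_hex_sheet()]).
#' @param mech A [mech_params()] set.
#' @param program A [contractility_program()] (NULL when `custom_gamma` is
#'   given).
#' @param integration An [integration_params()] set.
#' @param normalization A [normalization_rule()].
#' @param master_seed Integer seed controlling all randomness.
#' @param sheet Optional prebuilt `vf_sheet` overriding the sheet spec (used
#'   by the rosette and geometry variants).
#' @param custom_gamma Optional `function(sheet, t)` returning per-cell Gamma,
#'   replacing the program (used by the reduced model).
#' @return A `vf_config`.
#' @export
run_config <- function(n_rows = 15L, n_cols = 24L, edge_length = 1,
                       margin_cols = 2L, mech = mech_params(),
                       program = contractility_program(),
                       integration = integration_params(),
                       normalization = normalization_rule(),
                       master_seed = 1L, sheet = NULL, custom_gamma = NULL) {
  if (!is.null(program)) {
    stopifnot(inherits(program, "vf_program"))
    nr <- if (is.null(sheet)) n_rows else sheet$n_rows
    if (program$n_central_rows > nr) {
      stop("contractile band wider than the sheet (n_central_rows > n_rows)")
    }
  }
  stopifnot(inherits(mech, "vf_mech_params"),
            inherits(integration, "vf_int_params"),
            inherits(normalization, "vf_norm_rule"))
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    edge_length = as.numeric(edge_length),
    margin_cols = as.integer(margin_cols),
    mech = mech, program = program, integration = integration,
    normalization = normalization,
    master_seed = as.integer(master_seed),
    sheet = sheet, custom_gamma = custom_gamma
  ), class = "vf_config")
}

#' @export
print.vf_config <- function(x, ...) {
  cat(sprintf("<vf_config> sheet %d x %d (margin %d cols), seed %d\n",
              x$n_rows, x$n_cols, x$margin_cols, x$master_seed))
  cat(sprintf("  program: %s; dt %g, max %d steps\n",
              if (is.null(x$program)) "custom gamma function"
              else x$program$variant,
              x$integration$dt, x$integration$max_steps))
  invisible(x)
}

## YAML config files -----------------------------------------------------------

config_schema <- list(
  top = c("preset", "sheet", "mech", "program", "integration",
          "normalization", "master_seed"),
  sheet = c("n_rows", "n_cols", "edge_length", "margin_cols"),
  mech = c("K", "A0", "lambda_transverse", "lambda_vertical", "lambda_margin",
           "kappa_edge", "rest_length"),
  program = c("variant", "gamma_cutoff", "gamma_mid", "sigma_width",
              "gamma_init", "alpha_rate", "gamma_max", "sigma_wiener",
              "n_central_rows", "twi_umax"),
  integration = c("dt", "friction_eta", "eps_t1", "t1_separation",
                  "t1_cooldown", "max_steps", "furrow_threshold",
                  "snapshot_every"),
  normalization = c("total_seconds", "area_scale", "require_completion")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")))
  }
}

#' Load and validate a YAML run configuration
#'
#' Schema: optional `preset` name plus `sheet`, `mech`, `program`,
#' `integration`, `normalization` sections and `master_seed`; all fields
#' default to the standard values (or the preset's), unknown keys are
#' rejected, and every constructor invariant (positive K, non-negative
#' tensions and contractility, odd band width, ...) is enforced before a run
#' can start.
#'
#' @param path Path to a YAML file.
#' @return A validated `vf_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys(raw, config_schema$top, "config")
  base <- if (!is.null(raw$preset)) preset_config(raw$preset) else run_config()
  for (sec in c("sheet", "mech", "program", "integration", "normalization")) {
    if (!is.null(raw[[sec]])) check_keys(raw[[sec]], config_schema[[sec]], sec)
  }
  sh <- raw$sheet
  pick <- function(section, key, default) {
    v <- section[[key]]
    if (is.null(v)) default else v
  }
  mech <- do.call(mech_params, utils::modifyList(
    unclass(base$mech), if (is.null(raw$mech)) list() else raw$mech))
  program <- base$program
  if (!is.null(raw$program) || !is.null(base$program)) {
    prog_args <- utils::modifyList(
      if (is.null(base$program)) list() else unclass(base$program),
      if (is.null(raw$program)) list() else raw$program)
    program <- do.call(contractility_program, prog_args)
  }
  integration <- do.call(integration_params, utils::modifyList(
    unclass(base$integration),
    if (is.null(raw$integration)) list() else raw$integration))
  normalization <- do.call(normalization_rule, utils::modifyList(
    unclass(base$normalization),
    if (is.null(raw$normalization)) list() else raw$normalization))
  run_config(
    n_rows = pick(sh, "n_rows", base$n_rows),
    n_cols = pick(sh, "n_cols", base$n_cols),
    edge_length = pick(sh, "edge_length", base$edge_length),
    margin_cols = pick(sh, "margin_cols", base$margin_cols),
    mech = mech, program = program, integration = integration,
    normalization = normalization,
    master_seed = if (is.null(raw$master_seed)) base$master_seed
                  else raw$master_seed,
    sheet = base$sheet
  )
}

#' Write a configuration to YAML
#'
#' Writes every effective parameter value, so `load_config(save_config(x))`
#' reproduces `x` exactly.
#'
#' @param config A `vf_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (!is.null(config$sheet) || !is.null(config$custom_gamma)) {
    stop("configs holding a prebuilt sheet or a custom gamma function ",
         "cannot be serialized to YAML")
  }
  obj <- list(
    sheet = list(n_rows = config$n_rows, n_cols = config$n_cols,
                 edge_length = config$edge_length,
                 margin_cols = config$margin_cols),
    mech = unclass(config$mech),
    program = if (is.null(config$program)) NULL else unclass(config$program),
    integration = unclass(config$integration),
    normalization = unclass(config$normalization),
    master_seed = config$master_seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

## Archive serialization -------------------------------------------------------

#' Write a run archive to a directory
#'
#' Text-only container: `manifest.json` (config, noise paths at full
#' precision, energy and furrow series, run metadata), `traces.csv` (the long
#' per-cell trace table), `t1_events.csv`, and one JSON mesh per snapshot
#' under `snapshots/`. Everything needed for a bit-exact [replay()] is
#' included.
#'
#' @param archive A `vf_archive`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_archive <- function(archive, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "snapshots"), showWarnings = FALSE)
  cfg <- archive$config
  manifest <- list(
    config = list(
      sheet = list(n_rows = cfg$n_rows, n_cols = cfg$n_cols,
                   edge_length = cfg$edge_length,
                   margin_cols = cfg$margin_cols),
      mech = unclass(cfg$mech),
      program = if (is.null(cfg$program)) NULL else unclass(cfg$program),
      integration = unclass(cfg$integration),
      normalization = unclass(cfg$normalization),
      master_seed = cfg$master_seed
    ),
    noise = if (is.null(archive$noise)) NULL else list(
      master_seed = archive$noise$master_seed, dt = archive$noise$dt,
      U = archive$noise$U, dW = archive$noise$dW
    ),
    modifications = archive$modifications,
    energy = archive$energy,
    furrow = archive$furrow,
    n_steps_run = archive$n_steps_run,
    completed = archive$completed,
    energy_increases = archive$energy_increases,
    snapshot_steps = vapply(archive$snapshots, `[[`, 0, "step")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = I(17), auto_unbox = TRUE, null = "null")
  utils::write.csv(archive_traces(archive), file.path(dir, "traces.csv"),
                   row.names = FALSE)
  utils::write.csv(archive$t1_events, file.path(dir, "t1_events.csv"),
                   row.names = FALSE)
  for (sn in archive$snapshots) {
    snap_sheet <- archive$final_sheet
    snap_sheet$pos <- sn$pos
    snap_sheet$cells <- sn$cells
    snap_sheet <- rebuild_topology(snap_sheet)
    sheet_to_json(snap_sheet,
                  file.path(dir, "snapshots",
                            sprintf("step_%06d.json", sn$step)))
  }
  invisible(dir)
}

#' Read back an archived run sufficiently for replay
#'
#' Restores the configuration and noise paths from `manifest.json`; the
#' returned object can be passed to [replay()] to regenerate traces and
#' snapshots bit-exactly.
#'
#' @param dir Directory written by [write_archive()].
#' @return A `vf_archive` stub (config + noise + stored series).
#' @export
read_archive <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  cfg <- man$config
  config <- run_config(
    n_rows = cfg$sheet$n_rows, n_cols = cfg$sheet$n_cols,
    edge_length = cfg$sheet$edge_length, margin_cols = cfg$sheet$margin_cols,
    mech = do.call(mech_params, as.list(cfg$mech)),
    program = if (is.null(cfg$program)) NULL
              else do.call(contractility_program, as.list(cfg$program)),
    integration = {
      it <- as.list(cfg$integration)
      if (is.null(it$furrow_threshold)) it$furrow_threshold <- NA_real_
      do.call(integration_params, it)
    },
    normalization = do.call(normalization_rule, as.list(cfg$normalization)),
    master_seed = cfg$master_seed
  )
  noise <- NULL
  if (!is.null(man$noise)) {
    dW <- man$noise$dW
    if (!is.matrix(dW)) dW <- matrix(dW, nrow = length(man$noise$U))
    storage.mode(dW) <- "double"
    noise <- structure(list(
      dW = dW,
      U = as.numeric(man$noise$U),
      master_seed = man$noise$master_seed, dt = man$noise$dt
    ), class = "vf_noise")
  }
  structure(list(config = config, noise = noise,
                 energy = man$energy, furrow = man$furrow,
                 n_steps_run = man$n_steps_run, completed = man$completed),
            class = "vf_archive")
}

## Summaries -------------------------------------------------------------------

#' Summarize a completed run
#'
#' JSON-ready record: final furrow width, per-row mean and s.d. of final area
#' and eccentricity, T1 swap count, stagnation counts over ventral cells and
#' the correlation-maximizing forward offset of the contractility rate (in
#' normalized seconds; NA for runs that did not complete or are
#' deterministic). All fields are recomputable from the traces alone.
#'
#' @param archive A `vf_archive`.
#' @param offsets_s Candidate forward offsets in normalized seconds.
#' @return A list.
#' @export
summarize_run <- function(archive, offsets_s = seq(0, 30, by = 1)) {
  sheet <- archive$final_sheet
  tr <- archive$traces
  last <- length(tr$step)
  area_f <- tr$area[, last]
  ecc_f <- tr$eccentricity[, last]
  rows <- sort(unique(sheet$cell_row))
  per_row <- data.frame(
    row = rows,
    mean_area = vapply(rows, function(r) mean(area_f[sheet$cell_row == r &
                                                       !sheet$cell_margin]), 0),
    sd_area = vapply(rows, function(r) stats::sd(area_f[sheet$cell_row == r &
                                                          !sheet$cell_margin]), 0),
    mean_ecc = vapply(rows, function(r) mean(ecc_f[sheet$cell_row == r &
                                                     !sheet$cell_margin]), 0),
    sd_ecc = vapply(rows, function(r) stats::sd(ecc_f[sheet$cell_row == r &
                                                        !sheet$cell_margin]), 0)
  )
  out <- list(
    n_steps_run = archive$n_steps_run,
    completed = archive$completed,
    final_furrow_width = archive$furrow[length(archive$furrow)],
    t1_count = sum(archive$t1_events$type == "swap"),
    per_row = per_row,
    stagnation_counts = NULL,
    best_offset_s = NA_real_
  )
  stochastic <- !is.null(archive$config$program) &&
    archive$config$program$variant %in%
      c("gradient_stochastic", "gradient_alternative", "twi")
  if (archive$completed && archive$n_steps_run > 20L) {
    rl <- rate_lag_analysis(archive)
    out$stagnation_counts <- rl$stagnation_counts
    if (stochastic) out$best_offset_s <- rl$best_offset_s
  }
  out
}

#' Contractility-rate / constriction-rate lag analysis of a run
#'
#' Normalizes the run to real time, computes smoothed contractility-rate and
#' area-reduction-rate series for every ventral cell (five central rows,
#' margins excluded), averages per-offset Pearson correlations across cells
#' (contractility rate shifted forward in time) and locates the
#' correlation-maximizing offset. Also counts stagnation periods per ventral
#' cell with the default thresholds (rate within 2 percent of A0 per 10 s for
#' at least 30 s).
#'
#' @param archive A completed `vf_archive`.
#' @param offsets_s Candidate forward offsets in normalized seconds.
#' @param smoothing_window Samples for rate smoothing.
#' @return List: `best_offset_s`, `offsets_s`, `mean_correlation` (per
#'   offset), `n_cells`, `stagnation_counts` (per ventral cell),
#'   `significant_positive` (fraction of ventral cells with p < 0.05 positive
#'   zero-lag rate correlation).
#' @export
rate_lag_analysis <- function(archive, offsets_s = seq(0, 30, by = 1),
                              smoothing_window = 5L, sample_every_s = 1) {
  sheet <- archive$final_sheet
  rule <- archive$config$normalization
  df_t <- archive$traces$t
  t_end <- max(df_t)
  raw_t_s <- df_t / t_end * rule$total_seconds
  ventral <- ventral_cells(sheet, exclude_border_cols = 2L)
  # resample to a fixed real-time cadence so rates and offsets do not depend
  # on the integrator step (live recordings are sampled every few seconds)
  t_s <- seq(0, rule$total_seconds, by = sample_every_s)
  pick <- vapply(t_s, function(ts) which.min(abs(raw_t_s - ts)), 0L)
  dt_s <- sample_every_s
  area <- archive$traces$area[ventral, pick, drop = FALSE]
  gam <- archive$traces$gamma[ventral, pick, drop = FALSE]
  n_t <- length(t_s)
  rate_g <- t(apply(gam, 1L, series_rate, t = t_s,
                    smoothing_window = smoothing_window))
  rate_c <- -t(apply(area, 1L, series_rate, t = t_s,
                     smoothing_window = smoothing_window))
  offsets <- unique(pmin(round(offsets_s / dt_s), n_t - 3L))
  offsets <- offsets[offsets >= 0]
  lc <- lagged_correlation(rate_g, rate_c, offsets)
  A0 <- archive$config$mech$A0
  tol <- 0.02 * A0 / 10
  counts <- vapply(seq_along(ventral), function(i) {
    nrow(stagnation_periods(area[i, ], t_s, tol_rate = tol,
                            min_duration = 30,
                            smoothing_window = smoothing_window))
  }, 0L)
  pvals <- vapply(seq_along(ventral), function(i) {
    ct <- stats::cor.test(rate_g[i, ], rate_c[i, ],
                          alternative = "greater")
    ct$p.value
  }, 0)
  list(best_offset_s = lc$best_offset * dt_s,
       offsets_s = offsets * dt_s,
       mean_correlation = lc$correlation,
       n_cells = length(ventral),
       stagnation_counts = counts,
       significant_positive = mean(pvals < 0.05))
}

## Frame rendering -------------------------------------------------------------

value_to_color <- function(v, lo, hi) {
  ramp <- grDevices::colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))
  z <- (v - lo) / max(hi - lo, .Machine$double.eps)
  z[!is.finite(z)] <- 0
  z <- pmin(pmax(z, 0), 1)
  cols <- ramp(z)
  sprintf("#%02x%02x%02x", round(cols[, 1L]), round(cols[, 2L]),
          round(cols[, 3L]))
}

#' Render archived snapshots as SVG frames
#'
#' One deterministic vector image per snapshot, cells colour-coded by apical
#' area (blue large, red small) or by contractility (white zero, red maximal).
#' Identical archives render to byte-identical files.
#'
#' @param archive A `vf_archive` with snapshots.
#' @param out_dir Output directory.
#' @param color_by `"area"` or `"gamma"`.
#' @return Character vector of file paths, invisibly.
#' @export
render_frames <- function(archive, out_dir, color_by = c("area", "gamma")) {
  color_by <- match.arg(color_by)
  if (is.null(archive$snapshots) || !length(archive$snapshots)) {
    stop("archive contains no snapshots to render")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p0 <- archive$snapshots[[1L]]$pos
  xr <- range(p0[, 1L]); yr <- range(p0[, 2L])
  pad <- 0.05 * max(diff(xr), diff(yr))
  A0 <- archive$config$mech$A0
  gmax <- if (!is.null(archive$config$program)) {
    max(archive$config$program$gamma_max, archive$config$program$gamma_mid,
        archive$config$program$gamma_cutoff)
  } else max(archive$traces$gamma, 1e-12)
  files <- character(length(archive$snapshots))
  base <- archive$final_sheet
  for (si in seq_along(archive$snapshots)) {
    sn <- archive$snapshots[[si]]
    col_idx <- sn$step + 1L
    vals <- if (color_by == "area") {
      sh <- base; sh$pos <- sn$pos; sh$cells <- sn$cells
      sh <- rebuild_topology(sh)
      cell_areas(sh)
    } else {
      archive$traces$gamma[, min(col_idx, ncol(archive$traces$gamma))]
    }
    cols <- if (color_by == "area") {
      value_to_color(-vals, -1.1 * A0, 0)   # small area -> red
    } else {
      value_to_color(vals, 0, gmax)
    }
    lines <- c(
      sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                     'viewBox="%.4f %.4f %.4f %.4f">'),
              xr[1L] - pad, yr[1L] - pad,
              diff(xr) + 2 * pad, diff(yr) + 2 * pad),
      sprintf('<g transform="translate(0 %.4f) scale(1 -1)">',
              yr[1L] + yr[2L]),
      vapply(seq_along(sn$cells), function(ci) {
        ring <- sn$pos[sn$cells[[ci]], , drop = FALSE]
        sprintf('<polygon points="%s" fill="%s" stroke="#333333" stroke-width="0.03"/>',
                paste(sprintf("%.5f,%.5f", ring[, 1L], ring[, 2L]),
                      collapse = " "),
                cols[ci])
      }, ""),
      "</g>", "</svg>")
    files[si] <- file.path(out_dir, sprintf("frame_%06d.svg", sn$step))
    writeLines(lines, files[si])
  }
  invisible(files)
}
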