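# Time integration, T1 neighbour exchanges, termination, archiving and replay.
#
# Vertices obey overdamped dynamics: friction balances the potential force,
# dx/dt = F/eta, integrated with an explicit Euler scheme. Boundary vertices
# are clamped. Whenever an interior edge drops below the critical length
# eps_t1 the two cells sharing it lose adjacency and the two flanking cells
# gain it (T1 transition); the collapsed edge re-opens perpendicular through
# its midpoint at length t1_separation.

#' Integration parameter set
#'
#' Model time is counted in schedule units: the contractility ramps, halt
#' windows and Wiener paths all advance with t-tilde, one unit per nominal
#' model time-step. The friction coefficient eta = 60 is the smallest value
#' (on a decade scan) for which a literal one-Euler-step-per-unit scheme
#' still descends the energy cleanly through the strongly constricted late
#' furrow with the standard mechanical parameters; the integrator subdivides
#' each unit into `1/dt` sub-steps for topological robustness (sub-step
#' displacement factor h = dt/eta ~ 0.008 at the defaults), which leaves the
#' dynamics unchanged.
#'
#' @param dt Euler sub-step in model-time units (default 0.5).
#' @param friction_eta Friction coefficient in model-time units (default 60).
#' @param eps_t1 Critical edge length triggering a T1 swap (default 0.1).
#' @param t1_separation Length of the re-opened edge after a swap (default
#'   0.15; must exceed `eps_t1`).
#' @param t1_cooldown Sub-steps during which a just-swapped vertex pair is
#'   immune to re-swapping (default 20, i.e. 10 model-time units),
#'   preventing flip-flopping.
#' @param max_steps Maximum number of Euler sub-steps (default 1200 = 600
#'   model-time units).
#' @param furrow_threshold Completion threshold on the furrow width as a
#'   fraction of A0 (default 0.35); NA disables the criterion (fixed-length
#'   runs).
#' @param snapshot_every Mesh snapshot cadence in sub-steps (default 2, one
#'   per model-time unit). Traces are recorded every sub-step.
#' @return A `vf_int_params` list.
#' @export
integration_params <- function(dt = 0.5, friction_eta = 60, eps_t1 = 0.1,
                               t1_separation = 0.15, t1_cooldown = 20L,
                               max_steps = 1200L, furrow_threshold = 0.35,
                               snapshot_every = 2L) {
  if (is.null(furrow_threshold)) furrow_threshold <- NA_real_
  stopifnot(dt > 0, friction_eta > 0, eps_t1 > 0, t1_separation > eps_t1,
            max_steps >= 0, snapshot_every >= 1)
  structure(list(dt = dt, friction_eta = friction_eta, eps_t1 = eps_t1,
                 t1_separation = t1_separation,
                 t1_cooldown = as.integer(t1_cooldown),
                 max_steps = as.integer(max_steps),
                 furrow_threshold = furrow_threshold,
                 snapshot_every = as.integer(snapshot_every)),
            class = "vf_int_params")
}

#' One explicit Euler step
#'
#' Moves every free vertex by `(dt/eta) * force`; fixed vertices stay put.
#'
#' @param sheet A `vf_sheet`.
#' @param params A [mech_params()] set.
#' @param gamma Per-cell contractility.
#' @param int_params An [integration_params()] set.
#' @return The sheet with updated vertex positions.
#' @export
euler_step <- function(sheet, params, gamma, int_params) {
  f <- vertex_forces(sheet, params, gamma)
  free <- !sheet$fixed
  sheet$pos[free, ] <- sheet$pos[free, , drop = FALSE] +
    (int_params$dt / int_params$friction_eta) * f[free, , drop = FALSE]
  sheet
}

# Cells incident to each vertex, as a list indexed by vertex id.
vertex_cells <- function(sheet) {
  split(sheet$cv$cell, factor(sheet$cv$v, levels = seq_len(nrow(sheet$pos))))
}

#' Neighbouring cells of a cell
#' @param sheet A `vf_sheet`.
#' @param cell Cell index.
#' @return Integer vector of cells sharing an edge with `cell`.
#' @export
cell_neighbors <- function(sheet, cell) {
  ec <- sheet$edge_cells
  hit <- ec[, 1L] == cell | (!is.na(ec[, 2L]) & ec[, 2L] == cell)
  nb <- c(ec[hit, 1L], ec[hit, 2L])
  sort(unique(nb[!is.na(nb) & nb != cell]))
}

# Execute a single T1 swap on edge (a, b). Ring surgery: with P the cell whose
# CCW ring runs (a, b) and Q the cell running (b, a), P keeps a, Q keeps b,
# and the flanking cells R (third cell at a) and S (third cell at b) insert
# the missing endpoint immediately before the one they already hold. The new
# edge opens perpendicular to the old one through its midpoint.
t1_swap <- function(sheet, a, b, separation) {
  cv <- sheet$cv
  P <- cv$cell[cv$v == a & cv$vn == b]
  Q <- cv$cell[cv$v == b & cv$vn == a]
  if (length(P) != 1L || length(Q) != 1L) return(NULL)
  cells_a <- cv$cell[cv$v == a]
  cells_b <- cv$cell[cv$v == b]
  R <- setdiff(cells_a, c(P, Q))
  S <- setdiff(cells_b, c(P, Q))
  if (length(R) != 1L || length(S) != 1L || R == S) return(NULL)
  # refuse a swap that would duplicate an existing R-S adjacency
  ec <- sheet$edge_cells
  if (any(!is.na(ec[, 2L]) &
          ((ec[, 1L] == R & ec[, 2L] == S) |
           (ec[, 1L] == S & ec[, 2L] == R)))) return(NULL)
  if (length(sheet$cells[[P]]) <= 3L || length(sheet$cells[[Q]]) <= 3L) {
    return(NULL)  # removing a vertex would degenerate the ring
  }
  pa <- sheet$pos[a, ]; pb <- sheet$pos[b, ]
  m <- (pa + pb) / 2
  u <- (pb - pa) / sqrt(sum((pb - pa)^2))
  perp <- c(-u[2L], u[1L])
  sheet$pos[a, ] <- m + (separation / 2) * perp
  sheet$pos[b, ] <- m - (separation / 2) * perp
  drop_vertex <- function(ring, v) ring[ring != v]
  insert_before <- function(ring, anchor, v) {
    k <- match(anchor, ring)
    append(ring, v, after = k - 1L)
  }
  sheet$cells[[P]] <- drop_vertex(sheet$cells[[P]], b)
  sheet$cells[[Q]] <- drop_vertex(sheet$cells[[Q]], a)
  sheet$cells[[R]] <- insert_before(sheet$cells[[R]], a, b)
  sheet$cells[[S]] <- insert_before(sheet$cells[[S]], b, a)
  sheet <- rebuild_topology(sheet)
  # a swap whose re-opened edge would twist a flanking ring is not admissible
  # in the current geometry; the caller skips it (the edge stays short and may
  # swap later once the neighbourhood has relaxed)
  for (ci in c(P, Q, R, S)) {
    ring <- sheet$pos[sheet$cells[[ci]], , drop = FALSE]
    if (polygon_area(ring) <= 0 || ring_self_intersects(ring)) return(NULL)
  }
  list(sheet = sheet, cells = c(P, Q, R, S))
}

#' Apply all due T1 transitions
#'
#' Scans interior edges shorter than `eps_t1` whose endpoints are both free
#' and trivalent, and swaps them shortest-first. Edges touching a fixed vertex
#' or the outer boundary are skipped and logged, never raised as errors.
#'
#' @param sheet A `vf_sheet`.
#' @param int_params An [integration_params()] set.
#' @param cooldown Named integer vector of vertex-pair cooldowns (internal).
#' @param step Current step number (for the event log).
#' @return List: `sheet`, `events` (data frame: step, type, v1, v2, cells
#'   losing/gaining adjacency), `cooldown`.
#' @export
apply_t1_transitions <- function(sheet, int_params, cooldown = integer(),
                                 step = 0L) {
  events <- list()
  first_pass <- TRUE
  repeat {
    geo <- edge_geometry(sheet)
    short <- which(geo$len < int_params$eps_t1)
    if (!length(short)) break
    interior <- !is.na(sheet$edge_cells[short, 2L])
    a <- sheet$edges[short, 1L]; b <- sheet$edges[short, 2L]
    movable <- !sheet$fixed[a] & !sheet$fixed[b]
    ncell <- tabulate(sheet$cv$v, nbins = nrow(sheet$pos))
    trivalent <- ncell[a] == 3L & ncell[b] == 3L
    keys <- paste(pmin(a, b), pmax(a, b), sep = ":")
    cooled <- keys %in% names(cooldown)[cooldown > step]
    ok <- interior & movable & trivalent & !cooled
    if (first_pass) {
      for (e in short[!ok & !cooled]) {
        events[[length(events) + 1L]] <- data.frame(
          step = step, type = "skipped",
          v1 = sheet$edges[e, 1L], v2 = sheet$edges[e, 2L],
          cell_lost_1 = NA_integer_, cell_lost_2 = NA_integer_,
          cell_gained_1 = NA_integer_, cell_gained_2 = NA_integer_)
        # re-log a persistently short ineligible edge only once per cooldown
        cooldown[paste(min(sheet$edges[e, ]), max(sheet$edges[e, ]),
                       sep = ":")] <- step + int_params$t1_cooldown
      }
      first_pass <- FALSE
    }
    cand <- short[ok]
    if (!length(cand)) break
    e <- cand[which.min(geo$len[cand])]
    va <- sheet$edges[e, 1L]; vb <- sheet$edges[e, 2L]
    res <- t1_swap(sheet, va, vb, int_params$t1_separation)
    key <- paste(min(va, vb), max(va, vb), sep = ":")
    if (is.null(res)) {
      # configuration does not admit a swap; log and freeze so the scan ends
      events[[length(events) + 1L]] <- data.frame(
        step = step, type = "skipped", v1 = va, v2 = vb,
        cell_lost_1 = NA_integer_, cell_lost_2 = NA_integer_,
        cell_gained_1 = NA_integer_, cell_gained_2 = NA_integer_)
      cooldown[key] <- step + int_params$t1_cooldown
      next
    }
    sheet <- res$sheet
    cooldown[key] <- step + int_params$t1_cooldown
    events[[length(events) + 1L]] <- data.frame(
      step = step, type = "swap", v1 = va, v2 = vb,
      cell_lost_1 = res$cells[1L], cell_lost_2 = res$cells[2L],
      cell_gained_1 = res$cells[3L], cell_gained_2 = res$cells[4L])
  }
  cooldown <- cooldown[cooldown > step]
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(step = integer(), type = character(), v1 = integer(),
               v2 = integer(), cell_lost_1 = integer(),
               cell_lost_2 = integer(), cell_gained_1 = integer(),
               cell_gained_2 = integer())
  list(sheet = sheet, events = events, cooldown = cooldown)
}

#' Furrow width
#'
#' Mean apical area of the cells in the five centralmost rows (midline +- 2),
#' margin cells excluded; the completion criterion of a run.
#'
#' @param sheet A `vf_sheet` with at least 5 rows.
#' @return Scalar mean area.
#' @export
furrow_width <- function(sheet) {
  if (sheet$n_rows < 5L) stop("furrow width needs at least 5 cell rows")
  sel <- abs(sheet$cell_row - sheet$midline) <= 2L & !sheet$cell_margin
  mean(cell_areas(sheet)[sel])
}

## Run loop --------------------------------------------------------------------

# Normalise a modification list into a canonical form.
canon_mods <- function(modifications, n_cells) {
  if (is.null(modifications) || !length(modifications)) return(list())
  if (!is.null(modifications$cells)) modifications <- list(modifications)
  lapply(modifications, function(m) {
    cells <- as.integer(m$cells)
    if (any(is.na(cells)) || any(cells < 1L) || any(cells > n_cells)) {
      stop("modification references unknown cell")
    }
    list(cells = cells,
         gamma = if (is.null(m$gamma)) 0 else m$gamma,
         from_step = if (is.null(m$from_step)) 1L else as.integer(m$from_step),
         to_step = if (is.null(m$to_step)) .Machine$integer.max
                   else as.integer(m$to_step))
  })
}

apply_mods <- function(gamma, mods, step) {
  for (m in mods) {
    if (step >= m$from_step && step <= m$to_step) gamma[m$cells] <- m$gamma
  }
  gamma
}

#' Run a simulation
#'
#' Executes the loop: evaluate Gamma(t) -> forces -> Euler step -> T1 pass ->
#' record, until `max_steps` or until the furrow width falls below
#' `furrow_threshold * A0`. The returned archive (config, noise paths, per-cell
#' traces, mesh snapshots, T1 event log) is self-contained: re-running it
#' through [replay()] with no modifications reproduces every trace bit-exactly.
#'
#' @param config A [run_config()] bundle.
#' @param noise Optional `vf_noise`; when NULL, sampled from
#'   `config$master_seed` (stochastic variants only).
#' @param modifications Declarative contractility overrides (see [replay()]).
#' @return A `vf_archive`.
#' @export
run_simulation <- function(config, noise = NULL, modifications = NULL) {
  mech <- config$mech
  program <- config$program
  ip <- config$integration
  sheet <- if (!is.null(config$sheet)) config$sheet else
    build_hex_sheet(config$n_rows, config$n_cols, config$edge_length,
                    margin_cols = config$margin_cols)
  n_c <- length(sheet$cells)
  n_v <- nrow(sheet$pos)
  mods <- canon_mods(modifications, n_c)
  stochastic <- !is.null(program) &&
    program$variant %in% c("gradient_stochastic", "gradient_alternative", "twi")
  if (stochastic && is.null(noise)) {
    noise <- sample_noise(config$master_seed, sheet, ip$max_steps, ip$dt,
                          twi_umax = program$twi_umax)
  }
  W <- numeric(n_c)
  y_mid <- NULL
  if (!is.null(program) && program$variant == "gradient_alternative") {
    cen0 <- cell_centroids(sheet)
    y_mid <- mean(cen0[sheet$cell_row == sheet$midline & !sheet$cell_margin, 2L])
  }
  gamma_of <- function(t, next_step) {
    g <- if (!is.null(config$custom_gamma)) {
      pmax(config$custom_gamma(sheet, t), 0)
    } else if (program$variant == "gradient_alternative") {
      cen <- cell_centroids(sheet)
      wgt <- alternative_gradient_weight(program, cen[, 2L], y_mid,
                                         sqrt(3) * sheet$edge_length)
      wgt[sheet$cell_margin] <- 0
      program_gamma(program, sheet, t, W = W, U = noise$U, weight = wgt)
    } else {
      program_gamma(program, sheet, t, W = W,
                    U = if (is.null(noise)) NULL else noise$U)
    }
    apply_mods(g, mods, next_step)
  }

  n_rec <- ip$max_steps + 1L
  tr_area <- matrix(NA_real_, n_c, n_rec)
  tr_gamma <- matrix(NA_real_, n_c, n_rec)
  tr_ecc <- matrix(NA_real_, n_c, n_rec)
  tr_cx <- matrix(NA_real_, n_c, n_rec)
  tr_cy <- matrix(NA_real_, n_c, n_rec)
  energy <- numeric(n_rec)
  fw <- numeric(n_rec)
  snapshots <- list()
  t1_log <- list()
  cooldown <- integer()
  n_increase <- 0L
  n_guard <- 0L
  n_guard_unresolved <- 0L

  record <- function(k) {
    tr_area[, k + 1L] <<- cell_areas(sheet)
    tr_gamma[, k + 1L] <<- gamma_cur
    cen <- cell_centroids(sheet)
    tr_cx[, k + 1L] <<- cen[, 1L]
    tr_cy[, k + 1L] <<- cen[, 2L]
    tr_ecc[, k + 1L] <<- cell_eccentricity(sheet)
    energy[k + 1L] <<- total_energy(sheet, mech, gamma_cur)
    fw[k + 1L] <<- if (sheet$n_rows >= 5L) furrow_width(sheet) else
      mean(cell_areas(sheet))
    if (k %% ip$snapshot_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <<-
        list(step = k, pos = sheet$pos, cells = sheet$cells)
    }
  }

  gamma_cur <- gamma_of(0, 1L)
  record(0L)
  completed <- FALSE
  k_final <- 0L
  scale <- ip$dt / ip$friction_eta
  free <- !sheet$fixed
  if (ip$max_steps > 0L) {
    for (k in seq_len(ip$max_steps)) {
      check_gamma(sheet, gamma_cur)
      # the step descends the energy with the tension classification frozen
      # at its start; class flips and T1 swaps may legitimately jump E
      et <- edge_tensions(sheet, mech)
      A_pre <- cell_areas(sheet)
      e_before <- energy_from_state(mech, gamma_cur, A_pre, et$lambda,
                                    et$len, sheet$edge_length)
      f <- forces_from_state(sheet, mech, gamma_cur, A_pre, et)
      pos_pre <- sheet$pos
      sheet$pos[free, ] <- sheet$pos[free, , drop = FALSE] +
        scale * f[free, , drop = FALSE]
      # embedding guard: the shoelace energy is blind to self-intersection, so
      # a crushed cell could fold through itself; bisect the offending
      # displacements (vertices stall at contact instead of inverting)
      bad <- cells_self_intersecting(sheet)
      if (length(bad)) {
        n_guard <- n_guard + 1L
        for (tries in 1:12) {
          vs <- unique(unlist(sheet$cells[bad], use.names = FALSE))
          vs <- vs[!sheet$fixed[vs]]
          sheet$pos[vs, ] <- (sheet$pos[vs, , drop = FALSE] +
                                pos_pre[vs, , drop = FALSE]) / 2
          bad <- cells_self_intersecting(sheet)
          if (!length(bad)) break
        }
        if (length(bad)) {
          # freeze just the offending cells at their pre-step geometry; the
          # rest of the sheet proceeds
          vs <- unique(unlist(sheet$cells[bad], use.names = FALSE))
          vs <- vs[!sheet$fixed[vs]]
          sheet$pos[vs, ] <- pos_pre[vs, , drop = FALSE]
          if (length(cells_self_intersecting(sheet))) {
            n_guard_unresolved <- n_guard_unresolved + 1L
          }
        }
      }
      len_post <- edge_geometry(sheet)$len
      e_after <- energy_from_state(mech, gamma_cur, cell_areas(sheet),
                                   et$lambda, len_post, sheet$edge_length)
      if (e_after > e_before + 1e-10 * max(1, abs(e_before))) {
        n_increase <- n_increase + 1L
      }
      t1 <- apply_t1_transitions(sheet, ip, cooldown, k)
      if (nrow(t1$events)) {
        t1_log[[length(t1_log) + 1L]] <- t1$events
        if (any(t1$events$type == "swap")) {
          sheet <- t1$sheet
          free <- !sheet$fixed
        }
      }
      cooldown <- t1$cooldown
      if (stochastic) W <- W + noise$dW[, k]
      gamma_cur <- gamma_of(k * ip$dt, k + 1L)
      record(k)
      k_final <- k
      if (!is.na(ip$furrow_threshold) && sheet$n_rows >= 5L &&
          fw[k + 1L] < ip$furrow_threshold * mech$A0) {
        completed <- TRUE
        break
      }
    }
  }
  if (k_final > 0L && n_increase > 0.01 * k_final) {
    warning(sprintf(paste0("energy increased in %d of %d steps outside T1 ",
                           "events; consider a smaller dt"),
                    n_increase, k_final))
  }
  if (is.null(snapshots[[length(snapshots)]]) ||
      snapshots[[length(snapshots)]]$step != k_final) {
    snapshots[[length(snapshots) + 1L]] <-
      list(step = k_final, pos = sheet$pos, cells = sheet$cells)
  }
  keep <- seq_len(k_final + 1L)
  t1_events <- if (length(t1_log)) do.call(rbind, t1_log) else
    data.frame(step = integer(), type = character(), v1 = integer(),
               v2 = integer(), cell_lost_1 = integer(),
               cell_lost_2 = integer(), cell_gained_1 = integer(),
               cell_gained_2 = integer())
  structure(list(
    config = config,
    noise = noise,
    modifications = mods,
    final_sheet = sheet,
    traces = list(step = keep - 1L, t = (keep - 1L) * ip$dt,
                  area = tr_area[, keep, drop = FALSE],
                  gamma = tr_gamma[, keep, drop = FALSE],
                  eccentricity = tr_ecc[, keep, drop = FALSE],
                  centroid_x = tr_cx[, keep, drop = FALSE],
                  centroid_y = tr_cy[, keep, drop = FALSE]),
    energy = energy[keep],
    furrow = fw[keep],
    snapshots = snapshots,
    t1_events = t1_events,
    n_steps_run = k_final,
    completed = completed,
    energy_increases = n_increase,
    guard_events = n_guard,
    guard_unresolved = n_guard_unresolved
  ), class = "vf_archive")
}

#' Replay an archived run, optionally with modifications
#'
#' Re-runs the archived configuration against the archived noise paths. With
#' an empty modification list the result is bit-identical to the original.
#' Modifications are declarative overrides, each a list with `cells` (indices),
#' `gamma` (forced value, default 0), `from_step` / `to_step` (default whole
#' run), e.g. `list(cells = nb, gamma = 0)` switches off contractility of a
#' neighbourhood for the entire run.
#'
#' @param archive A `vf_archive` from [run_simulation()].
#' @param modifications A single override or list of overrides (default none).
#' @return A new `vf_archive`.
#' @export
replay <- function(archive, modifications = NULL) {
  run_simulation(archive$config, noise = archive$noise,
                 modifications = modifications)
}

#' @export
print.vf_archive <- function(x, ...) {
  cat(sprintf("<vf_archive> %d cells, %d steps run%s\n",
              nrow(x$traces$area), x$n_steps_run,
              if (x$completed) " (furrow completed)" else ""))
  cat(sprintf("  final furrow width %.4f, T1 swaps %d, seed %s\n",
              x$furrow[length(x$furrow)],
              sum(x$t1_events$type == "swap"),
              format(x$config$master_seed)))
  invisible(x)
}

#' Per-cell traces as a long data frame
#'
#' Export schema: cell_id, row, col, step, t, area, gamma, eccentricity,
#' centroid_x, centroid_y. Accepted back by the metrics layer, and matches the
#' CSV written by [write_archive()] so externally tracked cells can be
#' analysed with the same functions.
#'
#' @param archive A `vf_archive`.
#' @return A data frame.
#' @export
archive_traces <- function(archive) {
  tr <- archive$traces
  n_c <- nrow(tr$area)
  n_t <- length(tr$step)
  sheet0 <- if (!is.null(archive$config$sheet)) archive$config$sheet else
    build_hex_sheet(archive$config$n_rows, archive$config$n_cols,
                    archive$config$edge_length,
                    margin_cols = archive$config$margin_cols)
  data.frame(
    cell_id = rep(seq_len(n_c), times = n_t),
    row = rep(sheet0$cell_row, times = n_t),
    col = rep(sheet0$cell_col, times = n_t),
    step = rep(tr$step, each = n_c),
    t = rep(tr$t, each = n_c),
    area = as.vector(tr$area),
    gamma = as.vector(tr$gamma),
    eccentricity = as.vector(tr$eccentricity),
    centroid_x = as.vector(tr$centroid_x),
    centroid_y = as.vector(tr$centroid_y)
  )
}
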