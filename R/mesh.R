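# Mesh data structures and geometric primitives.
#
# A sheet is a planar polygonal tiling. Coordinates: x = antero-posterior (AP)
# axis (columns), y = latero-ventral (LV) axis (rows). Hexagons are built
# "flat-top": two edges parallel to the AP axis, four at +-60 degrees, so each
# cell carries two transverse-class and four vertical-class boundaries at rest.

#' Regular hexagon area
#'
#' Area of a regular hexagon with the given edge length, `3*sqrt(3)/2 * s^2`.
#'
#' @param edge_length Edge length (model length units).
#' @return Numeric area.
#' @export
hex_area <- function(edge_length = 1) {
  1.5 * sqrt(3) * edge_length^2
}

## Flat incidence + edge table -------------------------------------------------

# Rebuild derived topology (flat cell/vertex incidence and the edge table)
# from the cell rings. Called after construction and after every T1 swap.
rebuild_topology <- function(sheet) {
  cells <- sheet$cells
  ring_len <- lengths(cells)
  if (any(ring_len < 3L)) stop("degenerate cell ring (fewer than 3 vertices)")
  cell_id <- rep.int(seq_along(cells), ring_len)
  v <- unlist(cells, use.names = FALSE)
  # next/prev vertex within each ring
  idx <- seq_along(v)
  first <- cumsum(c(1L, ring_len[-length(ring_len)]))
  last <- cumsum(ring_len)
  nxt <- idx + 1L
  nxt[last] <- first
  prv <- idx - 1L
  prv[first] <- last
  vn <- v[nxt]
  vp <- v[prv]

  a <- pmin(v, vn)
  b <- pmax(v, vn)
  if (any(v == vn)) stop("edge with identical endpoints")
  nv <- nrow(sheet$pos)
  key <- as.numeric(a) * (nv + 1) + as.numeric(b)
  dup <- duplicated(key)
  eid <- match(key, key[!dup])
  n_e <- sum(!dup)
  cnt <- tabulate(eid, n_e)
  if (any(cnt > 2L)) stop("edge shared by more than two cells")
  edges <- cbind(a[!dup], b[!dup])
  edge_cells <- matrix(NA_integer_, n_e, 2L)
  edge_cells[eid[!dup], 1L] <- cell_id[!dup]
  edge_cells[eid[dup], 2L] <- cell_id[dup]

  sheet$cv <- list(cell = cell_id, v = v, vn = vn, vp = vp, edge = eid)
  sheet$edges <- edges
  sheet$edge_cells <- edge_cells
  # precomputed aggregation indices (fixed until the next topology change):
  # per-cell sums exploit that cv slots are ring-contiguous; per-vertex and
  # per-edge-endpoint sums use sorted run boundaries
  vord <- order(v)
  vs <- v[vord]
  vends <- c(which(vs[-1L] != vs[-length(vs)]), length(vs))
  g <- c(edges[, 1L], edges[, 2L])
  eord <- order(g)
  gs <- g[eord]
  eends <- c(which(gs[-1L] != gs[-length(gs)]), length(gs))
  sheet$agg <- list(
    cell_ptr = c(0L, cumsum(ring_len)),
    vord = vord, vptr = c(0L, vends), vids = vs[vends],
    eord = eord, eptr = c(0L, eends), eids = gs[eends]
  )
  m1 <- sheet$cell_margin[edge_cells[, 1L]]
  c2 <- edge_cells[, 2L]
  m2 <- !is.na(c2) & sheet$cell_margin[ifelse(is.na(c2), 1L, c2)]
  sheet$edge_margin <- m1 | m2
  # non-adjacent segment pairs within each ring, as global cv slot indices;
  # used by the vectorised embedding check
  pair_i <- integer(); pair_j <- integer()
  off <- 0L
  for (L in ring_len) {
    if (L >= 4L) {
      loc <- which(outer(seq_len(L), seq_len(L),
                         function(i, j) j > i + 1L & !(i == 1L & j == L)),
                   arr.ind = TRUE)
      pair_i <- c(pair_i, off + loc[, 1L])
      pair_j <- c(pair_j, off + loc[, 2L])
    }
    off <- off + L
  }
  sheet$agg$xpair_i <- pair_i
  sheet$agg$xpair_j <- pair_j
  sheet
}

# Cells whose ring currently self-intersects (proper segment crossings among
# non-adjacent ring segments), vectorised over the whole sheet.
cells_self_intersecting <- function(sheet) {
  i <- sheet$agg$xpair_i
  if (!length(i)) return(integer())
  j <- sheet$agg$xpair_j
  cv <- sheet$cv
  p <- sheet$pos
  px <- p[cv$v[i], 1L]; py <- p[cv$v[i], 2L]
  rx <- p[cv$vn[i], 1L] - px; ry <- p[cv$vn[i], 2L] - py
  qx <- p[cv$v[j], 1L]; qy <- p[cv$v[j], 2L]
  sx <- p[cv$vn[j], 1L] - qx; sy <- p[cv$vn[j], 2L] - qy
  den <- rx * sy - ry * sx
  dx <- qx - px; dy <- qy - py
  tt <- (dx * sy - dy * sx) / den
  uu <- (dx * ry - dy * rx) / den
  eps <- 1e-12
  hit <- abs(den) > 1e-14 & tt > eps & tt < 1 - eps & uu > eps & uu < 1 - eps
  hit[is.na(hit)] <- FALSE
  unique(cv$cell[i[hit]])
}

# Contiguous-run sums: ptr is a 0-based boundary vector c(0, run ends).
run_sums <- function(x, ptr) {
  cs <- c(0, cumsum(x))
  cs[ptr[-1L] + 1L] - cs[ptr[-length(ptr)] + 1L]
}

# Sum x (one value per cv slot) over each cell.
agg_cells <- function(x, sheet) {
  run_sums(x, sheet$agg$cell_ptr)
}

# Sum x (one value per cv slot) over each vertex; returns length-n_v vector.
agg_verts <- function(x, sheet) {
  out <- numeric(nrow(sheet$pos))
  out[sheet$agg$vids] <- run_sums(x[sheet$agg$vord], sheet$agg$vptr)
  out
}

# Sum x (one value per directed edge endpoint, ordered c(end1, end2)) per
# vertex; returns length-n_v vector.
agg_edge_ends <- function(x, sheet) {
  out <- numeric(nrow(sheet$pos))
  out[sheet$agg$eids] <- run_sums(x[sheet$agg$eord], sheet$agg$eptr)
  out
}

## Construction ----------------------------------------------------------------

# Build hexagonal cells for arbitrary (row, col) lattice positions with exact
# vertex sharing. Vertices live on the half-integer lattice
# (s/2 * X, sqrt(3)/2 * s * Y), which makes deduplication exact.
build_hex_cells <- function(ij, edge_length) {
  s <- edge_length
  i <- ij[, 1L]
  j <- ij[, 2L]
  cx <- 3L * (j - 1L)                      # in units of s/2
  cy <- 2L * (i - 1L) + (j - 1L) %% 2L     # in units of sqrt(3)/2 s
  ox <- c(2L, 1L, -1L, -2L, -1L, 1L)       # CCW, starting at angle 0
  oy <- c(0L, 1L, 1L, 0L, -1L, -1L)
  n_c <- nrow(ij)
  X <- rep(cx, each = 6L) + rep.int(ox, n_c)
  Y <- rep(cy, each = 6L) + rep.int(oy, n_c)
  key <- paste(X, Y)
  dup <- duplicated(key)
  vid <- match(key, key[!dup])
  pos <- cbind(x = X[!dup] * (s / 2), y = Y[!dup] * (sqrt(3) / 2 * s))
  cells <- split(vid, rep.int(seq_len(n_c), rep.int(6L, n_c)))
  names(cells) <- NULL
  list(pos = pos, cells = cells)
}

#' Build a hexagonal cell sheet
#'
#' Constructs `n_rows` x `n_cols` regular hexagons in brick-offset packing.
#' Rows run along the AP (x) axis; the midline row is `ceiling(n_rows/2)`.
#' Perimeter vertices are flagged fixed (the sheet boundary is clamped during
#' simulation). The outermost `margin_cols` columns on each side are flagged
#' as the non-contractile margin.
#'
#' @param n_rows,n_cols Sheet dimensions in cells (both >= 1).
#' @param edge_length Hexagon edge length; every cell starts at area
#'   `hex_area(edge_length)`.
#' @param margin_cols Number of non-contractile margin columns at each AP end
#'   (0 disables margins).
#' @param fix_boundary Flag perimeter vertices as fixed (default TRUE). Set
#'   FALSE for free-boundary relaxation experiments (e.g. an isolated cell).
#' @return A `vf_sheet`: vertices (`pos`, `fixed`), cell rings (`cells`),
#'   per-cell `row`/`col`/`margin`, the derived edge table and the midline row.
#' @export
build_hex_sheet <- function(n_rows, n_cols, edge_length = 1,
                            margin_cols = 2L, fix_boundary = TRUE) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("sheet size must be positive integers (n_rows >= 1, n_cols >= 1)")
  }
  if (!is.finite(edge_length) || edge_length <= 0) {
    stop("edge_length must be positive")
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  margin_cols <- as.integer(margin_cols)
  ij <- cbind(rep(seq_len(n_rows), times = n_cols),
              rep(seq_len(n_cols), each = n_rows))
  geo <- build_hex_cells(ij, edge_length)
  margin <- ij[, 2L] <= margin_cols | ij[, 2L] > n_cols - margin_cols
  sheet <- structure(list(
    pos = geo$pos,
    fixed = logical(nrow(geo$pos)),
    cells = geo$cells,
    cell_row = ij[, 1L],
    cell_col = ij[, 2L],
    cell_margin = margin,
    n_rows = n_rows,
    n_cols = n_cols,
    midline = as.integer(ceiling(n_rows / 2)),
    edge_length = edge_length
  ), class = "vf_sheet")
  sheet <- rebuild_topology(sheet)
  if (fix_boundary) {
    bnd <- is.na(sheet$edge_cells[, 2L])
    sheet$fixed[unique(as.vector(sheet$edges[bnd, ]))] <- TRUE
  }
  sheet
}

#' Build the reduced seven-cell rosette
#'
#' One central hexagon surrounded by six neighbours; the outer perimeter is
#' fixed while the six vertices of the central cell remain free. Used by the
#' reduced model of stagnation mechanics.
#'
#' @param edge_length Hexagon edge length.
#' @return A `vf_sheet` with 7 cells; the central cell is the one with
#'   `row == 2, col == 2` (see [rosette_center()]).
#' @export
build_hex_rosette <- function(edge_length = 1) {
  ij <- rbind(c(2L, 2L), c(1L, 2L), c(3L, 2L),
              c(2L, 1L), c(3L, 1L), c(2L, 3L), c(3L, 3L))
  geo <- build_hex_cells(ij, edge_length)
  sheet <- structure(list(
    pos = geo$pos,
    fixed = logical(nrow(geo$pos)),
    cells = geo$cells,
    cell_row = ij[, 1L],
    cell_col = ij[, 2L],
    cell_margin = logical(7L),
    n_rows = 3L,
    n_cols = 3L,
    midline = 2L,
    edge_length = edge_length
  ), class = "vf_sheet")
  sheet <- rebuild_topology(sheet)
  bnd <- is.na(sheet$edge_cells[, 2L])
  sheet$fixed[unique(as.vector(sheet$edges[bnd, ]))] <- TRUE
  sheet
}

#' Index of the central cell of a rosette
#' @param sheet A rosette from [build_hex_rosette()].
#' @return Integer cell index.
#' @export
rosette_center <- function(sheet) {
  which(sheet$cell_row == 2L & sheet$cell_col == 2L)
}

## Geometry --------------------------------------------------------------------

#' Signed polygon area (shoelace)
#'
#' @param ring Two-column matrix of vertex positions, counter-clockwise for a
#'   positive result.
#' @return Numeric area (positive for CCW simple polygons).
#' @export
polygon_area <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Area-weighted polygon centroid
#'
#' @param ring Two-column matrix of vertex positions (simple polygon).
#' @return Length-2 numeric vector `(x, y)`.
#' @export
polygon_centroid <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100 * max(1, sum(abs(ring)))) {
    stop("degenerate polygon: zero area")
  }
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Vectorised per-cell areas from the flat incidence.
cell_areas <- function(sheet) {
  p <- sheet$pos; cv <- sheet$cv
  x <- p[cv$v, 1L]; y <- p[cv$v, 2L]
  xn <- p[cv$vn, 1L]; yn <- p[cv$vn, 2L]
  agg_cells(x * yn - xn * y, sheet) / 2
}

# Vectorised per-cell area-weighted centroids (n_cells x 2).
cell_centroids <- function(sheet) {
  p <- sheet$pos; cv <- sheet$cv
  x <- p[cv$v, 1L]; y <- p[cv$v, 2L]
  xn <- p[cv$vn, 1L]; yn <- p[cv$vn, 2L]
  cr <- x * yn - xn * y
  a <- agg_cells(cr, sheet) / 2
  cx <- agg_cells((x + xn) * cr, sheet) / (6 * a)
  cy <- agg_cells((y + yn) * cr, sheet) / (6 * a)
  cbind(x = cx, y = cy)
}

# Current edge vectors and lengths.
edge_geometry <- function(sheet) {
  d <- sheet$pos[sheet$edges[, 2L], , drop = FALSE] -
       sheet$pos[sheet$edges[, 1L], , drop = FALSE]
  list(d = d, len = sqrt(d[, 1L]^2 + d[, 2L]^2))
}

#' Classify edges as transverse or vertical
#'
#' An edge is transverse when the acute angle between its direction and the AP
#' (x) axis is at most 45 degrees, vertical when it is larger; edges at exactly
#' 45 degrees are classed transverse. The class is recomputed from the current
#' geometry (edges rotate as cells constrict).
#'
#' @param sheet A `vf_sheet`.
#' @param edge Optional integer vector of edge indices (default: all edges).
#' @return Character vector, `"transverse"` or `"vertical"`.
#' @export
edge_orientation_class <- function(sheet, edge = NULL) {
  geo <- edge_geometry(sheet)
  d <- geo$d
  if (!is.null(edge)) d <- d[edge, , drop = FALSE]
  adx <- abs(d[, 1L]); ady <- abs(d[, 2L])
  if (any(adx == 0 & ady == 0)) stop("zero-length edge has no orientation")
  unname(ifelse(ady <= adx, "transverse", "vertical"))
}

## Validation ------------------------------------------------------------------

# TRUE if the closed polygon given by `ring` (positions) self-intersects.
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4L) return(FALSE)
  seg_a <- ring
  seg_b <- ring[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    for (j in js) {
      p <- seg_a[i, ]; r <- seg_b[i, ] - p
      q <- seg_a[j, ]; s <- seg_b[j, ] - q
      den <- r[1L] * s[2L] - r[2L] * s[1L]
      if (abs(den) < 1e-14) next
      t <- ((q[1L] - p[1L]) * s[2L] - (q[2L] - p[2L]) * s[1L]) / den
      u <- ((q[1L] - p[1L]) * r[2L] - (q[2L] - p[2L]) * r[1L]) / den
      if (t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Check all sheet invariants
#'
#' Verifies ring sanity (>= 3 distinct vertices, positive signed area, simple
#' polygon), edge/cell incidence consistency, the planar Euler relation
#' V - E + F = 1 (outer face excluded), degree 3 of interior vertices, finite
#' positions, and that the traversed outer boundary polygon has the same area
#' as the summed cell areas (no gaps or overlaps).
#'
#' @param sheet A `vf_sheet`.
#' @return Character vector of violation messages; empty when the sheet is
#'   valid. Violations are data, not errors.
#' @export
validate_topology <- function(sheet) {
  bad <- character()
  if (!all(is.finite(sheet$pos))) bad <- c(bad, "non-finite vertex position")
  ring_len <- lengths(sheet$cells)
  if (any(ring_len < 3L)) bad <- c(bad, "cell ring with fewer than 3 vertices")
  if (any(vapply(sheet$cells, anyDuplicated, 0L) > 0L)) {
    bad <- c(bad, "cell ring with repeated vertex")
  }
  # re-derive incidence from the rings so edits to `cells` are reflected
  fresh <- tryCatch(rebuild_topology(sheet), error = function(e) NULL)
  if (is.null(fresh)) {
    bad <- c(bad, "incidence tables inconsistent with rings")
    return(bad)
  }
  areas <- tryCatch(cell_areas(fresh), error = function(e) NULL)
  if (is.null(areas)) {
    bad <- c(bad, "incidence tables inconsistent with rings")
    return(bad)
  }
  neg <- which(areas <= 0)
  if (length(neg)) {
    bad <- c(bad, paste0("non-positive signed area (CW ring?) in cell ",
                         paste(neg, collapse = ", ")))
  }
  for (ci in seq_along(sheet$cells)) {
    if (ring_self_intersects(sheet$pos[sheet$cells[[ci]], , drop = FALSE])) {
      bad <- c(bad, paste0("self-intersecting ring in cell ", ci))
    }
  }
  chk <- fresh
  used <- sort(unique(unlist(sheet$cells, use.names = FALSE)))
  v_n <- length(used)
  e_n <- nrow(chk$edges)
  f_n <- length(chk$cells)
  if (v_n - e_n + f_n != 1L) {
    bad <- c(bad, sprintf("Euler relation violated: V-E+F = %d", v_n - e_n + f_n))
  }
  deg <- tabulate(as.vector(chk$edges), nbins = nrow(sheet$pos))
  bnd_e <- is.na(chk$edge_cells[, 2L])
  bnd_v <- unique(as.vector(chk$edges[bnd_e, , drop = FALSE]))
  interior <- setdiff(used, bnd_v)
  if (length(interior) && any(deg[interior] != 3L)) {
    bad <- c(bad, "interior vertex with degree != 3")
  }
  # outer boundary traversal: boundary edges, directed as in their cell ring
  if (length(bad) == 0L && any(bnd_e)) {
    cv <- chk$cv
    on_bnd <- bnd_e[cv$edge] & !duplicated(cv$edge)
    from <- cv$v[on_bnd]; to <- cv$vn[on_bnd]
    if (anyDuplicated(from) == 0L && setequal(from, to)) {
      path <- integer(length(from))
      cur <- from[1L]
      ok <- TRUE
      for (k in seq_along(path)) {
        path[k] <- cur
        cur <- to[match(cur, from)]
        if (is.na(cur)) { ok <- FALSE; break }
      }
      if (ok && cur == path[1L] && length(unique(path)) == length(path)) {
        outer_a <- abs(polygon_area(sheet$pos[path, , drop = FALSE]))
        if (abs(outer_a - sum(areas)) > 1e-9 * max(outer_a, 1)) {
          bad <- c(bad, "cell areas do not tile the outer boundary polygon")
        }
      } else {
        bad <- c(bad, "outer boundary is not a single closed cycle")
      }
    } else {
      bad <- c(bad, "outer boundary is not a single closed cycle")
    }
  }
  bad
}

## Serialization ---------------------------------------------------------------

#' Serialize a sheet to JSON
#'
#' Documented schema: `vertices` (x, y, fixed), `cells` (ring of 1-based
#' vertex ids, row, col, margin), `meta` (n_rows, n_cols, midline,
#' edge_length). Round-trips losslessly through [sheet_from_json()].
#'
#' @param sheet A `vf_sheet`.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
sheet_to_json <- function(sheet, path = NULL) {
  obj <- list(
    vertices = list(x = sheet$pos[, 1L], y = sheet$pos[, 2L],
                    fixed = sheet$fixed),
    cells = list(ring = sheet$cells, row = sheet$cell_row,
                 col = sheet$cell_col, margin = sheet$cell_margin),
    meta = list(n_rows = sheet$n_rows, n_cols = sheet$n_cols,
                midline = sheet$midline, edge_length = sheet$edge_length)
  )
  txt <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Deserialize a sheet from JSON
#' @param x A file path or JSON string produced by [sheet_to_json()].
#' @return A `vf_sheet`.
#' @export
sheet_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  sheet <- structure(list(
    pos = cbind(x = as.numeric(obj$vertices$x), y = as.numeric(obj$vertices$y)),
    fixed = as.logical(obj$vertices$fixed),
    cells = lapply(obj$cells$ring, as.integer),
    cell_row = as.integer(obj$cells$row),
    cell_col = as.integer(obj$cells$col),
    cell_margin = as.logical(obj$cells$margin),
    n_rows = as.integer(obj$meta$n_rows),
    n_cols = as.integer(obj$meta$n_cols),
    midline = as.integer(obj$meta$midline),
    edge_length = as.numeric(obj$meta$edge_length)
  ), class = "vf_sheet")
  rebuild_topology(sheet)
}

#' @export
print.vf_sheet <- function(x, ...) {
  cat(sprintf(
    "<vf_sheet> %d x %d cells (%d total), %d vertices (%d fixed), %d edges\n",
    x$n_rows, x$n_cols, length(x$cells), nrow(x$pos), sum(x$fixed),
    nrow(x$edges)))
  cat(sprintf("  midline row %d; margin cells: %d; edge length %g\n",
              x$midline, sum(x$cell_margin), x$edge_length))
  invisible(x)
}
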