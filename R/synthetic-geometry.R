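#' Parametric synthetic cell geometry
#'
#' Describes a cell as nested circular/elliptical outlines: the cell boundary,
#' a nucleus strictly inside it, optional aggregate discs strictly inside the
#' cytoplasm and a bleach disc strictly inside the nucleus. Stands in for a
#' segmented cell geometry when no real image is available.
#'
#' @param cell,nucleus,bleach outlines created by [disc()] or [ellipse()].
#' @param aggregates list of outlines (may be empty).
#' @param h target mesh edge length (um).
#' @param h_nucleus target edge length inside the nucleus (um); defaults to
#'   `h`. A finer nuclear mesh resolves the bleach disc and the steep
#'   intensity gradients around it.
#' @return object of class `cell_geometry_spec`.
#' @export
cell_geometry_spec <- function(cell, nucleus, aggregates = list(), bleach = NULL,
                               h = 1, h_nucleus = h) {
  spec <- structure(list(cell = cell, nucleus = nucleus,
                         aggregates = aggregates, bleach = bleach, h = h,
                         h_nucleus = h_nucleus),
                    class = "cell_geometry_spec")
  validate_geometry_spec(spec)
  spec
}

#' Circular and elliptical outlines
#'
#' @param cx,cy center (um).
#' @param r radius (um) for a disc; `a`,`b` semi-axes for an ellipse.
#' @return outline object used by [cell_geometry_spec()].
#' @export
disc <- function(cx, cy, r) {
  stopifnot(r > 0)
  structure(list(cx = cx, cy = cy, a = r, b = r), class = "flip_outline")
}

#' @rdname disc
#' @param a,b semi-axis lengths (um).
#' @export
ellipse <- function(cx, cy, a, b) {
  stopifnot(a > 0, b > 0)
  structure(list(cx = cx, cy = cy, a = a, b = b), class = "flip_outline")
}

# signed "radial" distance-like measure: < 0 inside, approx physical distance
outline_dist <- function(o, x, y) {
  u <- (x - o$cx) / o$a; v <- (y - o$cy) / o$b
  (sqrt(u^2 + v^2) - 1) * min(o$a, o$b)
}

outline_inside <- function(o, x, y) outline_dist(o, x, y) < 0

outline_ring <- function(o, spacing) {
  perim <- pi * (3 * (o$a + o$b) - sqrt((3 * o$a + o$b) * (o$a + 3 * o$b)))
  n <- max(12L, ceiling(perim / spacing))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(o$cx + o$a * cos(th), o$cy + o$b * sin(th))
}

validate_geometry_spec <- function(spec) {
  inside_strict <- function(inner, outer, margin) {
    ring <- outline_ring(inner, min(inner$a, inner$b) / 8)
    all(outline_dist(outer, ring[, 1], ring[, 2]) < -margin)
  }
  m <- 0.25 * spec$h
  if (!inside_strict(spec$nucleus, spec$cell, m))
    stop("invalid geometry spec: nucleus not strictly inside the cell")
  for (ag in spec$aggregates) {
    if (!inside_strict(ag, spec$cell, m))
      stop("invalid geometry spec: aggregate not strictly inside the cell")
    ring <- outline_ring(ag, min(ag$a, ag$b) / 8)
    if (any(outline_dist(spec$nucleus, ring[, 1], ring[, 2]) < m))
      stop("invalid geometry spec: aggregate overlaps the nucleus")
  }
  if (length(spec$aggregates) > 1) {
    for (i in seq_along(spec$aggregates)) for (j in seq_len(i - 1L)) {
      ri <- outline_ring(spec$aggregates[[i]], min(spec$aggregates[[i]]$a, spec$aggregates[[i]]$b) / 8)
      if (any(outline_dist(spec$aggregates[[j]], ri[, 1], ri[, 2]) < m))
        stop("invalid geometry spec: aggregates overlap")
    }
  }
  if (!is.null(spec$bleach) && !inside_strict(spec$bleach, spec$nucleus, 0))
    stop("invalid geometry spec: bleach disc not strictly inside the nucleus")
  invisible(spec)
}

#' Mesh a synthetic cell geometry
#'
#' Places boundary points on every region outline and a hexagonal lattice of
#' interior points kept clear of the outlines, Delaunay-triangulates the point
#' set, and labels triangles by the compartment containing their centroid.
#' Because the interior lattice keeps a clearance band around every outline,
#' the triangulation conforms to the outlines: every chord between consecutive
#' ring points is a mesh edge, so membrane and aggregate interfaces coincide
#' with mesh edges (verified, with a meshing error raised on failure). The
#' bleach disc is not meshed conformingly; nucleus triangles whose centroid
#' falls inside it are flagged.
#'
#' @param spec a [cell_geometry_spec()].
#' @return a [flip_mesh()].
#' @export
build_synthetic_cell <- function(spec) {
  validate_geometry_spec(spec)
  h <- spec$h
  hn <- spec$h_nucleus %||% h
  rings <- c(list(cell = spec$cell, nucleus = spec$nucleus), spec$aggregates)
  base_h <- c(h, hn, rep(h, length(spec$aggregates)))
  ring_spacing <- mapply(function(o, hb) {
    perim <- pi * (3 * (o$a + o$b) - sqrt((3 * o$a + o$b) * (o$a + 3 * o$b)))
    min(hb, perim / 12)
  }, rings, base_h)
  ring_pts <- mapply(function(o, s) outline_ring(o, s), rings, ring_spacing,
                     SIMPLIFY = FALSE)

  hex_lattice <- function(bb, hh) {
    dy <- hh * sqrt(3) / 2
    ys <- seq(bb[3] + hh / 2, bb[4], by = dy)
    do.call(rbind, lapply(seq_along(ys), function(k) {
      xs <- seq(bb[1] + hh / 2 + (k %% 2) * hh / 2, bb[2], by = hh)
      cbind(xs, ys[k])
    }))
  }
  bb <- c(spec$cell$cx - spec$cell$a, spec$cell$cx + spec$cell$a,
          spec$cell$cy - spec$cell$b, spec$cell$cy + spec$cell$b)
  # coarse lattice outside the nucleus, fine lattice inside it
  grid <- hex_lattice(bb, h)
  nd <- outline_dist(spec$nucleus, grid[, 1], grid[, 2])
  keep <- outline_dist(spec$cell, grid[, 1], grid[, 2]) < -0.6 * ring_spacing[1] &
    (if (hn < h) nd > 0.6 * ring_spacing[2] else abs(nd) > 0.6 * ring_spacing[2])
  for (k in seq_along(rings)[-(1:2)]) {
    keep <- keep & abs(outline_dist(rings[[k]], grid[, 1], grid[, 2])) >
      0.6 * ring_spacing[k]
  }
  pts <- grid[keep, , drop = FALSE]
  if (hn < h) {
    nb <- c(spec$nucleus$cx - spec$nucleus$a, spec$nucleus$cx + spec$nucleus$a,
            spec$nucleus$cy - spec$nucleus$b, spec$nucleus$cy + spec$nucleus$b)
    fine <- hex_lattice(nb, hn)
    keepf <- outline_dist(spec$nucleus, fine[, 1], fine[, 2]) < -0.6 * ring_spacing[2]
    pts <- rbind(pts, fine[keepf, , drop = FALSE])
  }
  pts <- rbind(do.call(rbind, ring_pts), pts)

  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  tris <- t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))

  # drop slivers outside the (convex) cell outline
  cen <- (pts[tris[, 1], , drop = FALSE] + pts[tris[, 2], , drop = FALSE] +
            pts[tris[, 3], , drop = FALSE]) / 3
  inside <- outline_dist(spec$cell, cen[, 1], cen[, 2]) < 0
  tris <- tris[inside, , drop = FALSE]
  cen <- cen[inside, , drop = FALSE]

  # verify outline conformity: each ring chord must be a triangulation edge
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_edges <- unique(c(edge_key(tris[, 1], tris[, 2]),
                        edge_key(tris[, 2], tris[, 3]),
                        edge_key(tris[, 3], tris[, 1])))
  offset <- 0L
  for (k in seq_along(ring_pts)) {
    n <- nrow(ring_pts[[k]])
    idx <- offset + seq_len(n)
    chords <- edge_key(idx, c(idx[-1], idx[1]))
    if (!all(chords %in% all_edges))
      stop("meshing error: region outline not resolved as mesh edges; ",
           "reduce the target edge length h")
    offset <- offset + n
  }

  compartment <- rep("cytoplasm", nrow(tris))
  aggregate_id <- rep(NA_integer_, nrow(tris))
  compartment[outline_inside(spec$nucleus, cen[, 1], cen[, 2])] <- "nucleus"
  for (i in seq_along(spec$aggregates)) {
    sel <- outline_inside(spec$aggregates[[i]], cen[, 1], cen[, 2])
    compartment[sel] <- "aggregate"
    aggregate_id[sel] <- i
  }
  bleach <- rep(FALSE, nrow(tris))
  if (!is.null(spec$bleach))
    bleach <- compartment == "nucleus" &
      outline_inside(spec$bleach, cen[, 1], cen[, 2])

  flip_mesh(pts, tris, compartment, aggregate_id, bleach)
}

#' Default synthetic cell used by the recovery experiment
#'
#' A 30-um-diameter cell (the scale of an adherent CHO cell) with an
#' off-center 5-um-radius nucleus, three cytoplasmic aggregate discs (radius
#' 2 um) and a 1.2-um-radius bleach disc inside the nucleus. The nuclear
#' region is meshed finer than the cytoplasm so the bleach disc and the
#' steep gradients around it are resolved; at the default edge lengths the
#' mesh has roughly 400-500 triangles.
#'
#' @param h target edge length in the cytoplasm (um).
#' @param h_nucleus target edge length in the nucleus (um).
#' @return a [cell_geometry_spec()].
#' @export
default_cell_spec <- function(h = 2.4, h_nucleus = 1.05) {
  cell_geometry_spec(
    cell = disc(0, 0, 15),
    nucleus = disc(-6, 0, 5),
    aggregates = list(disc(6, 6, 2), disc(8, -3, 2), disc(0, -9, 2)),
    bleach = disc(-6, 0, 1.2),
    h = h, h_nucleus = h_nucleus)
}
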