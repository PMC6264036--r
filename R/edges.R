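#' Classify the mesh edges into boundary, interior and interface sets
#'
#' Builds the edge table of a conforming mesh and assigns each edge to exactly
#' one of the four disjoint sets: the outer cell boundary, interior edges
#' within a compartment, nuclear-membrane edges (cytoplasm|nucleus) and
#' aggregate-boundary edges (cytoplasm|aggregate). For interface edges the
#' minus side is always the cytoplasm triangle, so the indicator "minus side
#' is cytoplasmic" is TRUE by construction and the stored unit normal points
#' from cytoplasm into the enclosed region. Nucleus-aggregate adjacency is
#' rejected: the exchange model defines aggregates only against cytoplasm.
#'
#' @param mesh a [flip_mesh()].
#' @return object of class `flip_edges`: a data frame with one row per edge
#'   and columns `v1`, `v2` (vertex ids), `length` (um), `class` (one of
#'   `"boundary"`, `"interior"`, `"membrane"`, `"aggregate"`), `tri_minus`,
#'   `tri_plus` (triangle ids; `tri_plus` is `NA` on the boundary), `nx`, `ny`
#'   (unit normal of the minus side) and `aggregate_id` (for aggregate edges).
#' @export
classify_edges <- function(mesh) {
  tr <- mesh$triangles
  nt <- nrow(tr)
  # all directed edges with their triangle of origin
  ev1 <- c(tr[, 1], tr[, 2], tr[, 3])
  ev2 <- c(tr[, 2], tr[, 3], tr[, 1])
  tri <- rep(seq_len(nt), 3L)
  a <- pmin(ev1, ev2); b <- pmax(ev1, ev2)
  key <- paste(a, b)
  grp <- split(seq_along(key), key)
  counts <- lengths(grp)
  if (any(counts > 2L))
    stop("non-conforming mesh: an edge is shared by more than two triangles")

  n_e <- length(grp)
  v1 <- integer(n_e); v2 <- integer(n_e)
  tmin <- integer(n_e); tplus <- rep(NA_integer_, n_e)
  cls <- character(n_e); agg <- rep(NA_integer_, n_e)

  comp <- mesh$compartment; aid <- mesh$aggregate_id
  for (i in seq_len(n_e)) {
    idx <- grp[[i]]
    t1 <- tri[idx[1]]
    v1[i] <- ev1[idx[1]]; v2[i] <- ev2[idx[1]]
    if (length(idx) == 1L) {
      cls[i] <- "boundary"; tmin[i] <- t1
    } else {
      t2 <- tri[idx[2]]
      c1 <- comp[t1]; c2 <- comp[t2]
      if (c1 == c2) {
        if (c1 == "aggregate" && aid[t1] != aid[t2])
          stop("invalid mesh: two different aggregates share an edge")
        cls[i] <- "interior"; tmin[i] <- min(t1, t2); tplus[i] <- max(t1, t2)
      } else if (("cytoplasm" %in% c(c1, c2)) && ("nucleus" %in% c(c1, c2))) {
        cls[i] <- "membrane"
        tmin[i] <- if (c1 == "cytoplasm") t1 else t2
        tplus[i] <- if (c1 == "cytoplasm") t2 else t1
      } else if (("cytoplasm" %in% c(c1, c2)) && ("aggregate" %in% c(c1, c2))) {
        cls[i] <- "aggregate"
        tmin[i] <- if (c1 == "cytoplasm") t1 else t2
        tplus[i] <- if (c1 == "cytoplasm") t2 else t1
        agg[i] <- aid[if (c1 == "aggregate") t1 else t2]
      } else {
        stop("invalid mesh: aggregate touching the nucleus is not supported")
      }
    }
  }

  p1 <- mesh$vertices[v1, , drop = FALSE]
  p2 <- mesh$vertices[v2, , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  len <- sqrt(ex^2 + ey^2)
  nx <- ey / len; ny <- -ex / len
  # orient the normal outward from the minus triangle
  cen <- triangle_centroids(mesh)
  mid <- (p1 + p2) / 2
  dotc <- (mid[, 1] - cen[tmin, 1]) * nx + (mid[, 2] - cen[tmin, 2]) * ny
  sgn <- ifelse(dotc >= 0, 1, -1)
  nx <- nx * sgn; ny <- ny * sgn

  out <- data.frame(v1 = v1, v2 = v2, length = len, class = cls,
                    tri_minus = tmin, tri_plus = tplus,
                    nx = nx, ny = ny, aggregate_id = agg,
                    stringsAsFactors = FALSE)
  class(out) <- c("flip_edges", "data.frame")
  out
}

#' Interface perimeters
#'
#' Total length of the nuclear membrane and of each aggregate boundary.
#'
#' @param edges a [classify_edges()] result.
#' @return list with `membrane` (um) and `aggregate` (named numeric by id).
#' @export
interface_perimeters <- function(edges) {
  mem <- sum(edges$length[edges$class == "membrane"])
  ae <- edges[edges$class == "aggregate", ]
  list(membrane = mem,
       aggregate = vapply(split(ae$length, ae$aggregate_id), sum, numeric(1)))
}
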