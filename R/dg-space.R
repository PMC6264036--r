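#' Piecewise-linear discontinuous Galerkin space
#'
#' Three nodal P1 degrees of freedom per triangle, discontinuous across all
#' edges. Dof `3*(t-1)+k` is the nodal value of triangle `t` at its `k`-th
#' vertex. Precomputes triangle areas and the (constant) gradients of the
#' local basis functions; all element integrals of products of P1 functions
#' are evaluated exactly from closed-form formulas.
#'
#' @param mesh a [flip_mesh()].
#' @return object of class `dg_space` with `mesh`, `ndof`, `area` (per
#'   triangle), `grad` (list of 3x2 gradient matrices) and `dof_xy`
#'   (coordinates of every dof's vertex).
#' @export
dg_space <- function(mesh) {
  tr <- mesh$triangles
  nt <- nrow(tr)
  area <- triangle_areas(mesh)
  if (any(area <= 0)) stop("degenerate triangle with zero area")
  grad <- vector("list", nt)
  for (t in seq_len(nt)) {
    p <- mesh$vertices[tr[t, ], , drop = FALSE]
    # grad phi_i = perp(p_j - p_k) / (2A), (i,j,k) cyclic
    g <- rbind(c(p[2, 2] - p[3, 2], p[3, 1] - p[2, 1]),
               c(p[3, 2] - p[1, 2], p[1, 1] - p[3, 1]),
               c(p[1, 2] - p[2, 2], p[2, 1] - p[1, 1])) / (2 * area[t])
    grad[[t]] <- g
  }
  dof_xy <- mesh$vertices[as.vector(t(tr)), , drop = FALSE]
  structure(list(mesh = mesh, ndof = 3L * nt, area = area, grad = grad,
                 dof_xy = dof_xy),
            class = "dg_space")
}

#' Dof indices of a triangle
#' @param t triangle index (vectorized).
#' @return integer vector of the 3 dof indices (columns if `t` is a vector).
#' @keywords internal
tri_dofs <- function(t) rbind(3L * (t - 1L) + 1L, 3L * (t - 1L) + 2L, 3L * (t - 1L) + 3L)

#' Evaluate a scalar function on the dof nodes
#'
#' @param space a [dg_space()].
#' @param f function of (x, y), vectorized.
#' @return numeric DG coefficient vector of length `space$ndof`.
#' @export
dg_interpolate <- function(space, f) {
  f(space$dof_xy[, 1], space$dof_xy[, 2])
}

#' Integrate a DG field over the mesh (or a subset of triangles)
#'
#' @param space a [dg_space()].
#' @param u DG coefficient vector.
#' @param triangles optional triangle subset.
#' @return the exact integral of the piecewise-linear field.
#' @export
dg_integral <- function(space, u, triangles = NULL) {
  nt <- length(space$area)
  ts <- if (is.null(triangles)) seq_len(nt) else triangles
  s <- 0
  for (t in ts) s <- s + space$area[t] * mean(u[3L * (t - 1L) + 1:3])
  s
}

#' Area-weighted mean of a DG field over a compartment
#'
#' @param space a [dg_space()].
#' @param u DG coefficient vector.
#' @param compartment `"cytoplasm"`, `"nucleus"` or `"aggregate"`.
#' @param aggregate_id optional id restricting to one aggregate.
#' @return scalar mean intensity.
#' @export
dg_region_mean <- function(space, u, compartment, aggregate_id = NULL) {
  sel <- space$mesh$compartment == compartment
  if (!is.null(aggregate_id))
    sel <- sel & !is.na(space$mesh$aggregate_id) &
      space$mesh$aggregate_id == aggregate_id
  ts <- which(sel)
  if (!length(ts)) stop("empty region: ", compartment)
  dg_integral(space, u, ts) / sum(space$area[ts])
}
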