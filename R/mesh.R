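#' Region-labeled triangle meshes
#'
#' A `flip_mesh` stores a conforming 2-D triangle mesh in physical coordinates
#' (micrometers) together with a compartment label per triangle
#' (`"cytoplasm"`, `"nucleus"` or `"aggregate"`, the latter with a positive
#' `aggregate_id`) and a logical `bleach` flag marking the triangles of the
#' bleached disc inside the nucleus.
#'
#' @param vertices numeric matrix, one row per vertex, columns x and y (um).
#' @param triangles integer matrix, one row per triangle, three vertex indices.
#' @param compartment character vector, one of `"cytoplasm"`, `"nucleus"`,
#'   `"aggregate"` per triangle.
#' @param aggregate_id integer vector, `NA` except for aggregate triangles
#'   where it is the aggregate id (>= 1).
#' @param bleach logical vector, `TRUE` on bleached (nucleus) triangles.
#' @param pixel_size optional scalar, um per pixel for image-derived meshes.
#'
#' @return An object of class `flip_mesh` with elements `vertices`,
#'   `triangles`, `compartment`, `aggregate_id`, `bleach`, `pixel_size`.
#'   Triangles are re-oriented counter-clockwise (positive signed area).
#' @export
flip_mesh <- function(vertices, triangles, compartment,
                      aggregate_id = NULL, bleach = NULL, pixel_size = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  nt <- nrow(triangles)
  if (ncol(vertices) != 2L) stop("vertices must have two columns (x, y)")
  if (ncol(triangles) != 3L) stop("triangles must have three columns")
  if (length(compartment) != nt) stop("one compartment label per triangle required")
  if (!all(compartment %in% c("cytoplasm", "nucleus", "aggregate")))
    stop("unknown compartment label")
  if (is.null(aggregate_id)) aggregate_id <- rep(NA_integer_, nt)
  if (is.null(bleach)) bleach <- rep(FALSE, nt)
  aggregate_id <- as.integer(aggregate_id)
  if (any(compartment == "aggregate" & (is.na(aggregate_id) | aggregate_id < 1L)))
    stop("aggregate triangles need aggregate_id >= 1")
  if (any(compartment != "aggregate" & !is.na(aggregate_id)))
    stop("aggregate_id must be NA outside aggregates")
  if (any(bleach & compartment != "nucleus"))
    stop("bleach_flag is only allowed on nucleus triangles")

  # orient counter-clockwise
  a <- signed_areas(vertices, triangles)
  flip <- which(a < 0)
  if (length(flip)) triangles[flip, 2:3] <- triangles[flip, 3:2]
  if (any(abs(signed_areas(vertices, triangles)) < 1e-14))
    stop("degenerate triangle with (near-)zero area")

  structure(
    list(vertices = vertices, triangles = triangles,
         compartment = compartment, aggregate_id = aggregate_id,
         bleach = as.logical(bleach), pixel_size = pixel_size),
    class = "flip_mesh")
}

signed_areas <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
           (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Triangle areas and centroids
#'
#' @param mesh a [flip_mesh()].
#' @return `triangle_areas`: numeric vector of (positive) areas in um^2.
#' @export
triangle_areas <- function(mesh) {
  abs(signed_areas(mesh$vertices, mesh$triangles))
}

#' @rdname triangle_areas
#' @return `triangle_centroids`: matrix of centroid coordinates.
#' @export
triangle_centroids <- function(mesh) {
  (mesh$vertices[mesh$triangles[, 1], , drop = FALSE] +
     mesh$vertices[mesh$triangles[, 2], , drop = FALSE] +
     mesh$vertices[mesh$triangles[, 3], , drop = FALSE]) / 3
}

#' Areas of the labeled regions
#'
#' Sums triangle areas per compartment (aggregates individually).
#'
#' @param mesh a [flip_mesh()].
#' @return named list: `cytoplasm`, `nucleus`, `aggregate` (named by id),
#'   `bleach`, `total` (um^2).
#' @export
region_areas <- function(mesh) {
  a <- triangle_areas(mesh)
  agg <- split(a[mesh$compartment == "aggregate"],
               mesh$aggregate_id[mesh$compartment == "aggregate"])
  list(cytoplasm = sum(a[mesh$compartment == "cytoplasm"]),
       nucleus = sum(a[mesh$compartment == "nucleus"]),
       aggregate = vapply(agg, sum, numeric(1)),
       bleach = sum(a[mesh$bleach]),
       total = sum(a))
}

#' @export
print.flip_mesh <- function(x, ...) {
  ra <- region_areas(x)
  cat("flip_mesh:", nrow(x$vertices), "vertices,", nrow(x$triangles), "triangles\n")
  cat(sprintf("  cytoplasm %.1f um^2, nucleus %.1f um^2, %d aggregate(s), bleach %.2f um^2\n",
              ra$cytoplasm, ra$nucleus, length(ra$aggregate), ra$bleach))
  invisible(x)
}

#' Convert a pixel count to physical length
#'
#' @param n_pixels number of pixels (>= 0).
#' @param pixel_size pixel size in um/pixel (> 0).
#' @return length in um, `n_pixels * pixel_size`.
#' @examples
#' pixel_to_physical(25, 0.0461847)  # bleach-spot width ~1.15 um
#' @export
pixel_to_physical <- function(n_pixels, pixel_size) {
  if (any(n_pixels < 0)) stop("n_pixels must be >= 0")
  if (any(pixel_size <= 0)) stop("pixel_size must be > 0")
  n_pixels * pixel_size
}

#' Structured triangle mesh of the unit square
#'
#' Test fixture: an n-by-n grid of squares, each split into two triangles,
#' labeled as a single cytoplasm region. Used by the heat-equation
#' convergence checks.
#'
#' @param n grid subdivisions per side.
#' @param width physical side length (default 1).
#' @return a [flip_mesh()].
#' @export
unit_square_mesh <- function(n, width = 1) {
  s <- seq(0, width, length.out = n + 1L)
  g <- expand.grid(x = s, y = s)
  vid <- function(i, j) (j - 1L) * (n + 1L) + i   # i = column (x), j = row (y)
  tris <- matrix(0L, 2L * n * n, 3L)
  k <- 0L
  for (j in seq_len(n)) for (i in seq_len(n)) {
    v00 <- vid(i, j); v10 <- vid(i + 1L, j); v01 <- vid(i, j + 1L); v11 <- vid(i + 1L, j + 1L)
    tris[k + 1L, ] <- c(v00, v10, v11)
    tris[k + 2L, ] <- c(v00, v11, v01)
    k <- k + 2L
  }
  flip_mesh(as.matrix(g), tris, rep("cytoplasm", nrow(tris)))
}

#' Two-triangle fixture mesh
#'
#' The unit square (scaled by `width`/`height`) split along its diagonal into
#' two triangles with user-chosen compartments; the shared edge is then a
#' one-edge interface. Used by the interface-exchange oracle tests.
#'
#' @param compartments length-2 character vector of labels for the two
#'   triangles (first: lower-right triangle, second: upper-left).
#' @param width,height rectangle dimensions (um).
#' @param aggregate_id id used for any `"aggregate"` entry.
#' @return a [flip_mesh()].
#' @export
two_triangle_mesh <- function(compartments = c("cytoplasm", "aggregate"),
                              width = 1, height = 1, aggregate_id = 1L) {
  v <- matrix(c(0, 0, width, 0, width, height, 0, height), ncol = 2, byrow = TRUE)
  tr <- matrix(c(1L, 2L, 3L, 1L, 3L, 4L), ncol = 3, byrow = TRUE)
  ids <- ifelse(compartments == "aggregate", aggregate_id, NA_integer_)
  flip_mesh(v, tr, compartments, aggregate_id = ids)
}
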