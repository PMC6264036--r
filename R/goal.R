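#' Load and denoise a FLIP image stack
#'
#' Reads a multi-frame TIFF, applies a Gaussian blur (default sigma 1 pixel)
#' to every frame, and attaches the acquisition metadata. Frames are stored as
#' matrices in image orientation (row 1 = top of the image).
#'
#' @param path path to a multi-frame TIFF (uint8/uint16/float32).
#' @param pixel_size um per pixel.
#' @param dt_frame frame interval (s).
#' @param blur_radius Gaussian blur sigma in pixels (0 disables denoising).
#' @return object of class `flip_stack`: list with `frames` (list of
#'   matrices), `pixel_size`, `dt_frame`.
#' @export
load_flip_stack <- function(path, pixel_size, dt_frame, blur_radius = 1) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]
    f
  })
  shp <- vapply(frames, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("inconsistent frame shapes in stack")
  if (blur_radius > 0) frames <- lapply(frames, blur_frame, sigma = blur_radius)
  structure(list(frames = frames, pixel_size = pixel_size, dt_frame = dt_frame),
            class = "flip_stack")
}

#' Gaussian blur of one frame
#'
#' @param frame numeric matrix.
#' @param sigma blur sigma in pixels.
#' @return blurred matrix of the same shape.
#' @export
blur_frame <- function(frame, sigma = 1) {
  as.matrix(EBImage::gblur(frame, sigma = sigma))
}

# physical (um) -> fractional pixel indices (row, col) for pixel-center
# sampling; image row 1 is the top, physical y grows upward
phys_to_pixel <- function(x, y, nrow_img, pixel_size) {
  col <- x / pixel_size + 0.5
  row <- nrow_img - y / pixel_size + 0.5
  cbind(row, col)
}

#' Project an image frame onto the DG space
#'
#' Every P1 dof takes the bilinearly interpolated image value at its vertex
#' location, per triangle, so the result is discontinuous across edges
#' exactly like the simulation space. Physical coordinates have the origin at
#' the lower-left image corner with y increasing upward.
#'
#' @param frame image matrix (row 1 = top).
#' @param space a [dg_space()].
#' @param pixel_size um per pixel.
#' @param origin physical coordinates of the lower-left image corner
#'   (default the physical origin).
#' @return DG coefficient vector of length `3 * n_triangles`.
#' @export
project_frame_to_dg <- function(frame, space, pixel_size, origin = c(0, 0)) {
  rc <- phys_to_pixel(space$dof_xy[, 1] - origin[1],
                      space$dof_xy[, 2] - origin[2], nrow(frame), pixel_size)
  r <- rc[, 1]; cl <- rc[, 2]
  # pixel centers sit half a pixel inside the image edge; vertices within
  # that half-pixel band are clamped, anything further out is an error
  if (any(r < 0.5 - 1e-9) || any(r > nrow(frame) + 0.5 + 1e-9) ||
      any(cl < 0.5 - 1e-9) || any(cl > ncol(frame) + 0.5 + 1e-9))
    stop("mesh vertex outside the image extent")
  # bilinear interpolation between pixel centers, extrapolating linearly in
  # the half-pixel band along the image border
  r0 <- pmin(pmax(floor(r), 1L), nrow(frame) - 1L)
  c0 <- pmin(pmax(floor(cl), 1L), ncol(frame) - 1L)
  fr <- r - r0; fc <- cl - c0
  idx <- function(i, j) frame[cbind(i, j)]
  (1 - fr) * (1 - fc) * idx(r0, c0) + (1 - fr) * fc * idx(r0, c0 + 1L) +
    fr * (1 - fc) * idx(r0 + 1L, c0) + fr * fc * idx(r0 + 1L, c0 + 1L)
}

#' Build a goal series from an image stack
#'
#' @param stack a [load_flip_stack()] result.
#' @param space a [dg_space()].
#' @param protocol a [bleach_protocol()] supplying the comparison times.
#' @return a [frame_series()] of goal fields `c_g(t_i)`.
#' @export
goal_series_from_stack <- function(stack, space, protocol) {
  n <- length(stack$frames)
  C <- vapply(stack$frames, project_frame_to_dg, numeric(space$ndof),
              space = space, pixel_size = stack$pixel_size)
  frame_series(frame_times(protocol)[seq_len(n)], C)
}

#' Misfit functional between simulation and goal series
#'
#' `E = (1/n) sum_i int_Omega (c_sim(t_i) - c_g(t_i))^2 dx`, evaluated exactly
#' with the DG mass matrix. Nonnegative, zero iff the series coincide, and
#' symmetric in its arguments.
#'
#' @param sim,goal [frame_series()] objects on the same space with equal
#'   lengths.
#' @param Mass the DG mass matrix ([assemble_mass()]).
#' @return scalar misfit E.
#' @export
misfit <- function(sim, goal, Mass) {
  if (ncol(sim$C) != ncol(goal$C) || nrow(sim$C) != nrow(goal$C))
    stop("simulation and goal series must have the same shape")
  n <- ncol(sim$C)
  E <- 0
  for (i in seq_len(n)) {
    d <- sim$C[, i] - goal$C[, i]
    E <- E + as.numeric(d %*% (Mass %*% d))
  }
  E / n
}

#' Rasterize a frame series to a multi-frame TIFF
#'
#' Samples every DG frame on a regular pixel grid (point-in-triangle lookup,
#' pixels outside the mesh get 0) and writes a float32 multi-frame TIFF plus a
#' YAML sidecar with the pixel size and protocol timing.
#'
#' @param series a [frame_series()].
#' @param space a [dg_space()].
#' @param path output TIFF path.
#' @param pixel_size um per pixel of the raster.
#' @param protocol optional [bleach_protocol()] stored in the sidecar.
#' @param normalize divide by the global max so values fit the TIFF float
#'   convention (recorded in the sidecar as `intensity_scale`).
#' @return invisibly, the sidecar path.
#' @export
write_frame_series_tiff <- function(series, space, path, pixel_size,
                                    protocol = NULL, normalize = TRUE) {
  ctx <- raster_context(space, pixel_size)
  scale <- if (normalize) max(abs(series$C)) else 1
  imgs <- lapply(seq_along(series$times), function(i)
    rasterize_frame(ctx, series$C[, i]) / scale)
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  sidecar <- paste0(path, ".yaml")
  meta <- list(pixel_size = pixel_size, intensity_scale = scale,
               origin = as.numeric(ctx$origin), times = as.numeric(series$times))
  if (!is.null(protocol))
    meta <- c(meta, protocol[c("dt_frame", "t_bleach", "t_image", "t_compare")])
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}

#' Raster sampling context for a DG space
#'
#' Precomputes the pixel-grid/mesh correspondence (containing triangle and
#' barycentric weights per pixel center) so frame series can be rasterized
#' repeatedly at no extra lookup cost. The raster covers the mesh bounding
#' box with the origin at its lower-left corner.
#'
#' @param space a [dg_space()].
#' @param pixel_size um per pixel.
#' @return list with `nrow`, `ncol`, `origin`, `pixel_size`, `tri_of`,
#'   `bary` (used by [rasterize_frame()]).
#' @export
raster_context <- function(space, pixel_size) {
  mesh <- space$mesh
  xr <- range(mesh$vertices[, 1]); yr <- range(mesh$vertices[, 2])
  shift <- c(xr[1], yr[1])
  ncol_img <- ceiling((xr[2] - xr[1]) / pixel_size) + 1L
  nrow_img <- ceiling((yr[2] - yr[1]) / pixel_size) + 1L
  px <- (seq_len(ncol_img) - 0.5) * pixel_size + shift[1]
  py <- (nrow_img - seq_len(nrow_img) + 0.5) * pixel_size + shift[2]
  pts <- cbind(rep(px, each = nrow_img), rep(py, ncol_img))
  tri_of <- locate_triangles(mesh, pts)
  bary <- barycentric_coords(mesh, pts, tri_of)
  list(nrow = nrow_img, ncol = ncol_img, origin = shift,
       pixel_size = pixel_size, tri_of = tri_of, bary = bary)
}

#' Rasterize one DG field on a pixel grid
#'
#' @param ctx a [raster_context()].
#' @param u DG coefficient vector.
#' @param background value for pixels outside the mesh.
#' @return image matrix (row 1 = top).
#' @export
rasterize_frame <- function(ctx, u, background = 0) {
  val <- rep(background, length(ctx$tri_of))
  ok <- !is.na(ctx$tri_of)
  d <- tri_dofs(ctx$tri_of[ok])
  val[ok] <- ctx$bary[ok, 1] * u[d[1, ]] + ctx$bary[ok, 2] * u[d[2, ]] +
    ctx$bary[ok, 3] * u[d[3, ]]
  matrix(val, ctx$nrow, ctx$ncol)
}

# point location: for each query point return the containing triangle (NA if
# none); brute force over candidate triangles via a coarse grid bucket
locate_triangles <- function(mesh, pts) {
  tr <- mesh$triangles
  v <- mesh$vertices
  nt <- nrow(tr)
  out <- rep(NA_integer_, nrow(pts))
  # bounding boxes
  xs <- matrix(v[tr, 1], nt, 3); ys <- matrix(v[tr, 2], nt, 3)
  xmin <- apply(xs, 1, min); xmax <- apply(xs, 1, max)
  ymin <- apply(ys, 1, min); ymax <- apply(ys, 1, max)
  ord <- order(xmin)
  for (q in seq_len(nrow(pts))) {
    x <- pts[q, 1]; y <- pts[q, 2]
    cand <- which(xmin <= x & xmax >= x & ymin <= y & ymax >= y)
    for (t in cand) {
      b <- tri_bary(v[tr[t, ], ], x, y)
      if (all(b > -1e-10)) { out[q] <- t; break }
    }
  }
  out
}

tri_bary <- function(p, x, y) {
  d <- (p[2, 2] - p[3, 2]) * (p[1, 1] - p[3, 1]) +
    (p[3, 1] - p[2, 1]) * (p[1, 2] - p[3, 2])
  l1 <- ((p[2, 2] - p[3, 2]) * (x - p[3, 1]) + (p[3, 1] - p[2, 1]) * (y - p[3, 2])) / d
  l2 <- ((p[3, 2] - p[1, 2]) * (x - p[3, 1]) + (p[1, 1] - p[3, 1]) * (y - p[3, 2])) / d
  c(l1, l2, 1 - l1 - l2)
}

barycentric_coords <- function(mesh, pts, tri_of) {
  out <- matrix(NA_real_, nrow(pts), 3)
  ok <- which(!is.na(tri_of))
  for (q in ok) {
    out[q, ] <- tri_bary(mesh$vertices[mesh$triangles[tri_of[q], ], ],
                         pts[q, 1], pts[q, 2])
  }
  out
}
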