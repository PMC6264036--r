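#' Model parameters of the FLIP reaction-diffusion system
#'
#' @param alpha diffusion constant of the free pool (um^2/s).
#' @param beta lumped bleach rate while the laser is on (1/s); stands for the
#'   product of the intrinsic bleach rate and the excited-state fraction.
#' @param gamma hindrance proportionality constant (1/(s * intensity unit))
#'   mapping the pre-bleach hindered field to binding rates.
#' @param membrane_mode `"permeable"` (parameter `p`) or `"active"`
#'   (parameters `k_cn`, `k_nc`).
#' @param p nuclear-membrane permeability (um/s), permeable mode.
#' @param k_cn,k_nc cytoplasm->nucleus and nucleus->cytoplasm rates (1/s),
#'   active mode.
#' @param k1 cytoplasm->aggregate binding rate (1/s).
#' @param k2 aggregate->cytoplasm release rate (1/s).
#' @return object of class `flip_parameters`.
#' @export
flip_parameters <- function(alpha, beta, gamma,
                            membrane_mode = c("permeable", "active"),
                            p = 0, k_cn = 0, k_nc = 0, k1 = 0, k2 = 0) {
  membrane_mode <- match.arg(membrane_mode)
  vals <- c(alpha, beta, gamma, p, k_cn, k_nc, k1, k2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all model parameters must be finite and >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 membrane_mode = membrane_mode, p = p,
                 k_cn = k_cn, k_nc = k_nc, k1 = k1, k2 = k2),
            class = "flip_parameters")
}

#' Split the pre-bleach frame into free and hindered pools
#'
#' The free molecules are assumed uniformly distributed at equilibrium, so the
#' uniform free intensity is the minimum of the (denoised) first frame and the
#' hindered field is the pointwise excess; the binding rate is consequently
#' zero at the lowest-intensity locations.
#'
#' @param c0 DG field of the first frame, nonnegative, not identically zero.
#' @return list with `u0` (scalar free intensity) and `ub0` (DG field >= 0);
#'   `u0 + ub0` reproduces `c0` exactly.
#' @export
split_initial_intensity <- function(c0) {
  if (!length(c0)) stop("empty intensity field")
  if (any(!is.finite(c0))) stop("non-finite intensities")
  u0 <- min(c0)
  list(u0 = u0, ub0 = c0 - u0)
}

#' Hindrance rate fields from the pre-bleach frame
#'
#' `k_on(x) = gamma * ub0(x)` and `k_off = gamma * u0`: spatially varying
#' binding proportional to the initial hindered intensity, constant release;
#' the pair is in detailed balance with the initial split at every point.
#'
#' @param gamma proportionality constant (>= 0).
#' @param u0 uniform free intensity.
#' @param ub0 hindered DG field.
#' @return list with `k_on` (DG field, 1/s) and `k_off` (scalar, 1/s).
#' @export
compute_rate_fields <- function(gamma, u0, ub0) {
  if (gamma < 0) stop("gamma must be >= 0")
  list(k_on = gamma * ub0, k_off = gamma * u0)
}

#' Equilibrium constant between two compartments
#'
#' Ratio of area-weighted mean intensities of the pre-bleach frame:
#' aggregates vs cytoplasm gives `K = k1/k2`, nucleus vs cytoplasm gives
#' `K_M = k_cn/k_nc`. Used to eliminate one rate of each exchange pair before
#' calibration.
#'
#' @param space a [dg_space()].
#' @param c0 pre-bleach DG field.
#' @param numerator `"aggregate"` or `"nucleus"`.
#' @return scalar equilibrium constant.
#' @export
equilibrium_constant <- function(space, c0, numerator = c("aggregate", "nucleus")) {
  numerator <- match.arg(numerator)
  num <- dg_region_mean(space, c0, numerator)
  den <- dg_region_mean(space, c0, "cytoplasm")
  if (den <= 0) stop("nonpositive cytoplasm mean intensity")
  num / den
}

#' Bleach protocol of a FLIP experiment
#'
#' Each frame interval of length `dt_frame` consists of a bleach segment
#' (`t_bleach` seconds at full laser power) followed by an imaging segment
#' (`t_image` seconds); the first frame is acquired before any bleaching.
#' Frames are compared at `t_i = dt_frame*(i-1) + t_compare`.
#'
#' @param dt_frame frame interval (s).
#' @param t_bleach bleach duration per frame (s).
#' @param t_image imaging duration per frame (s); must satisfy
#'   `t_bleach + t_image = dt_frame`.
#' @param n_frames number of frames (including the pre-bleach frame).
#' @param t_compare sampling offset within the frame (s), `0 < t_compare <=
#'   dt_frame`.
#' @return object of class `bleach_protocol`.
#' @export
bleach_protocol <- function(dt_frame = 2.8, t_bleach = 2, t_image = 0.8,
                            n_frames = 30, t_compare = 2.6) {
  if (abs(t_bleach + t_image - dt_frame) > 1e-9)
    stop("t_bleach + t_image must equal dt_frame")
  if (t_compare <= 0 || t_compare > dt_frame + 1e-9)
    stop("t_compare must lie in (0, dt_frame]")
  if (n_frames < 1) stop("need at least one frame")
  structure(list(dt_frame = dt_frame, t_bleach = t_bleach, t_image = t_image,
                 n_frames = as.integer(n_frames), t_compare = t_compare),
            class = "bleach_protocol")
}

#' Frame comparison times
#' @param protocol a [bleach_protocol()].
#' @return numeric vector `t_i = dt_frame*(i-1) + t_compare`.
#' @export
frame_times <- function(protocol) {
  protocol$dt_frame * (seq_len(protocol$n_frames) - 1) + protocol$t_compare
}

#' Laser on/off schedule
#'
#' The piecewise-constant bleach indicator: off for the whole first frame
#' interval (the first image is taken before bleaching, and for negative
#' times), then on for `t_bleach` and off for `t_image` within every
#' subsequent frame interval.
#'
#' @param protocol a [bleach_protocol()].
#' @return data frame with columns `t_start`, `t_end`, `theta` (0/1).
#' @export
bleach_schedule <- function(protocol) {
  segs <- list(data.frame(t_start = 0, t_end = protocol$dt_frame, theta = 0))
  for (i in seq_len(protocol$n_frames - 1L)) {
    t0 <- protocol$dt_frame * i
    segs[[length(segs) + 1L]] <-
      data.frame(t_start = t0, t_end = t0 + protocol$t_bleach, theta = 1)
    segs[[length(segs) + 1L]] <-
      data.frame(t_start = t0 + protocol$t_bleach, t_end = t0 + protocol$dt_frame,
                 theta = 0)
  }
  do.call(rbind, segs)
}

#' Bleach indicator at a time point
#' @param protocol a [bleach_protocol()].
#' @param t time (s), vectorized.
#' @return 0/1 indicator.
#' @export
bleach_indicator <- function(protocol, t) {
  off <- t < protocol$dt_frame | t < 0
  tin <- t %% protocol$dt_frame
  ifelse(!off & tin < protocol$t_bleach, 1, 0)
}

# largest dt <= dt_frame/min_substeps that divides t_bleach, t_image and
# t_compare (so every segment boundary and sampling time is a step boundary)
protocol_dt <- function(protocol, min_substeps = 10L) {
  scale <- 1e6
  vals <- round(scale * c(protocol$t_bleach, protocol$t_image,
                          protocol$t_compare,
                          protocol$dt_frame - protocol$t_compare))
  vals <- vals[vals > 0]
  g <- Reduce(function(a, b) {
    while (b) { t <- b; b <- a %% b; a <- t }
    a
  }, vals)
  dt <- g / scale
  steps <- protocol$dt_frame / dt
  if (steps < min_substeps) dt <- dt / ceiling(min_substeps / steps)
  dt
}

#' Simulated FLIP frame series
#'
#' @param times frame comparison times (s), strictly increasing.
#' @param C matrix of observable fields `c = u + u_b`, one column per frame
#'   (DG coefficients).
#' @return object of class `frame_series`.
#' @export
frame_series <- function(times, C) {
  if (length(times) != ncol(C)) stop("one column per frame required")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(times = times, C = C), class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat("frame_series:", length(x$times), "frames,", nrow(x$C), "dofs, t =",
      format(min(x$times)), "..", format(max(x$times)), "s\n")
  invisible(x)
}

#' Run a forward FLIP simulation
#'
#' Initializes the free/hindered pools from the pre-bleach field, derives the
#' hindrance rates, assembles the system operators for the chosen membrane
#' model, and advances the coupled system by backward Euler, switching between
#' the pre-factored bleach-on and bleach-off operators according to the
#' protocol. The observable `c = u + u_b` is recorded at every frame
#' comparison time.
#'
#' @param mesh a [flip_mesh()].
#' @param params a [flip_parameters()].
#' @param protocol a [bleach_protocol()].
#' @param c0 pre-bleach DG field (also used to derive `k_on`).
#' @param ops optional pre-built [flip_operators()] (for repeated runs on the
#'   same mesh and initial frame).
#' @param dt time step (s); default: the largest step that subdivides every
#'   protocol segment with at least 10 steps per frame.
#' @param sigma0 base SIPG penalty (see [flip_operators()]).
#' @return a [frame_series()].
#' @export
forward_simulate <- function(mesh, params, protocol, c0, ops = NULL,
                             dt = NULL, sigma0 = 10) {
  if (is.null(ops))
    ops <- flip_operators(mesh, c0, membrane_mode = params$membrane_mode,
                          sigma0 = sigma0)
  if (is.null(dt)) dt <- protocol_dt(protocol)
  nb <- round(protocol$t_bleach / dt)
  ni <- round(protocol$t_image / dt)
  nc <- round(protocol$t_compare / dt)
  if (abs(nb * dt - protocol$t_bleach) > 1e-9 ||
      abs(ni * dt - protocol$t_image) > 1e-9 ||
      abs(nc * dt - protocol$t_compare) > 1e-9)
    stop("dt must divide t_bleach, t_image and t_compare")

  sp <- split_initial_intensity(c0)
  state <- list(u = rep(sp$u0, ops$space$ndof) + 0 * sp$ub0, ub = sp$ub0, t = 0)
  n <- ops$space$ndof
  C <- matrix(0, n, protocol$n_frames)
  times <- frame_times(protocol)

  record <- function(frame) C[, frame] <<- state$u + state$ub
  # frame 1: laser off for the whole first interval
  if (nc > 0) state <- backward_euler_step(ops, params, state, dt, FALSE, nc)
  record(1L)
  rest1 <- (nb + ni) - nc
  if (rest1 > 0) state <- backward_euler_step(ops, params, state, dt, FALSE, rest1)
  if (protocol$n_frames > 1L) for (i in 2:protocol$n_frames) {
    if (nc <= nb) {
      if (nc > 0) state <- backward_euler_step(ops, params, state, dt, TRUE, nc)
      record(i)
      if (nb - nc > 0) state <- backward_euler_step(ops, params, state, dt, TRUE, nb - nc)
      if (ni > 0) state <- backward_euler_step(ops, params, state, dt, FALSE, ni)
    } else {
      if (nb > 0) state <- backward_euler_step(ops, params, state, dt, TRUE, nb)
      state <- backward_euler_step(ops, params, state, dt, FALSE, nc - nb)
      record(i)
      if ((nb + ni) - nc > 0)
        state <- backward_euler_step(ops, params, state, dt, FALSE, (nb + ni) - nc)
    }
  }
  frame_series(times, C)
}
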