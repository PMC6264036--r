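# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the default-scale cell mesh (roughly 450 triangles)
fixture_cell_mesh <- function() {
  memo("cell_mesh", function() build_synthetic_cell(default_cell_spec()))
}

# a coarser version of the same geometry for cheap calibration tests
small_cell_spec <- function() {
  cell_geometry_spec(disc(0, 0, 15), disc(-6, 0, 5),
                     aggregates = list(disc(6, 6, 2), disc(8, -3, 2),
                                       disc(0, -9, 2)),
                     bleach = disc(-6, 0, 1.2), h = 3.4, h_nucleus = 1.6)
}

fixture_small_mesh <- function() {
  memo("small_mesh", function() build_synthetic_cell(small_cell_spec()))
}

# mesh with an equilibrium-compatible prebleach field (equal region means)
fixture_equilibrium_setup <- function(mode = "permeable") {
  memo(paste0("equil_", mode), function() {
    mesh <- fixture_small_mesh()
    space <- dg_space(mesh)
    c0 <- synthetic_prebleach_field(space, K = 1, K_M = 1)
    list(mesh = mesh, space = space, c0 = c0,
         ops = flip_operators(mesh, c0, membrane_mode = mode))
  })
}

truth_free <- c(alpha = 17, beta = 36, gamma = 0.2, p = 0.3, k1 = 0.0718)

# deterministic smooth pseudo-random field (no RNG state touched)
runif_fixed <- function(n, offset = 0) 0.5 + 0.4 * sin(seq_len(n) + offset)

# dense method-of-lines oracle: integrate Mass2 dx/dt = S(t) x with a stiff
# solver, switching S at the bleach schedule boundaries
mol_oracle <- function(ops, params, protocol, x0, times) {
  M2 <- as.matrix(ops$Mass2)
  S_on <- solve(M2, as.matrix(spatial_operator(ops, params, TRUE)))
  S_off <- solve(M2, as.matrix(spatial_operator(ops, params, FALSE)))
  seg <- bleach_schedule(protocol)
  x <- x0
  out <- matrix(NA_real_, length(x0), length(times))
  t_now <- 0
  deriv <- function(t, y, parms) list(parms %*% y)
  for (k in seq_len(nrow(seg))) {
    tt <- sort(unique(c(seg$t_start[k], times[times > seg$t_start[k] + 1e-12 &
                                               times <= seg$t_end[k] + 1e-12],
                        seg$t_end[k])))
    A <- if (seg$theta[k] > 0) S_on else S_off
    sol <- deSolve::lsoda(x, tt, deriv, parms = A, rtol = 1e-10, atol = 1e-12)
    for (ti in seq_along(times))
      if (any(abs(sol[, 1] - times[ti]) < 1e-9))
        out[, ti] <- sol[which.min(abs(sol[, 1] - times[ti])), -1]
    x <- as.numeric(sol[nrow(sol), -1])
  }
  out
}
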