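test_that("backward Euler with all rates zero leaves the state unchanged", {
  setup <- fixture_equilibrium_setup()
  params <- flip_parameters(0, 0, 0, "permeable", p = 0, k1 = 0, k2 = 0)
  n <- setup$ops$space$ndof
  state <- list(u = runif_fixed(n), ub = runif_fixed(n, offset = 1), t = 0)
  out <- backward_euler_step(setup$ops, params, state, dt = 0.5, FALSE, 3L)
  expect_equal(out$u, state$u, tolerance = 1e-12)
  expect_equal(out$ub, state$ub, tolerance = 1e-12)
  expect_equal(out$t, 1.5)
})

test_that("pure bleach over the whole domain matches the implicit scalar recursion", {
  base <- two_triangle_mesh(c("cytoplasm", "cytoplasm"))
  mesh <- flip_mesh(base$vertices, base$triangles, c("nucleus", "nucleus"),
                    bleach = c(TRUE, TRUE))
  c0 <- rep(2, 6)
  ops <- flip_operators(mesh, c0, "permeable")
  beta <- 36; dt <- 0.1; nst <- 10L
  params <- flip_parameters(0, beta, 0, "permeable")
  state <- list(u = rep(1, 6), ub = rep(0, 6), t = 0)
  out <- backward_euler_step(ops, params, state, dt, bleach_on = TRUE, nst)
  expect_equal(out$u, rep(1 / (1 + beta * dt)^nst, 6), tolerance = 1e-10)
})

test_that("two-triangle exchange agrees with the matrix exponential to O(dt)", {
  mesh <- two_triangle_mesh(c("cytoplasm", "aggregate"))
  space <- dg_space(mesh)
  edges <- classify_edges(mesh)
  sc <- interface_scale_factors(mesh, edges, "aggregate")
  X <- assemble_directional_exchange(space, edges, "aggregate", 1, 0.5, sc)
  M <- assemble_mass(space)
  Sd <- solve(as.matrix(M), as.matrix(X))
  u0 <- c(1, 1, 1, 0, 0, 0)
  Tend <- 2
  exact <- as.numeric(Matrix::expm(Matrix::Matrix(Sd * Tend)) %*% u0)
  be_err <- function(dt) {
    A <- as.matrix(M) - dt * as.matrix(X)
    u <- u0
    for (k in seq_len(round(Tend / dt))) u <- solve(A, as.matrix(M) %*% u)
    max(abs(u - exact))
  }
  errs <- vapply(c(0.1, 0.05, 0.025), be_err, numeric(1))
  # first-order decay: each halving of dt reduces the error by ~2
  expect_gt(errs[1] / errs[2], 1.5)
  expect_gt(errs[2] / errs[3], 1.5)
})

test_that("total mass is conserved with bleach off for both membrane models", {
  for (mode in c("permeable", "active")) {
    setup <- fixture_equilibrium_setup(mode)
    params <- flip_parameters(17, 36, 0.2, mode, p = 0.3,
                              k_cn = 0.25, k_nc = 0.25 / setup$ops$K_M,
                              k1 = 0.0718, k2 = 0.0718 / setup$ops$K)
    sp <- split_initial_intensity(setup$c0)
    state <- list(u = rep(sp$u0, setup$ops$space$ndof), ub = sp$ub0, t = 0)
    m0 <- total_mass(setup$ops, state)
    state <- backward_euler_step(setup$ops, params, state, dt = 0.2,
                                 bleach_on = FALSE, n_steps = 100L)
    expect_lt(abs(total_mass(setup$ops, state) - m0) / m0, 1e-10)
  }
})

test_that("compartment-balanced equilibrium states are stationary", {
  for (mode in c("permeable", "active")) {
    setup <- fixture_equilibrium_setup(mode)
    ops <- setup$ops
    mesh <- setup$mesh
    # K = K_M = 1 on this fixture, so a globally uniform free pool with the
    # detailed-balance hindered field is a full equilibrium of the model
    expect_equal(ops$K, 1, tolerance = 1e-12)
    params <- flip_parameters(17, 36, 0.2, mode, p = 0.3,
                              k_cn = 0.25, k_nc = 0.25,
                              k1 = 0.0718, k2 = 0.0718)
    sp <- split_initial_intensity(setup$c0)
    u <- rep(sp$u0, ops$space$ndof)
    ub <- (sp$ub0 / sp$u0) * u
    S <- spatial_operator(ops, params, bleach_on = FALSE)
    resid <- as.numeric(S %*% c(u, ub))
    expect_lt(max(abs(resid)) / max(abs(u)), 1e-10)
    state <- backward_euler_step(ops, params, list(u = u, ub = ub, t = 0),
                                 dt = 0.2, FALSE, 1L)
    expect_lt(max(abs(state$u - u)) / max(abs(u)), 1e-10)
    expect_lt(max(abs(state$ub - ub)) / max(abs(u)), 1e-10)
  }
})
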