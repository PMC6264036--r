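test_that("mass matrix has the exact local P1 block and sums to the area", {
  mesh <- two_triangle_mesh(c("cytoplasm", "cytoplasm"), width = 2, height = 1)
  space <- dg_space(mesh)
  M <- assemble_mass(space)
  ones <- rep(1, space$ndof)
  expect_equal(as.numeric(ones %*% (M %*% ones)), 2, tolerance = 1e-14)
  Tarea <- space$area[1]
  expect_equal(as.matrix(M[1:3, 1:3]),
               Tarea / 12 * matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3),
               tolerance = 1e-14)
  expect_lt(max(abs(M - Matrix::t(M))), 1e-15)
})

test_that("SIPG diffusion annihilates constants and is exact for linear fields", {
  mesh <- unit_square_mesh(3)
  space <- dg_space(mesh)
  edges <- classify_edges(mesh)
  alpha <- 2.5
  D <- assemble_diffusion_sipg(space, edges, alpha, sigma = 10)
  expect_lt(max(abs(D %*% rep(1, space$ndof))), 1e-12)
  # globally continuous linear field: penalty/jumps vanish, energy = alpha*area
  u <- dg_interpolate(space, function(x, y) x)
  expect_equal(as.numeric(u %*% (D %*% u)), alpha * 1, tolerance = 1e-12)
  expect_lt(max(abs(D - Matrix::t(D))), 1e-12)
  # positive semidefinite for the default penalty
  ev <- eigen(as.matrix(D), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_error(assemble_diffusion_sipg(space, edges, 1, sigma = 0), "sigma")
})

test_that("SIPG heat equation converges at second order in L2", {
  run <- function(n) {
    mesh <- unit_square_mesh(n)
    space <- dg_space(mesh)
    edges <- classify_edges(mesh)
    M <- assemble_mass(space)
    D <- assemble_diffusion_sipg(space, edges, alpha = 1, sigma = 10)
    Tend <- 0.02
    nst <- ceiling(Tend / (0.05 / n^2))
    dt <- Tend / nst
    f <- Matrix::lu(M + dt * D)
    u <- dg_interpolate(space, function(x, y) cos(pi * x) * cos(pi * y))
    for (k in seq_len(nst)) u <- as.numeric(Matrix::solve(f, M %*% u))
    ue <- dg_interpolate(space, function(x, y) cos(pi * x) * cos(pi * y)) *
      exp(-2 * pi^2 * Tend)
    d <- u - ue
    sqrt(as.numeric(d %*% (M %*% d)))
  }
  e1 <- run(8)
  e2 <- run(16)
  expect_gte(e1 / e2, 3)
})

test_that("reaction blocks satisfy detailed balance and the direct integral", {
  mesh <- two_triangle_mesh(c("cytoplasm", "cytoplasm"))
  space <- dg_space(mesh)
  # null case
  R0 <- assemble_local_reaction(space, rep(0, space$ndof), 0)
  expect_equal(Matrix::norm(R0$Kon, "F") + Matrix::norm(R0$Koff, "F"), 0)
  # one triangle, area T, k_on = 2, k_off = 1, u = 1, ub = 3:
  # u-row residual against v = 1 is (1*3 - 2*1)*T
  R <- assemble_local_reaction(space, rep(2, space$ndof), 1)
  u <- rep(1, space$ndof); ub <- rep(3, space$ndof)
  resid_u <- R$Koff %*% ub - R$Kon %*% u
  Tarea <- space$area[1]
  expect_equal(sum(resid_u[1:3]), (1 * 3 - 2 * 1) * Tarea, tolerance = 1e-13)
  # pointwise equilibrium k_off*ub = k_on*u gives a zero contribution
  ub_eq <- 2 * u / 1
  expect_lt(max(abs(R$Koff %*% ub_eq - R$Kon %*% u)), 1e-13)
  expect_error(assemble_local_reaction(space, rep(-1, space$ndof), 1), "k_on")
})

test_that("bleach matrix integrates only over flagged triangles", {
  mesh <- flip_mesh(two_triangle_mesh(c("cytoplasm", "cytoplasm"))$vertices,
                    two_triangle_mesh(c("cytoplasm", "cytoplasm"))$triangles,
                    c("nucleus", "nucleus"), bleach = c(TRUE, FALSE))
  space <- dg_space(mesh)
  beta <- 3
  B <- assemble_bleach(space, mesh, beta)
  ones <- rep(1, space$ndof)
  expect_equal(as.numeric(ones %*% (B %*% ones)), beta * space$area[1],
               tolerance = 1e-14)
  expect_true(all(B[4:6, ] == 0))          # unflagged triangle rows are zero
  expect_equal(Matrix::norm(assemble_bleach(space, mesh, 0), "F"), 0)
  expect_error(assemble_bleach(space, mesh, -1), "beta")
})

test_that("directional exchange reproduces the hand edge integral and conserves mass", {
  mesh <- two_triangle_mesh(c("cytoplasm", "aggregate"))
  space <- dg_space(mesh)
  edges <- classify_edges(mesh)
  L <- sqrt(2)                              # diagonal interface
  X <- assemble_directional_exchange(space, edges, "aggregate",
                                     k_fwd = 1, k_bwd = 0, scale = 1)
  # u = 1 on the cytoplasm side, 0 on the aggregate side: the aggregate side
  # receives total L and the cytoplasm side loses L
  uC <- c(1, 1, 1, 0, 0, 0)
  r <- as.numeric(X %*% uC)
  expect_equal(sum(r[4:6]), L, tolerance = 1e-13)
  expect_equal(sum(r[1:3]), -L, tolerance = 1e-13)
  # local edge blocks are the P1 edge mass matrix (L/6)[[2,1],[1,2]] x rates
  rows_a <- 3L + which(mesh$triangles[2, ] %in% c(1, 3))  # aggregate-side dofs
  cols_c <- which(mesh$triangles[1, ] %in% c(1, 3))       # cytoplasm-side dofs
  blk <- as.matrix(X[rows_a, cols_c])
  expect_equal(sort(unique(round(as.vector(blk) / (L / 6), 10))), c(1, 2))
  # conservation: column sums vanish (test function 1 on both sides)
  expect_lt(max(abs(rep(1, 6) %*% X)), 1e-13)
  # cross-edge equilibrium u_A = (k1/k2) u_C is in the kernel
  K <- 1.4
  Xk <- assemble_directional_exchange(space, edges, "aggregate",
                                      k_fwd = 0.7, k_bwd = 0.7 / K, scale = 1)
  ueq <- c(1, 1, 1, K, K, K)
  expect_lt(max(abs(Xk %*% ueq)), 1e-13)
  expect_error(assemble_directional_exchange(space, edges, "aggregate", -1, 0),
               ">= 0")
})

test_that("interface scale factors give region area over perimeter", {
  mesh <- two_triangle_mesh(c("cytoplasm", "aggregate"))
  edges <- classify_edges(mesh)
  sc <- interface_scale_factors(mesh, edges, "aggregate")
  expect_equal(sc, 0.5 / sqrt(2), tolerance = 1e-13)
  mesh2 <- fixture_small_mesh()
  edges2 <- classify_edges(mesh2)
  sc2 <- interface_scale_factors(mesh2, edges2, "membrane")
  ra <- region_areas(mesh2)
  per <- interface_perimeters(edges2)
  expect_equal(unique(round(sc2, 12)), round(ra$nucleus / per$membrane, 12))
})

test_that("permeable membrane operator penalizes only the membrane jump", {
  mesh <- two_triangle_mesh(c("cytoplasm", "nucleus"))
  space <- dg_space(mesh)
  edges <- classify_edges(mesh)
  p <- 0.3
  M <- assemble_permeable_membrane(space, edges, p)
  expect_equal(Matrix::norm(assemble_permeable_membrane(space, edges, 0), "F"), 0)
  # continuous field across the membrane: M u = 0
  u <- dg_interpolate(space, function(x, y) 1 + 2 * x - y)
  expect_lt(max(abs(M %*% u)), 1e-12)
  # constant jump d across the single membrane edge of length L
  d <- 0.7
  uj <- c(rep(1, 3), rep(1 + d, 3))
  L <- sqrt(2)
  expect_equal(as.numeric(uj %*% (M %*% uj)), -p * d^2 * L, tolerance = 1e-12)
  # negative semidefinite
  ev <- eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(ev), 1e-12)
  expect_error(assemble_permeable_membrane(space, edges, -0.1), ">= 0")
})
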