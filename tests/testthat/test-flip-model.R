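test_that("the initial split gives a uniform free pool and exact reconstruction", {
  c0 <- c(1, 0.2, 0.7, 0.2, 1.0, 0.5)
  sp <- split_initial_intensity(c0)
  expect_equal(sp$u0, 0.2)
  expect_equal(sp$ub0[5], 0.8)
  expect_true(all(sp$ub0 >= 0))
  expect_equal(sp$u0 + sp$ub0, c0)                 # exact reconstruction
  uh <- split_initial_intensity(rep(3, 10))
  expect_equal(uh$u0, 3)
  expect_true(all(uh$ub0 == 0))
  expect_error(split_initial_intensity(numeric(0)), "empty")
})

test_that("hindrance rates follow the proportionality rule and detailed balance", {
  rf <- compute_rate_fields(0.2, u0 = 1, ub0 = c(0, 0.5, 2))
  expect_equal(rf$k_off, 0.2)
  expect_equal(rf$k_on, c(0, 0.1, 0.4))
  # balance identity k_on * u0 = k_off * ub0 at every dof
  expect_equal(rf$k_on * 1, rf$k_off * c(0, 0.5, 2))
  expect_equal(compute_rate_fields(0.3, 1, rep(0, 4))$k_on, rep(0, 4))
  expect_error(compute_rate_fields(-0.1, 1, 0), "gamma")
})

test_that("equilibrium constants are area-weighted intensity ratios", {
  mesh <- fixture_small_mesh()
  space <- dg_space(mesh)
  c0 <- synthetic_prebleach_field(space, K = 1.16, K_M = 1.26)
  expect_equal(equilibrium_constant(space, c0, "aggregate"), 1.16,
               tolerance = 1e-10)
  expect_equal(equilibrium_constant(space, c0, "nucleus"), 1.26,
               tolerance = 1e-10)
  flat <- synthetic_prebleach_field(space, K = 1, K_M = 1)
  expect_equal(equilibrium_constant(space, flat, "aggregate"), 1,
               tolerance = 1e-10)
})

test_that("the bleach schedule alternates 2 s on / 0.8 s off after a pre-bleach frame", {
  prot <- bleach_protocol(dt_frame = 2.8, t_bleach = 2, t_image = 0.8,
                          n_frames = 4, t_compare = 2.6)
  sched <- bleach_schedule(prot)
  expect_equal(sched$theta[1], 0)                       # pre-bleach frame
  on <- sched[sched$theta == 1, ]
  expect_true(all(abs(on$t_end - on$t_start - 2) < 1e-12))
  off <- sched[sched$theta == 0, ][-1, ]
  expect_true(all(abs(off$t_end - off$t_start - 0.8) < 1e-12))
  expect_equal(frame_times(prot)[1], 2.6)               # t_i formula, i = 1
  expect_equal(frame_times(prot)[3], 2.8 * 2 + 2.6)
  expect_equal(bleach_indicator(prot, -1), 0)           # pre-experiment
  expect_equal(bleach_indicator(prot, 3.0), 1)
  expect_equal(bleach_indicator(prot, 5.2), 0)
  expect_error(bleach_protocol(dt_frame = 2, t_bleach = 2, t_image = 0.8),
               "dt_frame")
})

test_that("equilibrium initial states stay fixed without bleaching", {
  setup <- fixture_equilibrium_setup()
  params <- flip_parameters(17, 0, 0.2, "permeable", p = 0.3,
                            k1 = 0.05, k2 = 0.05)
  prot <- bleach_protocol(n_frames = 4)
  fs <- forward_simulate(setup$mesh, params, prot, setup$c0, ops = setup$ops)
  for (i in 2:4)
    expect_lt(max(abs(fs$C[, i] - fs$C[, 1])) / max(fs$C[, 1]), 1e-8)
})

test_that("bleaching monotonically removes mass; without bleaching mass is conserved", {
  mesh <- fixture_small_mesh()
  space <- dg_space(mesh)
  c0 <- synthetic_prebleach_field(space)
  prot <- bleach_protocol(n_frames = 6)
  params <- flip_parameters(17, 36, 0.2, "permeable", p = 0.3,
                            k1 = 0.0718, k2 = 0.0718 / 1.16)
  ops <- flip_operators(mesh, c0, "permeable")
  fs <- forward_simulate(mesh, params, prot, c0, ops = ops)
  M <- ops$Mass
  mass <- vapply(seq_len(6), function(i)
    as.numeric(rep(1, space$ndof) %*% (M %*% fs$C[, i])), numeric(1))
  expect_true(all(diff(mass) < 0))
  # same run with beta = 0: conserved across frames
  params0 <- flip_parameters(17, 0, 0.2, "permeable", p = 0.3,
                             k1 = 0.0718, k2 = 0.0718 / 1.16)
  fs0 <- forward_simulate(mesh, params0, prot, c0, ops = ops)
  mass0 <- vapply(seq_len(6), function(i)
    as.numeric(rep(1, space$ndof) %*% (M %*% fs0$C[, i])), numeric(1))
  expect_lt(max(abs(mass0 - mass0[1])) / mass0[1], 1e-10)
})

test_that("forward frames match a stiff method-of-lines solve to O(dt)", {
  skip_if_not_installed("deSolve")
  mesh <- two_triangle_mesh(c("cytoplasm", "nucleus"))
  mesh <- flip_mesh(mesh$vertices, mesh$triangles, mesh$compartment,
                    bleach = c(FALSE, TRUE))
  c0 <- c(1, 1.2, 1.1, 1.3, 1.05, 1.15)
  params <- flip_parameters(2, 5, 0.3, "permeable", p = 0.4)
  prot <- bleach_protocol(dt_frame = 1, t_bleach = 0.5, t_image = 0.5,
                          n_frames = 3, t_compare = 1)
  ops <- flip_operators(mesh, c0, "permeable")
  sp <- split_initial_intensity(c0)
  x0 <- c(rep(sp$u0, 6), sp$ub0)
  oracle <- mol_oracle(ops, params, prot, x0, frame_times(prot))
  c_oracle <- oracle[1:6, ] + oracle[7:12, ]
  err <- function(dt) {
    fs <- forward_simulate(mesh, params, prot, c0, ops = ops, dt = dt)
    max(abs(fs$C - c_oracle))
  }
  e1 <- err(0.1); e2 <- err(0.05)
  expect_gt(e1 / e2, 1.5)                  # first-order in dt
  expect_lt(e2, 0.05)
})

test_that("reduced nuclear export accumulates protein in the nucleus", {
  mesh <- fixture_small_mesh()
  space <- dg_space(mesh)
  c0 <- synthetic_prebleach_field(space)
  prot <- bleach_protocol(n_frames = 8)
  ratio_for <- function(k_nc) {
    params <- flip_parameters(17, 36, 0.2, "active", k_cn = 0.252, k_nc = k_nc,
                              k1 = 0.0718, k2 = 0.0718 / 1.16)
    ops <- flip_operators(mesh, c0, "active", K_M = 0.252 / k_nc)
    fs <- forward_simulate(mesh, params, prot, c0, ops = ops)
    cl <- fs$C[, 8]
    dg_region_mean(space, cl, "nucleus") / dg_region_mean(space, cl, "cytoplasm")
  }
  # bleaching happens in the nucleus, so trapping protein there by slowing
  # export speeds up total loss but raises the nucleus/cytoplasm ratio only
  # when export is the bottleneck; the ratio must rise monotonically as the
  # export rate k_nc falls
  ratios <- vapply(c(0.342, 0.2, 0.05), ratio_for, numeric(1))
  expect_lt(ratios[1], ratios[2])
  expect_lt(ratios[2], ratios[3])
})

test_that("aggregates hold fluorescence longer than the surrounding cytoplasm", {
  mesh <- fixture_small_mesh()
  space <- dg_space(mesh)
  c0 <- synthetic_prebleach_field(space)
  prot <- bleach_protocol(n_frames = 10)
  params <- flip_parameters(17, 36, 0.2, "permeable", p = 0.3,
                            k1 = 0.0718, k2 = 0.0718 / 1.16)
  fs <- forward_simulate(mesh, params, prot, c0)
  rel <- function(i, comp) {
    dg_region_mean(space, fs$C[, i], comp) / dg_region_mean(space, fs$C[, 1], comp)
  }
  expect_gt(rel(10, "aggregate"), rel(10, "cytoplasm"))
})
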