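test_that("the non-iterative barrier time is 2.302 / kbar", {
  expect_equal(optimal_barrier_time(1), 2.302)
  expect_equal(optimal_barrier_time(0.01), 230.2)
  expect_equal(optimal_barrier_time(2), optimal_barrier_time(1) / 2)
  expect_error(optimal_barrier_time(0), "positive")
  expect_error(optimal_barrier_time(-3), "positive")
})

test_that("branch rate entries have the right limits on both branches", {
  st <- molecular_state(rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 3.3, 0.5)))
  m <- eigendecompose(build_hessian(st, cutoff = 10, gamma = 1))
  tbar <- 1.7; t_f <- 4.0
  left <- branch_rate_matrix(m, tbar, "left")
  right <- branch_rate_matrix(m, tbar, "right", t_f = t_f)

  # zero modes: 1/tbar on the left, 1/(tbar - t_f) on the right
  expect_equal(left[m$zero_modes], rep(1 / tbar, 6))
  expect_equal(right[m$zero_modes], rep(1 / (tbar - t_f), 6))

  # the lambda -> 0 limit of lambda*coth(lambda t) is 1/t to first order
  lam_small <- 1e-9
  expect_equal(lam_small * ompath:::coth_stable(lam_small * tbar), 1 / tbar,
               tolerance = 1e-12)

  # nonzero modes match the direct high-precision cosh/sinh evaluation
  nz <- setdiff(seq_along(m$values), m$zero_modes)
  lam <- m$values[nz]
  expect_equal(left[nz], lam * cosh(lam * tbar) / sinh(lam * tbar),
               tolerance = 1e-12)
  expect_equal(right[nz],
               lam * cosh(lam * (tbar - t_f)) / sinh(lam * (tbar - t_f)),
               tolerance = 1e-12)

  # large-argument asymptote: lambda * t = 50 gives exactly lambda
  expect_equal(5 * ompath:::coth_stable(50), 5, tolerance = 1e-15)

  expect_error(branch_rate_matrix(m, -1, "left"), "positive")
  expect_error(branch_rate_matrix(m, 5, "right", t_f = 4), "exceed")
})

test_that("identical end states give a fixed-point transition state", {
  fx <- hinge_fixture(n_atoms = 10, gamma = 0.3)
  a <- as.vector(t(fx$a$coords))
  ts <- solve_transition_state(fx$model_a, fx$model_a, a, a, 2, 2)
  expect_equal(ts$xbar, a, tolerance = 1e-9)
  expect_equal(delta_energy(ts, a, a, fx$model_a, fx$model_a), 0, tolerance = 1e-12)
})

test_that("mirror-symmetric pairs give the exact midpoint and zero energy gap", {
  for (seed in c(2, 6)) {
    pair <- make_two_state_pair(n_atoms = 10, mode = "mirror", seed = seed,
                                noise = 0.2)
    ma <- eigendecompose(build_hessian(pair$a, gamma = 0.05))
    mb <- eigendecompose(build_hessian(pair$b, gamma = 0.05))
    expect_equal(ma$values, mb$values, tolerance = 1e-10)  # conjugate spectra
    a <- as.vector(t(pair$a$coords)); b <- as.vector(t(pair$b$coords))
    tbar <- optimal_barrier_time(average_force_constant(ma))
    ts <- solve_transition_state(ma, mb, a, b, tbar, tbar)
    expect_equal(ts$xbar, (a + b) / 2, tolerance = 1e-8)
    expect_equal(delta_energy(ts, a, b, ma, mb), 0, tolerance = 1e-8)
  }
})

test_that("the 3N solve reduces to the 1D velocity-continuity root on a diatomic", {
  fx <- embedded_diatomic(bond_a = 3.0, bond_b = 3.6, gamma_a = 0.8, gamma_b = 0.5)
  tbar_l <- 2.0; tbar_r <- 3.0
  ts <- solve_transition_state(fx$model_a, fx$model_b, fx$a, fx$b, tbar_l, tbar_r)
  # mode coordinate: bond projection on the stretch eigenvector carries
  # force constant 2*gamma
  well <- double_well_1d(a = 3.0 / sqrt(2), b = 3.6 / sqrt(2),
                         k_l = 2 * 0.8, k_r = 2 * 0.5)
  ref <- solve_transition_1d(well, t_f = tbar_l + tbar_r, tbar = tbar_l)
  expect_equal(stretch_coord(ts$xbar), ref$xbar, tolerance = 1e-8)
  expect_equal(delta_energy(ts, fx$a, fx$b, fx$model_a, fx$model_b),
               ref$delta_e, tolerance = 1e-8)
})

test_that("velocity continuity residual is tiny on every fixture", {
  cases <- list(
    hinge_fixture(n_atoms = 8, angle = 15, seed = 1, gamma = 0.05),
    hinge_fixture(n_atoms = 14, angle = 35, seed = 2, gamma = 0.01),
    hinge_fixture(n_atoms = 10, angle = 25, seed = 3, gamma = 0.5, noise = 0.1)
  )
  for (fx in cases) {
    kl <- average_force_constant(fx$model_a)
    kr <- average_force_constant(fx$model_b)
    ts <- solve_transition_state(fx$model_a, fx$model_b, fx$a, fx$b,
                                 optimal_barrier_time(kl), optimal_barrier_time(kr))
    expect_lt(ts$residual, 1e-6)
  }
})

test_that("the cusp minimizes the discretized OM action (independent oracle)", {
  # 2-atom system
  fx2 <- embedded_diatomic(3.0, 3.5, gamma_a = 0.6, gamma_b = 0.4)
  ts2 <- solve_transition_state(fx2$model_a, fx2$model_b, fx2$a, fx2$b, 2.0, 2.5)
  or2 <- om_action_cusp_extrapolated(fx2$model_a$hessian, fx2$model_b$hessian,
                                     as.vector(t(fx2$a$coords)),
                                     as.vector(t(fx2$b$coords)), 2.0, 2.5, m = 150)
  expect_equal(ts2$xbar, or2, tolerance = 1e-6)

  # 3-atom system with distinct well stiffnesses
  pair <- make_two_state_pair(n_atoms = 3, mode = "hinge", angle = 30, seed = 5)
  ma <- eigendecompose(build_hessian(pair$a, cutoff = 15, gamma = 0.3))
  mb <- eigendecompose(build_hessian(pair$b, cutoff = 15, gamma = 0.4))
  a <- as.vector(t(pair$a$coords)); b <- as.vector(t(pair$b$coords))
  ts3 <- solve_transition_state(ma, mb, a, b, 2.5, 3.0)
  or3 <- om_action_cusp_extrapolated(ma$hessian, mb$hessian, a, b, 2.5, 3.0, m = 150)
  expect_equal(ts3$xbar, or3, tolerance = 1e-6)
})

test_that("energy gap cases: coincident cusp and scalar reduction", {
  fx <- hinge_fixture(n_atoms = 10, gamma = 0.2)
  a <- as.vector(t(fx$a$coords)); b <- as.vector(t(fx$b$coords))
  ts <- solve_transition_state(fx$model_a, fx$model_b, a, b, 3, 3)
  # xbar forced to a: the initial-well term vanishes
  ts_at_a <- ts; ts_at_a$xbar <- a
  expect_equal(delta_energy(ts_at_a, a, b, fx$model_a, fx$model_b),
               as.numeric(crossprod(a - b, fx$model_b$hessian %*% (a - b))) / 2)
  expect_error(delta_energy(ts, a[-1], b, fx$model_a, fx$model_b), "mismatch")
})

test_that("trajectories satisfy boundary conditions and cusp continuity", {
  fx <- hinge_fixture(n_atoms = 9, angle = 20, seed = 8, gamma = 0.1)
  a <- as.vector(t(fx$a$coords)); b <- as.vector(t(fx$b$coords))
  ts <- solve_transition_state(fx$model_a, fx$model_b, a, b, 4, 5)
  traj <- generate_trajectory(ts, fx$a, fx$b, fx$model_a, fx$model_b, n_frames = 120)

  expect_equal(traj$frames[1, ], a, ignore_attr = TRUE)
  expect_equal(traj$frames[nrow(traj$frames), ], b, ignore_attr = TRUE)
  cusp <- which(traj$times == ts$tbar_l)
  expect_length(cusp, 1L)
  expect_lt(max(abs(traj$frames[cusp, ] - ts$xbar)), 1e-8)
  expect_true(!is.unsorted(traj$times, strictly = TRUE))
  expect_equal(unique(traj$branch[traj$times <= ts$tbar_l]), "left")

  # finite-difference velocity jump across the cusp shrinks ~ linearly in h
  vel_jump <- function(n_frames) {
    tr <- generate_trajectory(ts, a, b, fx$model_a, fx$model_b, n_frames)
    i <- which(tr$times == ts$tbar_l)
    vl <- (tr$frames[i, ] - tr$frames[i - 1, ]) / (tr$times[i] - tr$times[i - 1])
    vr <- (tr$frames[i + 1, ] - tr$frames[i, ]) / (tr$times[i + 1] - tr$times[i])
    max(abs(vl - vr))
  }
  j1 <- vel_jump(100); j2 <- vel_jump(400)
  expect_lt(j2, j1 / 2)   # first-order continuity
})

test_that("soft modes just above the zero threshold interpolate finitely", {
  # a longer chain carries a near-zero torsion-like mode whose lambda*t is
  # far below 1; its branch factor must fall back to linear interpolation
  pair <- make_two_state_pair(n_atoms = 15, mode = "hinge", angle = 25, seed = 2)
  res <- compute_path(pair$a, pair$b)
  expect_true(all(is.finite(res$trajectory_full$frames)))
  expect_lt(res$report$velocity_residual, 1e-6)
})

test_that("truncation drops only the invariant ends and reports the spans", {
  fx <- hinge_fixture(n_atoms = 10, angle = 30, seed = 4, gamma = 0.05)
  res_full <- compute_path(fx$a, fx$b, gamma = 0.05, truncation_fraction = 0.1)
  traj <- res_full$trajectory_full

  tiny <- truncate_trajectory(traj, fraction = 1e-9)
  expect_equal(nrow(tiny$frames), nrow(traj$frames))

  cut <- truncate_trajectory(traj, fraction = 0.1)
  expect_lt(nrow(cut$frames), nrow(traj$frames))
  # retained frames are unchanged
  keep <- traj$times %in% cut$times
  expect_identical(cut$frames, traj$frames[keep, , drop = FALSE])
  expect_gt(cut$truncation$head_span + cut$truncation$tail_span, 0)
  expect_error(truncate_trajectory(traj, fraction = 1.5), "fraction")
  expect_error(truncate_trajectory(traj, fraction = 0), "fraction")
})

test_that("the 1% and 10% progress rules give nearly identical transition states", {
  fx <- hinge_fixture(n_atoms = 12, angle = 25, seed = 3, gamma = 0.01)
  kl <- average_force_constant(fx$model_a)
  kr <- average_force_constant(fx$model_b)
  # 10% rule: offset 2.302/k; 1% rule: offset -ln(0.01)/k = 4.605/k
  ts10 <- solve_transition_state(fx$model_a, fx$model_b, fx$a, fx$b,
                                 2.302 / kl, 2.302 / kr)
  ts01 <- solve_transition_state(fx$model_a, fx$model_b, fx$a, fx$b,
                                 4.605 / kl, 4.605 / kr)
  n <- length(ts10$xbar) / 3
  rmsd <- sqrt(sum((ts10$xbar - ts01$xbar)^2) / n)
  # imperceptible relative to the conformational change itself
  expect_lt(rmsd / rmsd_states(fx$a, fx$b), 0.05)
})

test_that("swapping the inputs exchanges branches and negates the gap", {
  fx <- hinge_fixture(n_atoms = 10, angle = 25, seed = 6, gamma = 0.05)
  fwd <- compute_path(fx$a, fx$b, gamma = 0.05, superpose = FALSE)
  rev <- compute_path(fx$b, fx$a, gamma = 0.05, superpose = FALSE)
  expect_equal(fwd$transition_state$xbar, rev$transition_state$xbar, tolerance = 1e-6)
  expect_equal(fwd$report$delta_e, -rev$report$delta_e, tolerance = 1e-8)
  expect_equal(fwd$report$tbar_l, rev$report$tbar_r)
  expect_equal(fwd$report$tbar_r, rev$report$tbar_l)
})

test_that("rigidly transforming both inputs rigidly transforms the cusp", {
  fx <- hinge_fixture(n_atoms = 10, angle = 20, seed = 10, gamma = 0.1)
  ts <- solve_transition_state(fx$model_a, fx$model_b, fx$a, fx$b, 5, 6)
  th <- 0.9
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, byrow = TRUE)
  shift <- c(4, -1, 2)
  move <- function(st) {
    st$coords <- st$coords %*% t(rot) + matrix(rep(shift, each = nrow(st$coords)), ncol = 3)
    st
  }
  a2 <- move(fx$a); b2 <- move(fx$b)
  ma2 <- eigendecompose(build_hessian(a2, gamma = 0.1))
  mb2 <- eigendecompose(build_hessian(b2, gamma = 0.1))
  ts2 <- solve_transition_state(ma2, mb2, a2, b2, 5, 6)
  moved_xbar <- as.vector(t(matrix(ts$xbar, ncol = 3, byrow = TRUE) %*% t(rot) +
                            matrix(rep(shift, each = 10), ncol = 3)))
  expect_equal(ts2$xbar, moved_xbar, tolerance = 1e-7)
})

test_that("the energy gap is invariant once the branch times are large", {
  # asymmetric diatomic: the non-rigid mode converges exponentially, so
  # doubling both branch times in the large-time regime leaves the energy
  # gap unchanged
  fx <- embedded_diatomic(3.0, 3.6, gamma_a = 0.8, gamma_b = 0.5)
  a <- as.vector(t(fx$a$coords)); b <- as.vector(t(fx$b$coords))
  de <- function(tl, tr) {
    ts <- solve_transition_state(fx$model_a, fx$model_b, a, b, tl, tr)
    delta_energy(ts, a, b, fx$model_a, fx$model_b)
  }
  d1 <- de(10, 10); d2 <- de(20, 20)
  expect_gt(abs(d1), 0)
  expect_lt(abs(d2 - d1) / abs(d1), 1e-3)
})

test_that("compute_path handles identical inputs and reports every stage", {
  pair <- make_two_state_pair(n_atoms = 8, mode = "hinge", angle = 0, seed = 1)
  expect_warning(res <- compute_path(pair$a, pair$b), "degenerate")
  expect_equal(res$transition_state$xbar, as.vector(t(pair$a$coords)),
               tolerance = 1e-8)
  expect_equal(res$report$delta_e, 0, tolerance = 1e-10)
  expect_true(all(c("kbar_a", "kbar_b", "tbar_l", "tbar_r", "delta_e",
                    "condition", "velocity_residual") %in% names(res$report)))
})
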