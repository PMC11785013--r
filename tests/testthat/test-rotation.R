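test_that("superposing a structure onto itself gives the identity", {
  s <- toy_fixture()$native
  fit <- kabsch_fit(s, s)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
})

test_that("a constructed rigid transform is recovered exactly", {
  set.seed(3)
  ref <- matrix(rnorm(60, sd = 4), 20, 3)
  R <- sbmotion:::rotation_about_axis(c(0, 0, 1), sbmotion:::rad(30))
  mob <- sweep(ref %*% t(solve(R)), 2, -c(1, 2, 3)) # inverse transform
  fit <- kabsch_fit(ref, mob)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  recovered <- sbmotion:::apply_fit(fit, mob)
  expect_equal(recovered, ref, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
})

test_that("noisy-fit rmsd matches an independent SVD implementation", {
  set.seed(12)
  ref <- matrix(rnorm(600, sd = 6), 200, 3)
  mob <- ref + matrix(rnorm(600, sd = 0.5), 200, 3)
  fit <- kabsch_fit(ref, mob)
  # bio3d as the independent oracle
  oracle <- bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(mob)),
                           fixed.inds = 1:600, mobile.inds = 1:600)
  oracle_rmsd <- sqrt(mean(rowSums((matrix(oracle, ncol = 3, byrow = TRUE) -
                                      ref)^2)))
  expect_equal(fit$rmsd, oracle_rmsd, tolerance = 1e-6)
  expect_lt(abs(fit$rmsd - 0.5 * sqrt(3 * (1 - 7 / 400))) / fit$rmsd, 0.1)
})

test_that("degenerate selections are rejected", {
  line <- cbind(1:10, 0, 0)
  expect_error(kabsch_fit(line, line), "collinear")
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)), "3 atoms")
})

test_that("Euler-Rodrigues axis/angle behaves at 0, generic and 180 degrees", {
  R0 <- diag(3)
  out <- er_axis_angle(R0, R0)
  expect_false(out$defined)
  expect_equal(out$angle_deg, 0)
  R45 <- sbmotion:::rotation_about_axis(c(0, 0, 1), sbmotion:::rad(45))
  out45 <- er_axis_angle(diag(3), R45)
  expect_equal(out45$angle_deg, 45, tolerance = 1e-9)
  expect_equal(abs(sum(out45$axis * c(0, 0, 1))), 1, tolerance = 1e-9)
  Rpi <- sbmotion:::rotation_about_axis(c(1, 0, 0), pi)
  outpi <- er_axis_angle(diag(3), Rpi)
  expect_equal(outpi$angle_deg, 180, tolerance = 1e-6)
  expect_equal(abs(outpi$axis[1]), 1, tolerance = 1e-6)
  expect_error(er_axis_angle(diag(3), matrix(2 * diag(3), 3, 3)),
               "proper rotation")
})

test_that("Z-Y-Z Euler decomposition round-trips 1000 random rotations", {
  set.seed(99)
  worst <- 0
  for (q in 1:1000) {
    R <- random_rotation()
    ang <- decompose_zyz(R)
    R2 <- euler_zyz(ang["phi"], ang["theta"], ang["psi"])
    worst <- max(worst, max(abs(R2 - R)))
    if (q <= 5) expect_true(ang["theta"] >= 0 && ang["theta"] <= pi)
  }
  expect_lt(worst, 1e-6)
})

test_that("constructed domain rotations are recovered exactly", {
  fix <- toy_fixture()
  s <- fix$native
  meta <- fix$meta
  er_axis <- c(0, 0, 1)
  one_frame_traj <- function(st) {
    frames <- array(0, c(1, nrow(st), 3))
    frames[1, , ] <- sbmotion:::coords(st)
    structure(list(frames = frames, config = sim_config(), seed = 1L),
              class = "sbm_trajectory")
  }
  # frame = reference: gamma = theta = 0 (theta inherits acos amplification
  # of the superposition roundoff, hence the 1e-6 degree tolerance)
  out0 <- rotation_tilt_timeseries(one_frame_traj(s), s, meta$body_selection,
                                   meta$domain_selection, er_axis)
  expect_lt(abs(out0$gamma), 1e-6)
  expect_lt(abs(out0$theta), 1e-6)
  # +10 degrees about the E-R axis: gamma = 10, theta = 0
  rot10 <- make_rotated_conformation(s, er_axis, 10)
  out10 <- rotation_tilt_timeseries(one_frame_traj(rot10), s,
                                    meta$body_selection,
                                    meta$domain_selection, er_axis)
  expect_lt(abs(out10$gamma - 10), 1e-6)
  expect_lt(abs(out10$theta), 1e-6)
  # 8 degrees about an axis orthogonal to the E-R axis: theta = 8, gamma = 0
  rot8 <- make_rotated_conformation(s, c(1, 0, 0), 8)
  out8 <- rotation_tilt_timeseries(one_frame_traj(rot8), s,
                                   meta$body_selection,
                                   meta$domain_selection, er_axis)
  expect_lt(abs(out8$theta - 8), 1e-6)
  expect_lt(abs(out8$gamma), 1e-6)
})

test_that("gamma and theta are invariant to a global rigid transform", {
  fix <- toy_fixture()
  s <- fix$native
  meta <- fix$meta
  rot <- make_rotated_conformation(s, c(0.6, 0.8, 0), 12)
  G <- sbmotion:::rotation_about_axis(c(1, 1, 2), 1.1)
  shift <- c(5, -3, 8)
  transform <- function(st) {
    sbmotion:::set_coords(st, sweep(sbmotion:::coords(st) %*% t(G), 2,
                                    shift, "+"))
  }
  traj_of <- function(st) {
    frames <- array(0, c(1, nrow(st), 3))
    frames[1, , ] <- sbmotion:::coords(st)
    structure(list(frames = frames, config = sim_config(), seed = 1L),
              class = "sbm_trajectory")
  }
  base <- rotation_tilt_timeseries(traj_of(rot), s, meta$body_selection,
                                   meta$domain_selection, c(0, 0, 1))
  moved <- rotation_tilt_timeseries(traj_of(transform(rot)), transform(s),
                                    meta$body_selection,
                                    meta$domain_selection,
                                    as.numeric(G %*% c(0, 0, 1)))
  expect_equal(moved$gamma, base$gamma, tolerance = 1e-8)
  expect_equal(moved$theta, base$theta, tolerance = 1e-8)
})

test_that("the E-R axis between constructed pre/post states is recovered", {
  fix <- toy_fixture()
  s <- fix$native
  meta <- fix$meta
  axis <- sbmotion:::unit(c(0.3, -0.5, 0.81))
  pre <- make_rotated_conformation(s, axis, 45)
  er <- er_axis_from_structures(s, pre, meta$body_selection,
                                meta$domain_selection)
  expect_true(er$defined)
  expect_equal(er$angle_deg, 45, tolerance = 1e-6)
  expect_equal(abs(sum(er$axis * axis)), 1, tolerance = 1e-9)
})
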