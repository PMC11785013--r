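frames_of <- function(...) {
  mats <- list(...)
  frames <- array(0, c(length(mats), nrow(mats[[1]]), 3))
  for (q in seq_along(mats)) frames[q, , ] <- mats[[q]]
  structure(list(frames = frames, config = sim_config(), seed = 1L),
            class = "sbm_trajectory")
}

test_that("a trajectory of reference copies has zero a.s.d. everywhere", {
  fix <- toy_fixture()
  xyz <- sbmotion:::coords(fix$native)
  traj <- frames_of(xyz, xyz, xyz)
  prof <- asd_per_residue(traj, fix$native, fix$meta$domain_selection)
  expect_true(all(prof$asd >= 0))
  expect_equal(prof$asd, rep(0, nrow(prof)), tolerance = 1e-10)
})

test_that("a residue displaced by exactly 2 A reports a.s.d. = 2", {
  fix <- toy_fixture()
  s <- fix$native
  meta <- fix$meta
  dom <- select_atoms(s, meta$domain_selection)
  moved_res <- max(s$resid[dom][s$chain[dom] == "A"])
  moved_atoms <- which(s$chain == "A" & s$resid == moved_res)
  # fit on the domain's other CA atoms so the alignment step is the identity
  fit_idx <- setdiff(dom[s$name[dom] == "CA"],
                     moved_atoms)
  xyz <- sbmotion:::coords(s)
  shifted <- xyz
  shifted[moved_atoms, 1] <- shifted[moved_atoms, 1] + 2
  # verify the alignment really is the identity on this fit selection
  fit <- kabsch_fit(xyz, shifted, fit_idx)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  traj <- frames_of(shifted, shifted)
  prof <- asd_per_residue(traj, s, meta$domain_selection,
                          fit_selection = fit_idx)
  expect_equal(prof$asd[prof$resid == moved_res & prof$chain == "A"], 2,
               tolerance = 1e-9)
  other <- prof$asd[!(prof$resid == moved_res & prof$chain == "A")]
  expect_equal(other, rep(0, length(other)), tolerance = 1e-9)
})

test_that("a.s.d. is invariant to rigid transforms of whole frames", {
  fix <- toy_fixture()
  set.seed(21)
  xyz <- sbmotion:::coords(fix$native)
  f1 <- xyz + matrix(rnorm(length(xyz), sd = 0.3), ncol = 3)
  G <- sbmotion:::rotation_about_axis(c(1, 0, 1), 0.8)
  f1_moved <- sweep(f1 %*% t(G), 2, c(3, 3, -2), "+")
  p1 <- asd_per_residue(frames_of(f1), fix$native, fix$meta$domain_selection)
  p2 <- asd_per_residue(frames_of(f1_moved), fix$native,
                        fix$meta$domain_selection)
  expect_equal(p2$asd, p1$asd, tolerance = 1e-8)
})

test_that("restraining the cofactor increases hinge-region deformation", {
  fix <- toy_fixture()
  ff <- add_distance_restraint(fix$ff_masked, fix$meta$ligand_index,
                               fix$meta$target_index, 5, 1.5)
  mk <- function(seed, restrained) {
    run_langevin(ff, sim_config(temperature = 0.5, friction = 1,
                                n_steps = 40000L, save_interval = 200L,
                                seed = seed,
                                restraints_active = restrained))
  }
  asd_of <- function(traj) {
    asd_per_residue(traj, fix$with_tail, fix$meta$mobile_selection)
  }
  # paired comparison over matched seeds; sign test on the hinge residue
  hinge <- min(fix$meta$hinge_resids)
  wins <- 0
  seeds <- c(301L, 302L, 303L)
  for (sd in seeds) {
    a_r <- asd_of(mk(sd, TRUE))
    a_u <- asd_of(mk(sd + 1000L, FALSE))
    h_r <- a_r$asd[a_r$resid == hinge]
    h_u <- a_u$asd[a_u$resid == hinge]
    if (h_r > h_u) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("uniform tilt samples give a flat free-energy profile", {
  set.seed(8)
  n <- 200000
  theta <- runif(n, 0, 20)
  prof <- free_energy_vs_tilt(theta, temperature = 0.5, bin_width = 1)
  filled <- prof[!is.na(prof$free_energy_kT) & prof$count > 0 &
                   prof$theta_mid < 20, ]
  expect_equal(min(prof$free_energy_kT, na.rm = TRUE), 0)
  # -log p per bin, measured against the exact flat level log(20): each
  # deviation is multinomial noise of sd sqrt((1-p)/(n p))
  p <- 1 / 20
  fluct <- sqrt((1 - p) / (n * p))
  dev <- (-log(filled$count / sum(filled$count))) - log(20)
  expect_lt(max(abs(dev)), 3.5 * fluct)
})

test_that("Boltzmann inversion recovers the curvature of a Gaussian tilt", {
  set.seed(17)
  sigma <- 3
  theta <- abs(rnorm(1e5, 0, sigma)) # folded at zero
  temperature <- 0.5
  prof <- free_energy_vs_tilt(theta, temperature, bin_width = 0.5)
  use <- prof[!is.na(prof$free_energy_kT) & prof$theta_mid < 2.5 * sigma, ]
  fit <- stats::lm(free_energy_kT ~ I(theta_mid^2), data = use,
                   weights = use$count)
  curv_kt <- 2 * unname(stats::coef(fit)[2]) # d2F/dtheta2 in kT
  expect_lt(abs(curv_kt - 1 / sigma^2) / (1 / sigma^2), 0.10)
  # in energy units the curvature is T/sigma^2
  curv_eps <- curv_kt * temperature
  expect_lt(abs(curv_eps - temperature / sigma^2) / (temperature / sigma^2),
            0.10)
})

test_that("free-energy profiles are invariant under sample duplication", {
  set.seed(5)
  theta <- abs(rnorm(5000, 0, 4))
  p1 <- free_energy_vs_tilt(theta, 0.5)
  p2 <- free_energy_vs_tilt(c(theta, theta), 0.5)
  expect_equal(p2$free_energy_kT, p1$free_energy_kT, tolerance = 1e-12)
  # empty bins are NA, not zero
  gappy <- free_energy_vs_tilt(c(0.5, 0.6, 5.5), 0.5, bin_width = 1)
  expect_true(is.na(gappy$free_energy_kT[gappy$theta_mid == 3.5]))
  expect_warning(free_energy_vs_tilt(c(1.1, 1.2), 0.5, bin_width = 5),
                 "single bin")
  expect_error(free_energy_vs_tilt(numeric(0), 0.5), "sample")
})

test_that("the Jacobian flag divides the density by sin(theta)", {
  set.seed(30)
  theta <- runif(5e4, 1, 19)
  plain <- free_energy_vs_tilt(theta, temperature = 1, bin_width = 2)
  jac <- free_energy_vs_tilt(theta, temperature = 1, bin_width = 2,
                             jacobian = TRUE)
  filled <- plain$count > 0
  delta <- (jac$free_energy_kT - plain$free_energy_kT)[filled]
  # the correction shifts F by +log sin(theta) plus a min-zero constant
  resid <- delta - log(sin(sbmotion:::rad(plain$theta_mid)))[filled]
  expect_lt(diff(range(resid)), 1e-9)
})
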