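contact_min_factor <- 0.96^12 - 2 * 0.96^6 # depth of a contact at its
                                           # native distance (~ -0.9528)

test_that("native-state energy is the closed-form contact sum", {
  ff <- toy_fixture()$ff
  pe <- potential_energy(ff)
  expect_equal(unname(pe$breakdown[c("bonds", "angles", "impropers",
                                     "planars", "dihedrals")]),
               rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(pe$breakdown["noncontacts"]), 0, tolerance = 1e-12)
  expected <- contact_min_factor * sum(ff$contacts$weight)
  expect_equal(pe$energy, expected, tolerance = 1e-6)
  expect_equal(sum(pe$breakdown), pe$energy, tolerance = 1e-12)
})

test_that("each contact has its minimum at sigma with depth -eps_c", {
  ff <- empty_forcefield(2)
  ff$contacts <- tibble::tibble(i = 1L, j = 2L, r0 = 3, sigma = 2.88,
                                weight = 1.7)
  at <- function(r) potential_energy(
    ff, rbind(c(0, 0, 0), c(r, 0, 0)))$energy
  expect_equal(at(2.88), -1.7, tolerance = 1e-12)
  # derivative changes sign across sigma
  h <- 1e-4
  expect_lt(at(2.88) , at(2.88 - h))
  expect_lt(at(2.88), at(2.88 + h))
  # native distance evaluates to the 0.96-scaled closed form
  expect_equal(at(3), 1.7 * contact_min_factor, tolerance = 1e-12)
})

test_that("a dihedral displaced by pi contributes 3x its weight", {
  ff <- empty_forcefield(4)
  ff$exclusions <- t(utils::combn(1:4, 2))
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.4, 0), c(1.6, 2, 1.2))
  phi0 <- sbmotion:::dihedral4(xyz, 1, 2, 3, 4)
  ff$dihedrals <- tibble::tibble(i = 1L, j = 2L, k = 3L, l = 4L,
                                 phi0 = phi0, class = "backbone",
                                 weight = 0.8)
  # at the native torsion the term vanishes
  expect_equal(potential_energy(ff, xyz)$energy, 0, tolerance = 1e-12)
  # rotate atom 4 about the j-k bond axis by pi
  axis <- sbmotion:::unit(xyz[3, ] - xyz[2, ])
  R <- sbmotion:::rotation_about_axis(axis, pi)
  xyz2 <- xyz
  xyz2[4, ] <- as.numeric(R %*% (xyz[4, ] - xyz[3, ])) + xyz[3, ]
  # F(pi) = (1 - cos pi) + (1 - cos 3pi)/2 = 3
  expect_equal(potential_energy(ff, xyz2)$energy, 3 * 0.8,
               tolerance = 1e-9)
})

test_that("non-contact pairs follow the truncated-shifted repulsion", {
  ff <- empty_forcefield(2)
  sc <- ff$scales
  at <- function(r) potential_energy(ff, rbind(c(0, 0, 0), c(r, 0, 0)))$energy
  shift <- sc$eps_nc * (sc$sigma_nc / sc$nc_cutoff)^12
  # at r = sigma_nc the pair energy is eps_nc up to the truncation shift
  expect_equal(at(2.5), sc$eps_nc - shift, tolerance = 1e-12)
  expect_lt(shift, 2e-3)
  expect_equal(at(3.6), 0) # beyond the truncation radius
})

test_that("overlapping atoms in pair terms raise an error naming the term", {
  ff <- empty_forcefield(2)
  ff$bonds <- tibble::tibble(i = 1L, j = 2L, r0 = 1.5, weight = 100)
  expect_error(potential_energy(ff, matrix(0, 2, 3)), "overlapping")
  expect_error(potential_energy(toy_fixture()$ff,
                                matrix(NaN, nrow(toy_fixture()$ff$structure),
                                       3)),
               "non-finite")
})

test_that("analytic forces match finite differences for every term type", {
  set.seed(11)
  xyz4 <- matrix(rnorm(12, sd = 2), 4, 3)
  term_ffs <- list(
    bond = {
      f <- empty_forcefield(4); f$exclusions <- t(utils::combn(1:4, 2))
      f$bonds <- tibble::tibble(i = 1L, j = 2L, r0 = 1.5, weight = 100); f
    },
    angle = {
      f <- empty_forcefield(4); f$exclusions <- t(utils::combn(1:4, 2))
      f$angles <- tibble::tibble(i = 1L, j = 2L, k = 3L, theta0 = 1.8,
                                 weight = 80); f
    },
    improper = {
      f <- empty_forcefield(4); f$exclusions <- t(utils::combn(1:4, 2))
      f$impropers <- tibble::tibble(i = 1L, j = 2L, k = 3L, l = 4L,
                                    chi0 = 0.4, weight = 10); f
    },
    planar = {
      f <- empty_forcefield(4); f$exclusions <- t(utils::combn(1:4, 2))
      f$planars <- tibble::tibble(i = 1L, j = 2L, k = 3L, l = 4L,
                                  weight = 40); f
    },
    dihedral = {
      f <- empty_forcefield(4); f$exclusions <- t(utils::combn(1:4, 2))
      f$dihedrals <- tibble::tibble(i = 1L, j = 2L, k = 3L, l = 4L,
                                    phi0 = 0.7, class = "backbone",
                                    weight = 1.3); f
    },
    contact = {
      f <- empty_forcefield(4); f$exclusions <- t(utils::combn(1:4, 2))
      f$contacts <- tibble::tibble(i = 1L, j = 2L, r0 = 3, sigma = 2.88,
                                   weight = 1); f
    },
    noncontact = empty_forcefield(4),
    restraint = {
      f <- empty_forcefield(4); f$exclusions <- t(utils::combn(1:4, 2))
      f$restraints <- tibble::tibble(i = 1L, j = 3L, r_min = 5, k = 1.5); f
    }
  )
  for (nm in names(term_ffs)) {
    ff <- term_ffs[[nm]]
    for (rep in 1:5) {
      xyz <- matrix(rnorm(12, sd = 2), 4, 3)
      pe <- potential_energy(ff, xyz)
      for (i in 1:4) {
        for (d in 1:3) {
          fd <- fd_force(ff, xyz, i, d)
          scale <- max(1, abs(fd))
          expect_lt(abs(fd - pe$forces[i, d]) / scale, 1e-5,
                    label = paste("term", nm))
        }
      }
    }
  }
})

test_that("forces on the full toy system match finite differences", {
  fix <- toy_fixture()
  ff <- add_distance_restraint(fix$ff_masked, fix$meta$ligand_index,
                               fix$meta$target_index, 5, 1.5)
  set.seed(4)
  xyz <- sbmotion:::coords(ff$structure) +
    matrix(rnorm(nrow(ff$structure) * 3, sd = 0.08), ncol = 3)
  pe <- potential_energy(ff, xyz)
  for (q in 1:40) {
    i <- sample(nrow(xyz), 1)
    d <- sample(3, 1)
    fd <- fd_force(ff, xyz, i, d)
    expect_lt(abs(fd - pe$forces[i, d]) / max(1, abs(fd)), 1e-5)
  }
})

test_that("restraints add their term without altering the others", {
  fix <- toy_fixture()
  ff0 <- fix$ff
  ff1 <- add_distance_restraint(ff0, fix$meta$ligand_index,
                                fix$meta$target_index, 5, 1.5)
  set.seed(5)
  xyz <- sbmotion:::coords(ff0$structure) +
    matrix(rnorm(nrow(ff0$structure) * 3, sd = 0.05), ncol = 3)
  b0 <- potential_energy(ff0, xyz)$breakdown
  b1 <- potential_energy(ff1, xyz)$breakdown
  other <- setdiff(names(b0), "restraints")
  expect_equal(b1[other], b0[other], tolerance = 1e-14)
  # restraint energy: (k/2) (r - r_min)^2, zero at the minimum
  r <- sqrt(sum((xyz[fix$meta$ligand_index, ] -
                   xyz[fix$meta$target_index, ])^2))
  expect_equal(unname(b1["restraints"]), 0.75 * (r - 5)^2, tolerance = 1e-10)
  # k = 1.5 eps/A^2 at r = 7 gives exactly 3 eps
  ffp <- empty_forcefield(2)
  ffp$restraints <- tibble::tibble(i = 1L, j = 2L, r_min = 5, k = 1.5)
  expect_equal(potential_energy(ffp, rbind(c(0, 0, 0), c(7, 0, 0)),
                                restraints_active = TRUE)$energy,
               3, tolerance = 1e-12)
  # k = 0 leaves energy and forces unchanged
  ffz <- add_distance_restraint(ff0, 1, 40, r_min = 5, k = 0)
  p0 <- potential_energy(ff0, xyz)
  pz <- potential_energy(ffz, xyz)
  expect_equal(pz$energy, p0$energy, tolerance = 1e-14)
  expect_equal(pz$forces, p0$forces, tolerance = 1e-14)
})
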