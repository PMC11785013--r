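# An alanine dipeptide built from the toy chain geometry: drop the CG atom
# of ALX residues and relabel, leaving exactly the ALA heavy-atom set.
ala_dipeptide <- function() {
  fix <- toy_fixture()
  s <- fix$native[fix$native$chain == "A" & fix$native$resid %in% 1:2 &
                    fix$native$name != "CG", ]
  s$resname <- "ALA"
  new_structure(tibble::as_tibble(s))
}

test_that("alanine dipeptide term counts match the template tables", {
  bt <- extract_bonded_terms(ala_dipeptide())
  # bonds: 4 intra per residue + 1 peptide link
  expect_equal(nrow(bt$bonds), 9L)
  # angles derived from the bond graph: CA1(3) C1(3) N2(1) CA2(3) C2(1)
  expect_equal(nrow(bt$angles), 11L)
  # impropers: CA chirality x2 + carbonyl of residue 1 (residue 2 lacks +N)
  expect_equal(nrow(bt$impropers), 3L)
  # one peptide planar group
  expect_equal(nrow(bt$planars), 1L)
  # propers: psi of residue 1 and phi of residue 2
  expect_equal(nrow(bt$dihedrals), 2L)
  expect_true(all(bt$dihedrals$class == "backbone"))
  # standard residues take bond values from the bundled reference table
  expect_true(all(bt$bonds$source == "table"))
})

test_that("dihedral equilibria equal the values measured in the input", {
  fix <- toy_fixture()
  bt <- extract_bonded_terms(fix$native)
  xyz <- sbmotion:::coords(fix$native)
  for (q in sample(nrow(bt$dihedrals), 10)) {
    measured <- sbmotion:::dihedral4(xyz, bt$dihedrals$i[q], bt$dihedrals$j[q],
                                     bt$dihedrals$k[q], bt$dihedrals$l[q])
    expect_equal(bt$dihedrals$phi0[q], measured, tolerance = 1e-6)
  }
})

test_that("a chain break leaves no bond spanning the gap", {
  fix <- toy_fixture()
  s <- fix$native[!(fix$native$chain == "A" & fix$native$resid == 10), ]
  s <- new_structure(tibble::as_tibble(s))
  bt <- extract_bonded_terms(s)
  r9_c <- which(s$chain == "A" & s$resid == 9 & s$name == "C")
  r11_n <- which(s$chain == "A" & s$resid == 11 & s$name == "N")
  spanning <- (bt$bonds$i == r9_c & bt$bonds$j == r11_n) |
    (bt$bonds$i == r11_n & bt$bonds$j == r9_c)
  expect_false(any(spanning))
})

test_that("untemplated residues produce a hard error naming them", {
  fix <- toy_fixture()
  s <- fix$native
  s$resname[s$resid == 3 & s$chain == "A"] <- "XYZ"
  expect_error(extract_bonded_terms(new_structure(tibble::as_tibble(s))),
               "XYZ")
})

test_that("energy-scale normalization solves the three constraints", {
  # 100 atoms, 40 contacts, 20 backbone + 10 sidechain dihedrals:
  # contact total = 200/3, eps_bb = 4/3, eps_sc = 2/3 (solved by hand)
  n <- 100L
  s <- new_structure(tibble::tibble(
    name = "C", resname = "UNK", chain = "A", resid = seq_len(n),
    x = seq_len(n) * 4, y = 0, z = 0
  ))
  bonded <- list(
    bonds = tibble::tibble(i = 1L, j = 2L, r0 = 4, source = "measured"),
    angles = tibble::tibble(i = integer(0), j = integer(0), k = integer(0),
                            theta0 = numeric(0), source = character(0)),
    impropers = tibble::tibble(i = integer(0), j = integer(0),
                               k = integer(0), l = integer(0),
                               chi0 = numeric(0)),
    planars = tibble::tibble(i = integer(0), j = integer(0), k = integer(0),
                             l = integer(0)),
    dihedrals = tibble::tibble(i = 1:30, j = 2:31, k = 3:32, l = 4:33,
                               phi0 = 0,
                               class = rep(c("backbone", "sidechain"),
                                           c(20, 10))),
    log = list()
  )
  contacts <- tibble::tibble(i = seq_len(40), j = seq_len(40) + 41L, r0 = 5)
  ff <- assign_energy_scales(s, bonded, contacts)
  expect_equal(sum(ff$contacts$weight), 200 / 3, tolerance = 1e-12)
  expect_equal(unique(ff$dihedrals$weight[ff$dihedrals$class == "backbone"]),
               4 / 3, tolerance = 1e-12)
  expect_equal(unique(ff$dihedrals$weight[ff$dihedrals$class == "sidechain"]),
               2 / 3, tolerance = 1e-12)
  # enforced identities
  expect_equal(sum(ff$contacts$weight) / sum(ff$dihedrals$weight), 2)
  expect_equal(sum(ff$contacts$weight) + sum(ff$dihedrals$weight), n)
  # doubling the atom count doubles every stabilizing weight
  s2 <- new_structure(tibble::tibble(
    name = "C", resname = "UNK", chain = "A", resid = seq_len(2 * n),
    x = seq_len(2 * n) * 4, y = 0, z = 0
  ))
  ff2 <- assign_energy_scales(s2, bonded, contacts)
  expect_equal(ff2$contacts$weight, 2 * ff$contacts$weight)
  expect_equal(ff2$dihedrals$weight, 2 * ff$dihedrals$weight)
  # degenerate inputs are rejected
  expect_error(assign_energy_scales(s, bonded, contacts[0, ]),
               "normalization")
})

test_that("fixed weights carry the standard printed values", {
  sc <- default_scales()
  expect_equal(sc$eps_r, 100)
  expect_equal(sc$eps_theta, 80)
  expect_equal(sc$eps_imp, 10)
  expect_equal(sc$eps_planar, 40)
  expect_equal(sc$eps_nc, 0.1)
  expect_equal(sc$sigma_nc, 2.5)
  expect_equal(sc$contact_sigma_scale, 0.96)
})

test_that("contact sigma is 0.96 times the native distance", {
  ff <- toy_fixture()$ff
  expect_equal(ff$contacts$sigma, 0.96 * ff$contacts$r0)
  expect_true(all(ff$contacts$r0 <= 6))
})

# connected components of the tail bond graph, counted by union-find
count_components <- function(nodes, bonds) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (q in seq_len(nrow(bonds))) {
    a <- find(bonds$i[q]); b <- find(bonds$j[q])
    if (a != b) parent[[as.character(a)]] <- b
  }
  length(unique(vapply(nodes, find, numeric(1))))
}

test_that("disorder masking removes exactly the touching contacts/dihedrals", {
  fix <- toy_fixture()
  ff <- fix$ff
  spec <- fix$disorder
  midx <- which(ff$structure$chain == "B")
  # brute-force count of terms touching masked residues
  c_expect <- sum(ff$contacts$i %in% midx | ff$contacts$j %in% midx)
  d_expect <- sum(ff$dihedrals$i %in% midx | ff$dihedrals$j %in% midx |
                    ff$dihedrals$k %in% midx | ff$dihedrals$l %in% midx)
  expect_gt(c_expect, 0)
  masked <- fix$ff_masked
  expect_equal(nrow(ff$contacts) - nrow(masked$contacts), c_expect)
  expect_equal(nrow(ff$dihedrals) - nrow(masked$dihedrals), d_expect)
  # no surviving term touches a masked residue
  expect_false(any(masked$contacts$i %in% midx | masked$contacts$j %in% midx))
  # bonds, angles, impropers, planars retained
  expect_equal(masked$bonds, ff$bonds)
  expect_equal(masked$angles, ff$angles)
  expect_equal(nrow(masked$impropers), nrow(ff$impropers))
  expect_equal(nrow(masked$planars), nrow(ff$planars))
  # chain-B bond graph still spans the tail
  tail_bonds <- masked$bonds[masked$bonds$i %in% midx &
                               masked$bonds$j %in% midx, ]
  g <- count_components(midx, tail_bonds)
  expect_equal(g, 1L)
})

test_that("empty disorder specification leaves the force field unchanged", {
  ff <- toy_fixture()$ff
  ff2 <- apply_disorder_mask(ff, NULL)
  expect_identical(ff2$contacts, ff$contacts)
  expect_identical(ff2$dihedrals, ff$dihedrals)
  expect_error(
    apply_disorder_mask(ff, tibble::tibble(chain = "Q", start = 1, end = 5)),
    "zero residues")
})

test_that("distance restraints validate their atoms and accumulate", {
  ff <- toy_fixture()$ff
  expect_error(add_distance_restraint(ff, 5, 5), "distinct")
  expect_error(add_distance_restraint(ff, 1, 10 * nrow(ff$structure)),
               "range")
  ff2 <- add_distance_restraint(ff, 1, 50, r_min = 5, k = 1.5)
  expect_equal(nrow(ff2$restraints), 1L)
  expect_equal(ff2$restraints$k, 1.5)
})

test_that("reference geometry is a stationary point of the measured terms", {
  expect_lt(validate_forcefield(toy_fixture()$ff), 1e-8)
})
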