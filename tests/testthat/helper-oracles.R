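# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# O(N^3) brute-force Shadow Contact Map: triple loop over every candidate
# pair and every possible occluder, applying the same geometric predicate
# by direct computation.
brute_force_shadow_map <- function(xyz, resid, cutoff = 6, shadow_radius = 1,
                                   excluded_keys = character(0)) {
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > cutoff) next
      if (resid[i] == resid[j]) next
      if (paste(i, j, sep = "-") %in% excluded_keys) next
      shadowed <- FALSE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        ab <- xyz[j, ] - xyz[i, ]
        tt <- sum((xyz[k, ] - xyz[i, ]) * ab) / sum(ab^2)
        if (tt <= 0 || tt >= 1) next
        closest <- xyz[i, ] + tt * ab
        if (sqrt(sum((xyz[k, ] - closest)^2)) < shadow_radius) {
          shadowed <- TRUE
          break
        }
      }
      if (!shadowed) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

# Expected mean and variance of the pair distance r for a 3-D pair bound by
# U(r) = (k/2) (r - r0)^2 at temperature T: quadrature over the radial
# Boltzmann density p(r) proportional to r^2 exp(-U/T).
radial_boltzmann_moments <- function(k, r0, temperature) {
  f <- function(r) r^2 * exp(-(k / 2) * (r - r0)^2 / temperature)
  lo <- max(0, r0 - 12 * sqrt(temperature / k))
  hi <- r0 + 12 * sqrt(temperature / k)
  z <- stats::integrate(f, lo, hi)$value
  m1 <- stats::integrate(function(r) r * f(r), lo, hi)$value / z
  m2 <- stats::integrate(function(r) r^2 * f(r), lo, hi)$value / z
  list(mean = m1, var = m2 - m1^2)
}

# Random clash-free atom cloud for shadow-map comparisons; resid groups of
# three atoms so same-residue exclusion is exercised.
random_configuration <- function(n_atoms, box = 12) {
  repeat {
    xyz <- matrix(runif(n_atoms * 3, 0, box), n_atoms, 3)
    dmin <- min(dist(xyz))
    if (dmin > 0.8) return(xyz)
  }
}

# Minimal force field with no terms, for term-by-term engine checks.
empty_forcefield <- function(n) {
  s <- new_structure(tibble::tibble(
    name = paste0("X", seq_len(n)), resname = "ALX", chain = "A",
    resid = seq_len(n), x = 0, y = 0, z = 0
  ))
  structure(list(
    structure = s,
    bonds = tibble::tibble(i = integer(0), j = integer(0), r0 = numeric(0),
                           weight = numeric(0)),
    angles = tibble::tibble(i = integer(0), j = integer(0), k = integer(0),
                            theta0 = numeric(0), weight = numeric(0)),
    impropers = tibble::tibble(i = integer(0), j = integer(0),
                               k = integer(0), l = integer(0),
                               chi0 = numeric(0), weight = numeric(0)),
    planars = tibble::tibble(i = integer(0), j = integer(0), k = integer(0),
                             l = integer(0), weight = numeric(0)),
    dihedrals = tibble::tibble(i = integer(0), j = integer(0),
                               k = integer(0), l = integer(0),
                               phi0 = numeric(0), class = character(0),
                               weight = numeric(0)),
    contacts = tibble::tibble(i = integer(0), j = integer(0),
                              r0 = numeric(0), sigma = numeric(0),
                              weight = numeric(0)),
    restraints = tibble::tibble(i = integer(0), j = integer(0),
                                r_min = numeric(0), k = numeric(0)),
    exclusions = matrix(integer(0), 0, 2),
    scales = c(default_scales(), list(eps_bb = 1, eps_sc = 0.5, eps_c = 1)),
    provenance = list(hash = "empty"),
    log = list()
  ), class = "sbm_forcefield")
}

# Random proper rotation matrix.
random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  sbmotion:::rotation_about_axis(ax, runif(1, 0, pi))
}

# Central finite-difference force on one coordinate.
fd_force <- function(ff, xyz, i, d, h = 1e-5) {
  xp <- xyz; xp[i, d] <- xp[i, d] + h
  xm <- xyz; xm[i, d] <- xm[i, d] - h
  -(potential_energy(ff, xp)$energy - potential_energy(ff, xm)$energy) / (2 * h)
}
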