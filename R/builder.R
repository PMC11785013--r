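#' @title Single-basin structure-based force field
#' @description
#' The force field treats a chosen experimental (or synthetic) structure as
#' the global potential-energy minimum. Bonds, angles and impropers are
#' harmonic; designated planar groups carry a `1 - cos(2 chi)` term; proper
#' dihedrals carry `F(phi - phi0)` with
#' `F(phi) = (1 - cos phi) + (1 - cos 3 phi)/2`; native contacts (Shadow
#' Contact Map) carry a 6-12 well with `sigma_ij = 0.96 x` the native
#' distance; all remaining pairs are purely repulsive with `sigma_nc = 2.5`
#' Angstrom. Energies are in reduced units of epsilon, lengths in Angstrom.
#' @name sbm_forcefield
NULL

#' Fixed energy-scale weights (reduced units)
#'
#' Bond 100 eps/A^2, angle 80 eps/rad^2, improper 10 eps/rad^2, planar
#' 40 eps, non-contact 0.1 eps with sigma 2.5 A (repulsion truncated and
#' shifted at `nc_cutoff`), and contact sigma scaling 0.96.
#'
#' @return Named list of weights.
#' @export
default_scales <- function() {
  list(eps_r = 100,      # bond, eps/A^2
       eps_theta = 80,   # angle, eps/rad^2
       eps_imp = 10,     # improper, eps/rad^2
       eps_planar = 40,  # planar, eps
       eps_nc = 0.1,     # non-contact repulsion, eps
       sigma_nc = 2.5,   # non-contact size, A
       nc_cutoff = 3.5,  # repulsion truncation, A
       contact_sigma_scale = 0.96)
}

# ---- geometry helpers ------------------------------------------------------

dist3 <- function(xyz, i, j) vnorm(xyz[i, ] - xyz[j, ])

angle3 <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]
  v <- xyz[k, ] - xyz[j, ]
  acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v)))))
}

dihedral4 <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  atan2(sum(cross3(n1, n2) * b2) / vnorm(b2), sum(n1 * n2))
}

# ---- residue bookkeeping ---------------------------------------------------

residue_table <- function(structure) {
  key <- paste(structure$chain, structure$resid, structure$insert, sep = "|")
  first <- !duplicated(key)
  tibble::tibble(
    key = key[first],
    chain = structure$chain[first],
    resid = structure$resid[first],
    insert = structure$insert[first],
    resname = structure$resname[first]
  )
}

# ---- bonded terms ----------------------------------------------------------

#' Extract bonded terms from a structure using residue templates
#'
#' Bond and angle equilibrium values come from a bundled reference table for
#' standard residues; any pair or triple absent from the table uses the value
#' measured in the input coordinates (counted in the returned log). Dihedral
#' and improper equilibria are always measured from the input. Every proper
#' dihedral is classified `backbone` (all four atoms in the backbone
#' atom-name set) or `sidechain`. Angles are derived from the bond graph.
#' Single-atom ligand residues are attached by harmonic bonds to their (up
#' to two) nearest atoms within 3.5 Angstrom.
#'
#' @param structure A structure tibble.
#' @param templates Template registry, see [residue_templates()].
#' @return List with tibbles `bonds`, `angles`, `impropers`, `planars`,
#'   `dihedrals`, plus a `log` list (skipped terms, measured fallbacks).
#' @export
extract_bonded_terms <- function(structure, templates = residue_templates()) {
  xyz <- coords(structure)
  res <- residue_table(structure)
  untemplated <- setdiff(unique(res$resname), names(templates))
  if (length(untemplated) > 0) {
    abort(paste0("no residue template for: ",
                 paste(untemplated, collapse = ", ")))
  }
  atom_key <- paste(structure$chain, structure$resid, structure$insert,
                    structure$name, sep = "|")
  atom_lookup <- setNames(seq_len(nrow(structure)), atom_key)
  res_key_set <- setNames(seq_len(nrow(res)), res$key)

  missing_atoms <- character(0)
  # resolve a template-relative atom name for residue row r; NA if absent
  resolve <- function(r, name) {
    offset <- 0L
    nm <- name
    if (startsWith(name, "+")) { offset <- 1L; nm <- substring(name, 2) }
    if (startsWith(name, "-")) { offset <- -1L; nm <- substring(name, 2) }
    rid <- res$resid[r] + offset
    rkey <- paste(res$chain[r], rid, "", sep = "|")
    if (offset != 0L && !(rkey %in% names(res_key_set))) return(NA_integer_)
    akey <- paste(res$chain[r], rid, res$insert[r], nm, sep = "|")
    idx <- atom_lookup[akey]
    if (is.na(idx)) missing_atoms <<- c(missing_atoms, akey)
    unname(idx)
  }

  bond_tab <- reference_bond_table()
  bond_lookup <- setNames(bond_tab$r0,
                          paste(bond_tab$resname, bond_tab$a1, bond_tab$a2))
  angle_tab <- reference_angle_table()
  angle_lookup <- setNames(rad(angle_tab$theta0_deg),
                           paste(angle_tab$resname, angle_tab$a1,
                                 angle_tab$a2, angle_tab$a3))

  bi <- bj <- integer(0); br0 <- numeric(0); bsrc <- character(0)
  add_bond <- function(i, j, resname, n1, n2) {
    if (is.na(i) || is.na(j)) return(invisible())
    v <- bond_lookup[paste(resname, n1, n2)]
    if (is.na(v)) v <- bond_lookup[paste(resname, n2, n1)]
    src <- if (is.na(v)) "measured" else "table"
    if (is.na(v)) v <- dist3(xyz, i, j)
    bi <<- c(bi, min(i, j)); bj <<- c(bj, max(i, j))
    br0 <<- c(br0, v); bsrc <<- c(bsrc, src)
    invisible()
  }

  imp <- list(); pla <- list(); dih <- list()
  for (r in seq_len(nrow(res))) {
    t <- templates[[res$resname[r]]]
    if (nrow(t$bonds) > 0) {
      for (b in seq_len(nrow(t$bonds))) {
        n1 <- t$bonds[b, 1]; n2 <- t$bonds[b, 2]
        add_bond(resolve(r, n1), resolve(r, n2), res$resname[r], n1, n2)
      }
    }
    for (q in t$impropers) {
      idx <- vapply(q, resolve, integer(1), r = r)
      if (!anyNA(idx)) imp[[length(imp) + 1]] <- idx
    }
    for (q in t$planars) {
      idx <- vapply(q, resolve, integer(1), r = r)
      if (!anyNA(idx)) pla[[length(pla) + 1]] <- idx
    }
    for (q in t$propers) {
      idx <- vapply(q, resolve, integer(1), r = r)
      if (!anyNA(idx)) dih[[length(dih) + 1]] <- idx
    }
    # single-atom ligands: harmonic attachment to nearest atoms
    if (identical(t$kind, "ligand") && length(t$atoms) == 1) {
      i <- resolve(r, t$atoms[1])
      if (!is.na(i)) {
        d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
        d[i] <- Inf
        near <- order(d)[1:2]
        near <- near[d[near] <= 3.5]
        for (j in near) add_bond(i, j, res$resname[r], "*", "*")
      }
    }
  }

  bonds <- tibble::tibble(i = bi, j = bj, r0 = br0, source = bsrc)
  bonds <- bonds[!duplicated(pair_key(bonds$i, bonds$j)), ]

  # angles from the bond graph
  adj <- vector("list", nrow(structure))
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
  }
  ai <- aj <- ak <- integer(0); ath <- numeric(0); asrc <- character(0)
  rel_name <- function(center, other) {
    if (structure$chain[center] != structure$chain[other])
      return(structure$name[other]) # cross-chain: plain name, no table hit
    off <- structure$resid[other] - structure$resid[center]
    pre <- if (off == 1) "+" else if (off == -1) "-" else if (off == 0) "" else "?"
    paste0(pre, structure$name[other])
  }
  for (jc in seq_len(nrow(structure))) {
    nb <- sort(unique(adj[[jc]]))
    if (length(nb) < 2) next
    for (a in seq_along(nb)[-length(nb)]) {
      for (b in (a + 1):length(nb)) {
        i <- nb[a]; k <- nb[b]
        rn <- structure$resname[jc]
        n1 <- rel_name(jc, i); n3 <- rel_name(jc, k)
        v <- angle_lookup[paste(rn, n1, structure$name[jc], n3)]
        if (is.na(v)) v <- angle_lookup[paste(rn, n3, structure$name[jc], n1)]
        src <- if (is.na(v)) "measured" else "table"
        if (is.na(v)) v <- angle3(xyz, i, jc, k)
        ai <- c(ai, i); aj <- c(aj, jc); ak <- c(ak, k)
        ath <- c(ath, unname(v)); asrc <- c(asrc, src)
      }
    }
  }
  angles <- tibble::tibble(i = ai, j = aj, k = ak, theta0 = ath, source = asrc)

  quad_tbl <- function(lst, measure = TRUE) {
    if (length(lst) == 0) {
      return(tibble::tibble(i = integer(0), j = integer(0), k = integer(0),
                            l = integer(0), x0 = numeric(0)))
    }
    m <- do.call(rbind, lst)
    x0 <- if (measure) {
      vapply(seq_len(nrow(m)),
             function(q) dihedral4(xyz, m[q, 1], m[q, 2], m[q, 3], m[q, 4]),
             numeric(1))
    } else rep(NA_real_, nrow(m))
    tibble::tibble(i = m[, 1], j = m[, 2], k = m[, 3], l = m[, 4], x0 = x0)
  }
  impropers <- quad_tbl(imp)
  names(impropers)[5] <- "chi0"
  planars <- quad_tbl(pla, measure = FALSE)[, 1:4]
  dihedrals <- quad_tbl(dih)
  names(dihedrals)[5] <- "phi0"
  bb <- backbone_atom_names()
  dihedrals$class <- vapply(seq_len(nrow(dihedrals)), function(q) {
    nm <- structure$name[c(dihedrals$i[q], dihedrals$j[q],
                           dihedrals$k[q], dihedrals$l[q])]
    if (all(nm %in% bb)) "backbone" else "sidechain"
  }, character(1))

  list(bonds = bonds, angles = angles, impropers = impropers,
       planars = planars, dihedrals = dihedrals,
       log = list(missing_atoms = unique(missing_atoms),
                  n_measured_bonds = sum(bonds$source == "measured"),
                  n_measured_angles = sum(angles$source == "measured")))
}

#' Non-bonded exclusion pairs
#'
#' Same-residue pairs plus 1-2, 1-3 and 1-4 bonded relationships; these
#' pairs are governed by bonded terms and take part in neither the contact
#' search nor the non-contact repulsion.
#'
#' @param structure A structure tibble.
#' @param bonds Bond tibble with columns `i`, `j`.
#' @return Two-column integer matrix of excluded pairs (i < j).
#' @export
bonded_exclusions <- function(structure, bonds) {
  pairs <- list()
  add <- function(i, j) {
    m <- cbind(pmin(i, j), pmax(i, j))
    pairs[[length(pairs) + 1]] <<- m
    invisible()
  }
  # same residue
  rkey <- paste(structure$chain, structure$resid, structure$insert)
  for (k in unique(rkey)) {
    idx <- which(rkey == k)
    if (length(idx) > 1) {
      cmb <- utils::combn(idx, 2)
      add(cmb[1, ], cmb[2, ])
    }
  }
  adj <- vector("list", nrow(structure))
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
  }
  add(bonds$i, bonds$j) # 1-2
  for (jc in seq_along(adj)) { # 1-3 through common centre jc
    nb <- unique(adj[[jc]])
    if (length(nb) > 1) {
      cmb <- utils::combn(nb, 2)
      add(cmb[1, ], cmb[2, ])
    }
  }
  for (b in seq_len(nrow(bonds))) { # 1-4 across central bond j-k
    jn <- setdiff(unique(adj[[bonds$i[b]]]), bonds$j[b])
    kn <- setdiff(unique(adj[[bonds$j[b]]]), bonds$i[b])
    if (length(jn) > 0 && length(kn) > 0) {
      g <- expand.grid(jn, kn)
      g <- g[g[, 1] != g[, 2], , drop = FALSE]
      if (nrow(g) > 0) add(g[, 1], g[, 2])
    }
  }
  m <- do.call(rbind, pairs)
  m <- m[!duplicated(pair_key(m[, 1], m[, 2])), , drop = FALSE]
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Shadow Contact Map
#'
#' A pair (i, j) is a native contact iff its distance in the reference
#' structure is at most `cutoff`, the pair is not excluded (same residue or
#' 1-2/1-3/1-4 bonded relationship), and no third atom of radius
#' `shadow_radius` occludes the line of sight: atom k shadows the pair when
#' its projection onto the segment i-j falls strictly between the endpoints
#' and its perpendicular distance to the segment is below `shadow_radius`.
#' The result is symmetric and invariant to atom input order.
#'
#' @param structure A structure tibble (the reference coordinates).
#' @param cutoff Contact distance cutoff, Angstrom.
#' @param shadow_radius Occluding-atom radius, Angstrom.
#' @param exclusions Optional two-column matrix of atom-index pairs to
#'   exclude (typically from [bonded_exclusions()]); same-residue pairs are
#'   always excluded.
#' @return Tibble with columns `i`, `j` (i < j) and `r0` (native distance).
#' @export
shadow_contact_map <- function(structure, cutoff = 6, shadow_radius = 1,
                               exclusions = NULL) {
  stopifnot(cutoff > 0, shadow_radius >= 0)
  xyz <- coords(structure)
  n <- nrow(xyz)
  rkey <- paste(structure$chain, structure$resid, structure$insert)
  excl <- character(0)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    excl <- pair_key(exclusions[, 1], exclusions[, 2])
  }
  # neighbour lists within cutoff (also candidate pairs)
  nb <- vector("list", n)
  ci <- cj <- integer(0)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    hits <- which(d2 <= cutoff^2 & seq_len(n) != i)
    nb[[i]] <- hits
    jj <- hits[hits > i]
    ci <- c(ci, rep.int(i, length(jj)))
    cj <- c(cj, jj)
  }
  keep <- rkey[ci] != rkey[cj] & !(pair_key(ci, cj) %in% excl)
  ci <- ci[keep]; cj <- cj[keep]
  visible <- logical(length(ci))
  for (q in seq_along(ci)) {
    i <- ci[q]; j <- cj[q]
    ks <- setdiff(union(nb[[i]], nb[[j]]), c(i, j))
    if (length(ks) == 0) { visible[q] <- TRUE; next }
    a <- xyz[i, ]
    ab <- xyz[j, ] - a
    len2 <- sum(ab^2)
    rel <- t(xyz[ks, , drop = FALSE]) - a
    tt <- colSums(rel * ab) / len2
    perp2 <- colSums(rel^2) - tt^2 * len2
    visible[q] <- !any(tt > 0 & tt < 1 & perp2 < shadow_radius^2)
  }
  d <- sqrt(rowSums((xyz[ci[visible], , drop = FALSE] -
                     xyz[cj[visible], , drop = FALSE])^2))
  tibble::tibble(i = ci[visible], j = cj[visible], r0 = d)
}

#' Assign energy scales (normalization of stabilizing terms)
#'
#' The stabilizing energy is partitioned so that the total over contacts and
#' proper dihedrals equals `n_atoms x epsilon`, contacts carry twice the
#' dihedral total, and each backbone dihedral carries twice the weight of a
#' sidechain dihedral (uniform within each class). Fixed weights for bonds,
#' angles, impropers, planars and non-contacts take their standard printed
#' values (see [default_scales()]).
#'
#' @param structure Reference structure tibble.
#' @param bonded Output of [extract_bonded_terms()].
#' @param contacts Output of [shadow_contact_map()].
#' @param scales Fixed weights, see [default_scales()].
#' @return An `sbm_forcefield` object.
#' @export
assign_energy_scales <- function(structure, bonded, contacts,
                                 scales = default_scales()) {
  n_atoms <- nrow(structure)
  n_c <- nrow(contacts)
  n_bb <- sum(bonded$dihedrals$class == "backbone")
  n_sc <- sum(bonded$dihedrals$class == "sidechain")
  if (n_c == 0 || (n_bb + n_sc) == 0) {
    abort("normalization needs at least one contact and one proper dihedral")
  }
  total <- n_atoms # in units of epsilon
  contact_total <- 2 / 3 * total
  dihedral_total <- 1 / 3 * total
  eps_sc <- dihedral_total / (2 * n_bb + n_sc)
  eps_bb <- 2 * eps_sc
  eps_c <- contact_total / n_c

  bonds <- bonded$bonds
  bonds$weight <- scales$eps_r
  angles <- bonded$angles
  angles$weight <- scales$eps_theta
  impropers <- bonded$impropers
  impropers$weight <- scales$eps_imp
  planars <- bonded$planars
  planars$weight <- scales$eps_planar
  dihedrals <- bonded$dihedrals
  dihedrals$weight <- ifelse(dihedrals$class == "backbone", eps_bb, eps_sc)
  contacts$sigma <- scales$contact_sigma_scale * contacts$r0
  contacts$weight <- eps_c

  ff <- list(
    structure = structure,
    bonds = bonds, angles = angles, impropers = impropers,
    planars = planars, dihedrals = dihedrals, contacts = contacts,
    restraints = tibble::tibble(i = integer(0), j = integer(0),
                                r_min = numeric(0), k = numeric(0)),
    exclusions = bonded_exclusions(structure, bonds),
    scales = c(scales, list(eps_bb = eps_bb, eps_sc = eps_sc, eps_c = eps_c)),
    log = bonded$log
  )
  ff$provenance <- list(
    source = attr(structure, "source") %||% "memory",
    n_atoms = n_atoms,
    hash = content_hash(list(bonds$r0, angles$theta0, dihedrals$phi0,
                             contacts$r0, n_atoms))
  )
  class(ff) <- "sbm_forcefield"
  ff
}

#' Build a complete force field from a reference structure
#'
#' Convenience wrapper: bonded terms, Shadow Contact Map, energy-scale
#' normalization, then optional disorder masking.
#'
#' @inheritParams extract_bonded_terms
#' @inheritParams shadow_contact_map
#' @param disorder Optional disorder specification, see
#'   [apply_disorder_mask()].
#' @param scales Fixed weights, see [default_scales()].
#' @return An `sbm_forcefield`.
#' @export
build_forcefield <- function(structure, templates = residue_templates(),
                             cutoff = 6, shadow_radius = 1, disorder = NULL,
                             scales = default_scales()) {
  bonded <- extract_bonded_terms(structure, templates)
  excl <- bonded_exclusions(structure, bonded$bonds)
  contacts <- shadow_contact_map(structure, cutoff, shadow_radius,
                                 exclusions = excl)
  ff <- assign_energy_scales(structure, bonded, contacts, scales)
  if (!is.null(disorder) && nrow(as_disorder_spec(disorder)) > 0) {
    ff <- apply_disorder_mask(ff, disorder)
  }
  ff
}

as_disorder_spec <- function(spec) {
  if (is.null(spec)) {
    return(tibble::tibble(chain = character(0), start = integer(0),
                          end = integer(0)))
  }
  spec <- tibble::as_tibble(spec)
  if (nrow(spec) > 0) stopifnot(all(c("chain", "start", "end") %in% names(spec)))
  spec
}

#' Remove stabilizing terms for disordered regions
#'
#' Contacts and proper dihedrals with at least one atom in a masked residue
#' are removed; bonds, angles, impropers and planars are retained so chain
#' connectivity and local geometry are preserved. Weights of the remaining
#' terms are unchanged (masking happens after normalization). Removed pairs
#' fall back to the generic non-contact repulsion.
#'
#' @param ff An `sbm_forcefield`.
#' @param spec Data frame with columns `chain`, `start`, `end` (inclusive
#'   author residue-number ranges).
#' @return The masked `sbm_forcefield`; removal counts are appended to its
#'   `log`.
#' @export
apply_disorder_mask <- function(ff, spec) {
  spec <- as_disorder_spec(spec)
  if (nrow(spec) == 0) return(ff)
  s <- ff$structure
  masked <- rep(FALSE, nrow(s))
  for (r in seq_len(nrow(spec))) {
    hit <- s$chain == spec$chain[r] & s$resid >= spec$start[r] &
      s$resid <= spec$end[r]
    if (!any(hit)) {
      abort(sprintf("disorder range %s %d-%d resolves to zero residues",
                    spec$chain[r], spec$start[r], spec$end[r]))
    }
    masked <- masked | hit
  }
  midx <- which(masked)
  c_drop <- ff$contacts$i %in% midx | ff$contacts$j %in% midx
  d_drop <- ff$dihedrals$i %in% midx | ff$dihedrals$j %in% midx |
    ff$dihedrals$k %in% midx | ff$dihedrals$l %in% midx
  ff$contacts <- ff$contacts[!c_drop, ]
  ff$dihedrals <- ff$dihedrals[!d_drop, ]
  ff$log$disorder <- list(n_masked_atoms = length(midx),
                          n_contacts_removed = sum(c_drop),
                          n_dihedrals_removed = sum(d_drop))
  ff
}

#' Add a harmonic distance restraint
#'
#' Adds `U = (k/2) (r_ij - r_min)^2` to the potential; zero at \code{r = r_min}.
#' A spring constant quoted in eps/nm^2 converts to eps/A^2 by dividing by
#' 100 (e.g. 150 eps/nm^2 = 1.5 eps/A^2).
#'
#' @param ff An `sbm_forcefield`.
#' @param atom_i,atom_j Atom indices (distinct).
#' @param r_min Restraint minimum, Angstrom.
#' @param k Spring constant, eps/A^2.
#' @return The `sbm_forcefield` with the restraint appended.
#' @export
add_distance_restraint <- function(ff, atom_i, atom_j, r_min = 5, k = 1.5) {
  n <- nrow(ff$structure)
  if (atom_i == atom_j) abort("restraint atoms must be distinct")
  if (min(atom_i, atom_j) < 1 || max(atom_i, atom_j) > n) {
    abort("restraint atom index out of range")
  }
  if (k < 0) abort("restraint spring constant must be non-negative")
  ff$restraints <- dplyr::bind_rows(
    ff$restraints,
    tibble::tibble(i = as.integer(atom_i), j = as.integer(atom_j),
                   r_min = r_min, k = k)
  )
  ff
}

#' @export
print.sbm_forcefield <- function(x, ...) {
  cat(sprintf(paste0(
    "Single-basin structure-based force field\n",
    "  atoms: %d   bonds: %d   angles: %d   impropers: %d   planars: %d\n",
    "  dihedrals: %d (bb %d / sc %d)   contacts: %d   restraints: %d\n",
    "  eps_c = %.4f, eps_bb = %.4f, eps_sc = %.4f (reduced units)\n"),
    nrow(x$structure), nrow(x$bonds), nrow(x$angles), nrow(x$impropers),
    nrow(x$planars), nrow(x$dihedrals),
    sum(x$dihedrals$class == "backbone"),
    sum(x$dihedrals$class == "sidechain"),
    nrow(x$contacts), nrow(x$restraints),
    x$scales$eps_c, x$scales$eps_bb, x$scales$eps_sc))
  invisible(x)
}
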