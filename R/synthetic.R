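#' Toy-system specification
#'
#' Describes a seedable synthetic two-domain all-atom system: a helical
#' protein-like body, a hinge linker, a helical domain carrying a bound
#' pseudo-cofactor atom, a target atom on the body, and (optionally, via
#' [make_disordered_tail()]) a flexible nucleotide-like tail standing in for
#' disordered rRNA. Residues use the reduced toy alphabet (`ALX`, `NUX`,
#' `LIG`, `TGT`) so the template tables stay small while every force-field
#' term class is exercised.
#'
#' @param n_residues_body,n_residues_domain Residue counts of the two
#'   helical segments.
#' @param linker_length Hinge linker residues between them.
#' @param disorder_tail_length Nucleotide-like tail residues (chain B).
#' @param ligand_target_distance Intended native distance between the
#'   pseudo-cofactor and the target atom, Angstrom; the realized value is
#'   recorded in the metadata.
#' @param seed Integer recorded with the system (the native build itself is
#'   deterministic; the seed propagates to simulations).
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_residues_body = 18, n_residues_domain = 8,
                     linker_length = 2, disorder_tail_length = 6,
                     ligand_target_distance = 10, seed = 1L) {
  stopifnot(n_residues_body >= 4, n_residues_domain >= 4,
            linker_length >= 1, disorder_tail_length >= 0)
  structure(list(n_residues_body = as.integer(n_residues_body),
                 n_residues_domain = as.integer(n_residues_domain),
                 linker_length = as.integer(linker_length),
                 disorder_tail_length = as.integer(disorder_tail_length),
                 ligand_target_distance = ligand_target_distance,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

# Natural-extension-reference-frame placement: position D bonded to C with
# |CD| = r, angle(B, C, D) = theta and dihedral(A, B, C, D) = phi (radians).
nerf <- function(A, B, C, r, theta, phi) {
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  C + cbind(bc, m, n) %*% d |> as.numeric()
}

# Build a chain of ALX residues from per-residue (phi, psi) torsions
# (degrees). Omega is exactly 180 so peptide planar groups sit at their
# energy minimum. Returns an atom tibble in template order.
build_alx_chain <- function(phi, psi, chain = "A", resid_start = 1L,
                            origin = c(0, 0, 0), chi1 = -60) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res)
  b <- list(NCA = 1.449, CAC = 1.522, CO = 1.229, CN = 1.335,
            CACB = 1.53, CBCG = 1.52)
  a <- lapply(list(NCAC = 110.1, CACO = 120.4, CACN = 116.6, CNCA = 121.9,
                   NCACB = 110.5, CACBCG = 114), rad)
  pos <- list() # pos[[i]] = list(N=, CA=, C=, O=, CB=, CG=)
  for (i in seq_len(n_res)) {
    p <- list()
    if (i == 1) {
      p$N <- origin
      p$CA <- origin + c(b$NCA, 0, 0)
      ang <- pi - a$NCAC
      p$C <- p$CA + b$CAC * c(cos(ang), sin(ang), 0)
    } else {
      q <- pos[[i - 1]]
      p$N <- nerf(q$N, q$CA, q$C, b$CN, a$CACN, rad(psi[i - 1]))
      p$CA <- nerf(q$CA, q$C, p$N, b$NCA, a$CNCA, pi) # omega = 180 exactly
      p$C <- nerf(q$C, p$N, p$CA, b$CAC, a$NCAC, rad(phi[i]))
    }
    p$O <- nerf(p$N, p$CA, p$C, b$CO, a$CACO, rad(psi[i] - 180))
    p$CB <- nerf(p$C, p$N, p$CA, b$CACB, a$NCACB, rad(-122))
    p$CG <- nerf(p$N, p$CA, p$CB, b$CBCG, a$CACBCG, rad(chi1))
    pos[[i]] <- p
  }
  atoms <- c("N", "CA", "C", "O", "CB", "CG")
  purrr::map_dfr(seq_len(n_res), function(i) {
    xyz <- do.call(rbind, pos[[i]][atoms])
    tibble::tibble(name = atoms, resname = "ALX", chain = chain,
                   resid = resid_start + i - 1L,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
}

# Build a chain of NUX residues with fixed A-form-like torsions along a
# given start frame. Returns an atom tibble in template order.
build_nux_chain <- function(n_res, chain = "B", resid_start = 1L,
                            origin = c(0, 0, 0), direction = c(1, 0, 0),
                            normal = c(0, 0, 1)) {
  b <- list(PO5 = 1.60, O5C5 = 1.44, C5C4 = 1.51, C4C3 = 1.53,
            C3O3 = 1.42, O3P = 1.60, C4N1 = 1.47, N1C2 = 1.35)
  a <- lapply(list(PO5C5 = 120.9, O5C5C4 = 111.5, C5C4C3 = 116,
                   C4C3O3 = 111, C3O3P = 119.7, O3PO5 = 104,
                   C5C4N1 = 110, C4N1C2 = 120), rad)
  tors <- lapply(list(alpha = -60, beta = 180, gamma = 60, delta = 80,
                      epsilon = -150, zeta = -70, base = -60, chi = -120),
                 rad)
  u <- unit(direction)
  w <- unit(cross3(u, normal))
  pos <- list()
  for (i in seq_len(n_res)) {
    p <- list()
    if (i == 1) {
      p$P <- origin
      p$O5 <- origin + b$PO5 * u
      ang <- pi - a$PO5C5
      p$C5 <- p$O5 + b$O5C5 * (cos(ang) * u + sin(ang) * w)
    } else {
      q <- pos[[i - 1]]
      p$P <- nerf(q$C4, q$C3, q$O3, b$O3P, a$C3O3P, tors$epsilon)
      p$O5 <- nerf(q$C3, q$O3, p$P, b$PO5, a$O3PO5, tors$zeta)
      p$C5 <- nerf(q$O3, p$P, p$O5, b$O5C5, a$PO5C5, tors$alpha)
    }
    p$C4 <- nerf(p$P, p$O5, p$C5, b$C5C4, a$O5C5C4, tors$beta)
    p$C3 <- nerf(p$O5, p$C5, p$C4, b$C4C3, a$C5C4C3, tors$gamma)
    p$O3 <- nerf(p$C5, p$C4, p$C3, b$C3O3, a$C4C3O3, tors$delta)
    p$N1 <- nerf(p$O5, p$C5, p$C4, b$C4N1, a$C5C4N1, tors$base)
    p$C2 <- nerf(p$C3, p$C4, p$N1, b$N1C2, a$C4N1C2, tors$chi)
    pos[[i]] <- p
  }
  nm <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "N1", "C2")
  key <- c("P", "O5", "C5", "C4", "C3", "O3", "N1", "C2")
  purrr::map_dfr(seq_len(n_res), function(i) {
    xyz <- do.call(rbind, pos[[i]][key])
    tibble::tibble(name = nm, resname = "NUX", chain = chain,
                   resid = resid_start + i - 1L,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
}

#' Build the native ("post-catalytic") toy two-domain system
#'
#' A single protein-like chain A: a helical body, an extended hinge linker
#' and a helical domain. A pseudo-cofactor atom (chain C, `LIG`) sits
#' covalently attached inside the domain and a target atom (chain C, `TGT`)
#' sits on the body surface, at a native separation near the requested
#' value. The build is deterministic; the returned metadata records the
#' ground truth every downstream stage needs.
#'
#' @param spec A [toy_spec()].
#' @return The native structure with attribute `"toy"`: a list holding
#'   `spec`, `ligand_index`, `target_index`,
#'   `native_ligand_target_distance`, `hinge_resids`, `body_selection`,
#'   `domain_selection` and `domain_resids`.
#' @export
make_toy_two_domain_system <- function(spec = toy_spec()) {
  nb <- spec$n_residues_body
  nl <- spec$linker_length
  nd <- spec$n_residues_domain
  n_res <- nb + nl + nd
  # helix torsions for body and domain; the linker leaves the helix in an
  # extended, sterically clean conformation (no non-contact pair inside the
  # repulsion cutoff at the native state)
  phi <- c(rep(-57, nb), rep(-120, nl), rep(-57, nd))
  psi <- c(rep(-47, nb), rep(100, nl), rep(-47, nd))
  prot <- build_alx_chain(phi, psi, chain = "A")

  # pseudo-cofactor: bonded to the CG of a mid-domain residue
  dom_res <- (nb + nl + 1):n_res
  anchor_res <- dom_res[ceiling(nd / 2)]
  anchor <- function(res, name) {
    as.numeric(prot[prot$resid == res & prot$name == name, c("x", "y", "z")])
  }
  lig <- nerf(anchor(anchor_res, "CA"), anchor(anchor_res, "CB"),
              anchor(anchor_res, "CG"), 1.8, rad(109), rad(60))

  # target: attached to the CG of the body residue whose geometry best
  # realizes the requested native ligand-target distance
  body_res <- seq_len(nb)
  cand <- purrr::map(body_res, function(res) {
    cg <- anchor(res, "CG")
    pos <- cg + 1.8 * unit(lig - cg)
    list(res = res, pos = pos, d = vnorm(lig - pos))
  })
  best <- cand[[which.min(vapply(cand, function(z)
    abs(z$d - spec$ligand_target_distance), numeric(1)))]]

  het <- tibble::tibble(
    name = c("S1", "C1"), resname = c("LIG", "TGT"), chain = "C",
    resid = c(1L, 2L),
    x = c(lig[1], best$pos[1]), y = c(lig[2], best$pos[2]),
    z = c(lig[3], best$pos[3]), het = TRUE
  )
  atoms <- dplyr::bind_rows(prot, het)
  s <- new_structure(atoms, source = sprintf("toy(seed=%d)", spec$seed))

  check_toy_clashes(s)

  lig_idx <- which(s$resname == "LIG")
  tgt_idx <- which(s$resname == "TGT")
  meta <- list(
    spec = spec,
    n_atoms = nrow(s),
    ligand_index = lig_idx,
    target_index = tgt_idx,
    native_ligand_target_distance = vnorm(coords(s)[lig_idx, ] -
                                          coords(s)[tgt_idx, ]),
    hinge_resids = (nb + 1):(nb + nl),
    domain_resids = dom_res,
    body_selection = sprintf("(chain A and resid 1:%d) or resname TGT", nb),
    domain_selection = sprintf("(chain A and resid %d:%d) or resname LIG",
                               nb + nl + 1L, n_res),
    # the moving unit (hinge linker + domain): the region scanned for
    # intramolecular deformation, mirroring a.s.d. over the whole protein
    mobile_selection = sprintf("chain A and resid %d:%d", nb + 1L, n_res)
  )
  attr(s, "toy") <- meta
  s
}

# Steric sanity check: non-bonded inter-residue pairs must not overlap.
# Consecutive residues on a chain and heteroatom-anchor pairs are bonded.
check_toy_clashes <- function(s, tol = 1.9) {
  xyz <- coords(s)
  n <- nrow(s)
  worst <- Inf
  for (i in seq_len(n - 1)) {
    jj <- (i + 1):n
    d <- sqrt(colSums((t(xyz[jj, , drop = FALSE]) - xyz[i, ])^2))
    same_res <- s$chain[jj] == s$chain[i] & s$resid[jj] == s$resid[i]
    adjacent <- s$chain[jj] == s$chain[i] & abs(s$resid[jj] - s$resid[i]) == 1
    het_anchor <- (s$het[i] | s$het[jj]) & d < 2.0
    consider <- !same_res & !adjacent & !het_anchor
    if (any(consider)) worst <- min(worst, min(d[consider]))
  }
  if (worst < tol) {
    abort(sprintf("toy build produced a steric clash (min distance %.2f A)",
                  worst))
  }
  invisible(worst)
}

#' Rotate the domain rigidly to construct a "pre-catalytic" conformation
#'
#' Domain atoms (default: the domain recorded in the toy metadata) are
#' rotated by `angle_deg` about `axis` through the hinge pivot (the CA of
#' the hinge residue); all other atoms are untouched.
#'
#' @param native A structure (typically from
#'   [make_toy_two_domain_system()]).
#' @param axis Rotation axis (unit 3-vector; normalized if not).
#' @param angle_deg Rotation angle, degrees.
#' @param hinge Hinge residue number on chain A (default: last hinge residue
#'   in the toy metadata).
#' @param domain Selection of the atoms to rotate (default: from metadata).
#' @return The rotated structure (metadata preserved).
#' @export
make_rotated_conformation <- function(native, axis, angle_deg,
                                      hinge = NULL, domain = NULL) {
  meta <- attr(native, "toy")
  if (is.null(hinge)) {
    if (is.null(meta)) abort("no toy metadata: supply `hinge`")
    hinge <- max(meta$hinge_resids)
  }
  if (is.null(domain)) {
    if (is.null(meta)) abort("no toy metadata: supply `domain`")
    domain <- meta$domain_selection
  }
  idx <- select_atoms(native, domain)
  pivot_row <- which(native$chain == "A" & native$resid == hinge &
                     native$name == "CA")
  if (length(pivot_row) != 1) abort("hinge residue CA not found")
  xyz <- coords(native)
  pivot <- xyz[pivot_row, ]
  R <- rotation_about_axis(unit(axis), rad(angle_deg))
  moved <- sweep(sweep(xyz[idx, , drop = FALSE], 2, pivot) %*% t(R), 2,
                 pivot, "+")
  xyz[idx, ] <- moved
  out <- set_coords(native, xyz)
  attr(out, "toy") <- meta
  out
}

#' Append a flexible nucleotide-like tail and its disorder specification
#'
#' Adds a chain-B `NUX` polymer lying alongside the body (close enough for
#' the Shadow Contact Map to find stabilizing body-tail contacts) and
#' returns the matching disorder ranges. With tail length zero the
#' structure is returned unchanged and the specification is empty.
#'
#' @param structure A toy structure.
#' @param spec The [toy_spec()] (uses `disorder_tail_length`).
#' @return List with `structure` and `disorder` (tibble `chain`, `start`,
#'   `end`).
#' @export
make_disordered_tail <- function(structure, spec = attr(structure, "toy")$spec) {
  n_tail <- spec$disorder_tail_length
  empty <- tibble::tibble(chain = character(0), start = integer(0),
                          end = integer(0))
  if (n_tail == 0) return(list(structure = structure, disorder = empty))
  body_ca <- structure$chain == "A" & structure$name == "CA" &
    structure$resid <= spec$n_residues_body
  P <- coords(structure)[body_ca, , drop = FALSE]
  ctr <- colMeans(P)
  ax <- svd(sweep(P, 2, ctr))$v[, 1]
  side <- unit(cross3(ax, c(0, 0, 1) - ax * ax[3]))
  origin <- ctr - ax * (spec$n_residues_body * 0.75) + side * 8.5
  tail <- build_nux_chain(n_tail, chain = "B", origin = origin,
                          direction = ax, normal = side)
  tail$het <- FALSE
  meta <- attr(structure, "toy")
  out <- new_structure(dplyr::bind_rows(tibble::as_tibble(structure), tail),
                       source = attr(structure, "source") %||% "toy")
  attr(out, "toy") <- meta
  list(structure = out,
       disorder = tibble::tibble(chain = "B", start = 1L,
                                 end = as.integer(n_tail)))
}
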