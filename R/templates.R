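#' Residue templates
#'
#' A template lists, for one residue type, its heavy atoms, intra-residue and
#' inter-residue bonds, and the improper, planar and proper dihedral
#' quadruples. Atom names prefixed `+` refer to the next residue in the same
#' chain, `-` to the previous one; terms whose neighbours are missing (chain
#' ends, breaks) are skipped. Angles are not listed: they are derived from
#' the bond graph (every pair of bonds sharing a central atom).
#'
#' The registry bundles standard templates for glycine and alanine, the
#' reduced toy alphabet (`ALX`, a protein-like residue with a two-atom
#' sidechain; `NUX`, a nucleotide-like residue with a two-atom base), and
#' single-atom pseudo-ligand templates (`LIG`, `TGT`). Additional ligands can
#' be added with [ligand_template()].
#'
#' @return Named list of templates.
#' @export
residue_templates <- function() {
  tpl <- function(atoms, bonds, propers = list(), impropers = list(),
                  planars = list(), kind = "protein") {
    list(atoms = atoms,
         bonds = matrix(bonds, ncol = 2, byrow = TRUE),
         propers = propers, impropers = impropers, planars = planars,
         kind = kind)
  }
  peptide_bb <- c("N", "CA", "C", "O",  "C", "+N")
  phi <- c("-C", "N", "CA", "C")
  psi <- c("N", "CA", "C", "+N")
  omega_planar <- c("CA", "C", "+N", "+CA")
  carbonyl_imp <- c("CA", "+N", "C", "O")

  list(
    GLY = tpl(
      atoms = c("N", "CA", "C", "O"),
      bonds = c("N", "CA", "CA", "C", peptide_bb[3:6]),
      propers = list(phi, psi),
      impropers = list(carbonyl_imp),
      planars = list(omega_planar)
    ),
    ALA = tpl(
      atoms = c("N", "CA", "C", "O", "CB"),
      bonds = c("N", "CA", "CA", "C", peptide_bb[3:6], "CA", "CB"),
      propers = list(phi, psi),
      impropers = list(c("N", "C", "CA", "CB"), carbonyl_imp),
      planars = list(omega_planar)
    ),
    ALX = tpl(
      atoms = c("N", "CA", "C", "O", "CB", "CG"),
      bonds = c("N", "CA", "CA", "C", peptide_bb[3:6],
                "CA", "CB", "CB", "CG"),
      propers = list(phi, psi, c("N", "CA", "CB", "CG")),
      impropers = list(c("N", "C", "CA", "CB"), carbonyl_imp),
      planars = list(omega_planar)
    ),
    NUX = tpl(
      atoms = c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "N1", "C2"),
      bonds = c("P", "O5'", "O5'", "C5'", "C5'", "C4'", "C4'", "C3'",
                "C3'", "O3'", "C4'", "N1", "N1", "C2", "O3'", "+P"),
      propers = list(c("P", "O5'", "C5'", "C4'"),
                     c("O5'", "C5'", "C4'", "C3'"),
                     c("C5'", "C4'", "C3'", "O3'"),
                     c("C4'", "C3'", "O3'", "+P"),
                     c("C3'", "O3'", "+P", "+O5'"),
                     c("C3'", "C4'", "N1", "C2")),
      impropers = list(c("C5'", "C3'", "C4'", "N1")),
      kind = "nucleic"
    ),
    LIG = tpl(atoms = "S1", bonds = character(0), kind = "ligand"),
    TGT = tpl(atoms = "C1", bonds = character(0), kind = "ligand")
  )
}

#' Build a ligand template from observed geometry
#'
#' For heteroligands without a bundled template: bonds are inferred from
#' interatomic distances in `structure` (pairs closer than `bond_cut`, with a
#' wider cut for S/P), angles follow from the bond graph, and no dihedral
#' terms are assigned, so the ligand is held near its native internal
#' geometry by bonds and angles alone.
#'
#' @param structure A structure tibble containing the ligand.
#' @param resname Residue name of the ligand.
#' @param bond_cut Distance cutoff for bond inference, Angstrom.
#' @return A template list suitable for [residue_templates()] registries.
#' @export
ligand_template <- function(structure, resname, bond_cut = 1.85) {
  at <- structure[structure$resname == resname, ]
  at <- at[at$chain == at$chain[1] & at$resid == at$resid[1], ]
  if (nrow(at) == 0) abort(paste0("no atoms with resname ", resname))
  xyz <- coords(at)
  bonds <- character(0)
  n <- nrow(at)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cut <- bond_cut
        if (any(c(at$element[i], at$element[j]) %in% c("S", "P"))) cut <- 2.1
        if (vnorm(xyz[i, ] - xyz[j, ]) <= cut) {
          bonds <- c(bonds, at$name[i], at$name[j])
        }
      }
    }
  }
  list(atoms = at$name,
       bonds = matrix(bonds, ncol = 2, byrow = TRUE),
       propers = list(), impropers = list(), planars = list(),
       kind = "ligand")
}

# Reference equilibrium values for standard residues (bonds in Angstrom,
# angles in degrees), keyed by residue and template-relative atom names.
# Pairs/triples absent from these tables fall back to the value measured in
# the input structure (logged by the builder).
reference_bond_table <- function() {
  tibble::tribble(
    ~resname, ~a1, ~a2, ~r0,
    "GLY", "N", "CA", 1.449,
    "GLY", "CA", "C", 1.522,
    "GLY", "C", "O", 1.229,
    "GLY", "C", "+N", 1.335,
    "ALA", "N", "CA", 1.449,
    "ALA", "CA", "C", 1.522,
    "ALA", "C", "O", 1.229,
    "ALA", "C", "+N", 1.335,
    "ALA", "CA", "CB", 1.526
  )
}

reference_angle_table <- function() {
  tibble::tribble(
    ~resname, ~a1, ~a2, ~a3, ~theta0_deg,
    "GLY", "N", "CA", "C", 110.1,
    "GLY", "CA", "C", "O", 120.4,
    "GLY", "CA", "C", "+N", 116.6,
    "GLY", "O", "C", "+N", 122.9,
    "GLY", "-C", "N", "CA", 121.9,
    "ALA", "N", "CA", "C", 110.1,
    "ALA", "CA", "C", "O", 120.4,
    "ALA", "CA", "C", "+N", 116.6,
    "ALA", "O", "C", "+N", 122.9,
    "ALA", "-C", "N", "CA", 121.9,
    "ALA", "N", "CA", "CB", 109.7,
    "ALA", "CB", "CA", "C", 111.1
  )
}

# Backbone atom-name sets used to classify proper dihedrals.
backbone_atom_names <- function() {
  c(protein_backbone_names, nucleic_backbone_names)
}
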