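#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a force field into one long term table
#'
#' @param x An `sbm_forcefield`.
#' @param ... Unused.
#' @return Tibble with `term` (class), atom indices `i`-`l`, the equilibrium
#'   `value` (length, angle or dihedral; `sigma` for contacts) and `weight`.
#' @export
tidy.sbm_forcefield <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$bonds, term = "bond", value = .data$r0,
                  k = NA_integer_, l = NA_integer_),
    dplyr::mutate(x$angles, term = "angle", value = .data$theta0,
                  l = NA_integer_),
    dplyr::mutate(x$impropers, term = "improper", value = .data$chi0),
    dplyr::mutate(x$planars, term = "planar", value = NA_real_),
    dplyr::mutate(x$dihedrals, term = paste0("dihedral_",
                                             substr(.data$class, 1, 2)),
                  value = .data$phi0),
    dplyr::mutate(x$contacts, term = "contact", value = .data$sigma,
                  k = NA_integer_, l = NA_integer_),
    dplyr::mutate(x$restraints, term = "restraint", value = .data$r_min,
                  weight = .data$k, k = NA_integer_, l = NA_integer_)
  )[, c("term", "i", "j", "k", "l", "value", "weight")]
}

#' One-row force-field summary
#'
#' @param x An `sbm_forcefield`.
#' @param ... Unused.
#' @return One-row tibble with term counts, energy scales and the
#'   normalization diagnostics (contact/dihedral stabilizing totals).
#' @export
glance.sbm_forcefield <- function(x, ...) {
  tibble::tibble(
    n_atoms = nrow(x$structure),
    n_bonds = nrow(x$bonds), n_angles = nrow(x$angles),
    n_impropers = nrow(x$impropers), n_planars = nrow(x$planars),
    n_dihedrals = nrow(x$dihedrals), n_contacts = nrow(x$contacts),
    n_restraints = nrow(x$restraints),
    eps_c = x$scales$eps_c, eps_bb = x$scales$eps_bb,
    eps_sc = x$scales$eps_sc,
    contact_energy = sum(x$contacts$weight),
    dihedral_energy = sum(x$dihedrals$weight)
  )
}

#' Tidy a superposition result
#'
#' @param x A `kabsch_fit`.
#' @param ... Unused.
#' @return One-row tibble with the rotation's axis/angle and the
#'   translation.
#' @export
tidy.kabsch_fit <- function(x, ...) {
  aa <- er_axis_angle(diag(3), x$rotation)
  tibble::tibble(angle_deg = aa$angle_deg,
                 axis_x = aa$axis[1], axis_y = aa$axis[2],
                 axis_z = aa$axis[3],
                 tx = x$translation[1], ty = x$translation[2],
                 tz = x$translation[3])
}

#' @rdname tidy.kabsch_fit
#' @export
glance.kabsch_fit <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n = x$n)
}

#' Per-frame energy log of a trajectory
#'
#' @param x An `sbm_trajectory`.
#' @param ... Unused.
#' @return The energy tibble (step, per-term energies, potential, kinetic,
#'   instantaneous temperature).
#' @export
tidy.sbm_trajectory <- function(x, ...) x$energies

#' @rdname tidy.sbm_trajectory
#' @export
glance.sbm_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  tibble::tibble(n_frames = d[1], n_atoms = d[2],
                 temperature = x$config$temperature,
                 timestep = x$config$timestep, n_steps = x$config$n_steps,
                 seed = x$seed,
                 mean_temperature = mean(x$energies$temperature[-1]))
}
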