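#' Simulation configuration
#'
#' Reduced units throughout: the energy unit is epsilon, lengths are in
#' Angstrom, every atom has mass 1, time is in sqrt(m A^2 / eps), and
#' temperature is in eps/k_B. The defaults (timestep 0.002, friction 1.0)
#' are conventional stable values for this class of potential; temperature
#' 0.5 is the reduced temperature used for production runs.
#'
#' @param temperature Reduced temperature (eps/k_B).
#' @param timestep Integration timestep (reduced time).
#' @param friction Langevin friction (1/reduced time); 0 gives plain
#'   velocity-Verlet (microcanonical) integration.
#' @param n_steps Number of integration steps.
#' @param save_interval Steps between saved frames; must divide `n_steps`.
#' @param seed Integer seed controlling initial velocities and the
#'   thermostat noise.
#' @param restraints_active Whether distance restraints in the force field
#'   are applied.
#' @return A `sim_config` list.
#' @export
sim_config <- function(temperature = 0.5, timestep = 0.002, friction = 1.0,
                       n_steps = 10000L, save_interval = 100L, seed = 1L,
                       restraints_active = TRUE) {
  stopifnot(temperature >= 0, timestep > 0, friction >= 0,
            n_steps >= 1, save_interval >= 1,
            n_steps %% save_interval == 0)
  structure(list(temperature = temperature, timestep = timestep,
                 friction = friction, n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 seed = as.integer(seed),
                 restraints_active = isTRUE(restraints_active)),
            class = "sim_config")
}

# Flatten a force field into the 0-based arrays the C++ engine consumes.
# The engine distinguishes topology index vectors (e.g. angles_ai) from the
# per-term weight vectors (angles_k etc.).
engine_spec <- function(ff, restraints_active = TRUE) {
  ex <- rbind(ff$exclusions,
              cbind(ff$contacts$i, ff$contacts$j))
  res <- if (restraints_active) ff$restraints else ff$restraints[0, ]
  list(
    n = nrow(ff$structure),
    bonds_i = ff$bonds$i - 1L, bonds_j = ff$bonds$j - 1L,
    bonds_r0 = ff$bonds$r0, bonds_k = ff$bonds$weight,
    angles_ai = ff$angles$i - 1L, angles_aj = ff$angles$j - 1L,
    angles_ak = ff$angles$k - 1L,
    angles_th0 = ff$angles$theta0, angles_k = ff$angles$weight,
    imps_i = ff$impropers$i - 1L, imps_j = ff$impropers$j - 1L,
    imps_k = ff$impropers$k - 1L, imps_l = ff$impropers$l - 1L,
    imps_x0 = ff$impropers$chi0, imps_w = ff$impropers$weight,
    plan_i = ff$planars$i - 1L, plan_j = ff$planars$j - 1L,
    plan_k = ff$planars$k - 1L, plan_l = ff$planars$l - 1L,
    plan_w = ff$planars$weight,
    dih_i = ff$dihedrals$i - 1L, dih_j = ff$dihedrals$j - 1L,
    dih_k = ff$dihedrals$k - 1L, dih_l = ff$dihedrals$l - 1L,
    dih_phi0 = ff$dihedrals$phi0, dih_w = ff$dihedrals$weight,
    con_i = ff$contacts$i - 1L, con_j = ff$contacts$j - 1L,
    con_sigma = ff$contacts$sigma, con_eps = ff$contacts$weight,
    res_i = res$i - 1L, res_j = res$j - 1L,
    res_r0 = res$r_min, res_k = res$k,
    nc_eps = ff$scales$eps_nc, nc_sigma = ff$scales$sigma_nc,
    nc_cutoff = ff$scales$nc_cutoff,
    excl_i = ex[, 1] - 1L, excl_j = ex[, 2] - 1L
  )
}

#' Potential energy, analytic forces and per-term breakdown
#'
#' The energy is the sum of all term classes; forces are the analytic
#' negative gradient. The non-contact repulsion is truncated at
#' `scales$nc_cutoff` and shifted so the potential is continuous there.
#'
#' @param ff An `sbm_forcefield`.
#' @param coordinates N x 3 matrix (default: the reference coordinates).
#' @param restraints_active Whether restraint terms are evaluated.
#' @return List with `energy` (scalar, eps), `forces` (N x 3, eps/A) and
#'   `breakdown` (named numeric vector by term class, summing to `energy`).
#' @export
potential_energy <- function(ff, coordinates = NULL,
                             restraints_active = TRUE) {
  xyz <- if (is.null(coordinates)) coords(ff$structure) else coords(coordinates)
  if (nrow(xyz) != nrow(ff$structure)) abort("coordinate count mismatch")
  if (any(!is.finite(xyz))) abort("non-finite coordinates")
  .engine_energy_forces(engine_spec(ff, restraints_active), xyz)
}

#' Check that the reference structure is a stationary point of the bonded,
#' dihedral and planar terms
#'
#' Contacts place their minimum at 0.96 x the native distance and the
#' non-contact repulsion is always positive, so the full potential is not
#' exactly stationary at the reference; the builder's correctness check is
#' that every term whose equilibrium value is taken from the reference
#' geometry exerts zero force there.
#'
#' @param ff An `sbm_forcefield`.
#' @param tol Maximum allowed force component, eps/A.
#' @return Invisibly, the maximum absolute force component.
#' @export
validate_forcefield <- function(ff, tol = 1e-8) {
  ff0 <- ff
  ff0$contacts <- ff0$contacts[0, ]
  ff0$restraints <- ff0$restraints[0, ]
  ff0$scales$eps_nc <- 0
  # bonds/angles from reference tables are not measured values; zero them too
  ff0$bonds$r0 <- vapply(seq_len(nrow(ff0$bonds)), function(q) {
    dist3(coords(ff$structure), ff0$bonds$i[q], ff0$bonds$j[q])
  }, numeric(1))
  ff0$angles$theta0 <- vapply(seq_len(nrow(ff0$angles)), function(q) {
    angle3(coords(ff$structure), ff0$angles$i[q], ff0$angles$j[q],
           ff0$angles$k[q])
  }, numeric(1))
  out <- potential_energy(ff0, restraints_active = FALSE)
  mx <- max(abs(out$forces))
  if (mx > tol) {
    warn(sprintf("reference not stationary for measured terms: max |F| = %g",
                 mx))
  }
  invisible(mx)
}

#' Run Langevin dynamics
#'
#' BAOAB splitting at the configured temperature; with `friction = 0` the
#' thermostat is disabled and the integrator reduces to velocity Verlet.
#' Initial velocities are drawn from the Maxwell-Boltzmann distribution at
#' the configured temperature unless a start state supplies them.
#' Trajectories are reproducible bit-for-bit for a fixed seed, config and
#' force field.
#'
#' @param ff An `sbm_forcefield`.
#' @param config A [sim_config()].
#' @param start Optional list with `coordinates` (N x 3) and optionally
#'   `velocities`; defaults to the reference coordinates.
#' @return An `sbm_trajectory`: list with `frames` (n_frames x N x 3 array,
#'   frame 1 = initial state), `energies` (tibble logged at every save
#'   interval), `config`, `seed` and the force-field hash.
#' @export
run_langevin <- function(ff, config = sim_config(), start = NULL) {
  n <- nrow(ff$structure)
  xyz <- if (is.null(start)) coords(ff$structure) else coords(start$coordinates)
  if (any(!is.finite(xyz))) abort("non-finite start coordinates")
  if (nrow(xyz) != n) abort("start coordinates have wrong atom count")
  spec <- engine_spec(ff, config$restraints_active)

  set.seed(config$seed)
  vel <- if (!is.null(start$velocities)) {
    as.matrix(start$velocities)
  } else if (config$temperature > 0) {
    matrix(rnorm(n * 3, sd = sqrt(config$temperature)), n, 3)
  } else {
    matrix(0, n, 3)
  }

  n_chunks <- config$n_steps %/% config$save_interval
  frames <- array(NA_real_, c(n_chunks + 1L, n, 3L))
  frames[1, , ] <- xyz
  e0 <- .engine_energy_forces(spec, xyz)
  ke0 <- 0.5 * sum(vel^2)
  logs <- vector("list", n_chunks + 1L)
  logs[[1]] <- c(step = 0, e0$breakdown, potential = e0$energy,
                 kinetic = ke0, temperature = 2 * ke0 / (3 * n))
  thermo <- config$friction > 0
  for (ch in seq_len(n_chunks)) {
    noise <- if (thermo) {
      matrix(rnorm(config$save_interval * n * 3), config$save_interval * n, 3)
    } else matrix(0, 0, 3)
    out <- .engine_integrate(spec, xyz, vel, config$timestep, config$friction,
                             config$temperature, config$save_interval, noise)
    if (!isTRUE(out$ok)) {
      dump <- tempfile("sbm-diverged-", fileext = ".tsv")
      utils::write.table(out$coordinates, dump, sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      abort(sprintf("integration aborted at step %d: %s (frame dumped to %s)",
                    ch * config$save_interval, out$error, dump))
    }
    xyz <- out$coordinates
    vel <- out$velocities
    frames[ch + 1L, , ] <- xyz
    logs[[ch + 1L]] <- c(step = ch * config$save_interval, out$breakdown,
                         potential = out$potential, kinetic = out$kinetic,
                         temperature = 2 * out$kinetic / (3 * n))
  }
  energies <- tibble::as_tibble(do.call(rbind, logs))
  structure(list(frames = frames, energies = energies, config = config,
                 seed = config$seed,
                 ff_hash = ff$provenance$hash %||% NA_character_),
            class = "sbm_trajectory")
}

#' @export
print.sbm_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(paste0("Langevin trajectory: %d frames x %d atoms ",
                     "(T = %g, dt = %g, %d steps, seed %d)\n"),
              d[1], d[2], x$config$temperature, x$config$timestep,
              x$config$n_steps, x$seed))
  invisible(x)
}

#' Per-frame distance between two atoms
#'
#' @param traj An `sbm_trajectory`.
#' @param atom_i,atom_j Atom indices.
#' @param threshold Optional distance threshold (Angstrom); adds a logical
#'   `below` column marking frames with `distance < threshold`.
#' @return Tibble with `frame`, `distance` and optionally `below`.
#' @export
distance_timeseries <- function(traj, atom_i, atom_j, threshold = NULL) {
  d <- dim(traj$frames)
  if (max(atom_i, atom_j) > d[2] || min(atom_i, atom_j) < 1) {
    abort("atom index out of range")
  }
  dx <- traj$frames[, atom_i, ] - traj$frames[, atom_j, ]
  dist <- sqrt(rowSums(dx^2))
  out <- tibble::tibble(frame = seq_len(d[1]), distance = dist)
  if (!is.null(threshold)) out$below <- out$distance < threshold
  out
}
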