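#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R x + t` over the selected atoms of `mobile` against `reference`. The
#' reflection branch of the SVD is corrected so `det(R) = +1`.
#'
#' @param reference,mobile Structures or N x 3 coordinate matrices.
#' @param selection Atom indices used for the fit (default: all); either a
#'   numeric vector or a selection string resolved on `reference` (when
#'   `reference` is a structure).
#' @return A `kabsch_fit` object: list with `rotation` (3 x 3), `translation`
#'   (length-3), `rmsd` (Angstrom, over the selection) and `n`.
#' @export
kabsch_fit <- function(reference, mobile, selection = NULL) {
  idx <- if (is.null(selection)) {
    seq_len(nrow(coords(reference)))
  } else if (is.character(selection)) {
    select_atoms(reference, selection)
  } else {
    as.integer(selection)
  }
  A <- coords(reference)[idx, , drop = FALSE]
  B <- coords(mobile)[idx, , drop = FALSE]
  if (nrow(A) != nrow(B)) abort("selection lengths differ")
  if (nrow(A) < 3) abort("need at least 3 atoms for superposition")
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  sv_check <- svd(Bc)$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1)) {
    abort("degenerate (collinear) selection: superposition is ill-defined")
  }
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ca - as.numeric(R %*% cb)
  fitted <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Ac)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd, n = nrow(A)),
            class = "kabsch_fit")
}

# Apply a kabsch_fit to an N x 3 coordinate matrix.
apply_fit <- function(fit, xyz) {
  sweep(coords(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Euler-Rodrigues axis and angle between two orientations
#'
#' Returns the axis and angle of the relative rotation `Rb Ra^T`. The angle
#' lies in \[0, 180\] degrees; when it is (numerically) zero the axis is
#' undefined and flagged.
#'
#' @param rotation_a,rotation_b 3 x 3 proper orthogonal matrices (or
#'   `kabsch_fit` objects).
#' @return List with `axis` (unit 3-vector or `NA`), `angle_deg`, and
#'   `defined` (logical).
#' @export
er_axis_angle <- function(rotation_a, rotation_b) {
  Ra <- if (inherits(rotation_a, "kabsch_fit")) rotation_a$rotation else rotation_a
  Rb <- if (inherits(rotation_b, "kabsch_fit")) rotation_b$rotation else rotation_b
  check_rotation(Ra)
  check_rotation(Rb)
  R <- Rb %*% t(Ra)
  tr <- sum(diag(R))
  angle <- acos(max(-1, min(1, (tr - 1) / 2)))
  if (angle < 1e-7) {
    return(list(axis = rep(NA_real_, 3), angle_deg = deg(angle),
                defined = FALSE))
  }
  if (abs(angle - pi) > 1e-6) {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle))
  } else {
    # near 180 degrees: axis from the symmetric part
    S <- (R + diag(3)) / 2
    axis <- unit(S[, which.max(diag(S))])
  }
  list(axis = unit(axis), angle_deg = deg(angle), defined = TRUE)
}

check_rotation <- function(R, tol = 1e-6) {
  if (max(abs(t(R) %*% R - diag(3))) > tol || abs(det(R) - 1) > tol) {
    abort("matrix is not a proper rotation")
  }
  invisible(R)
}

#' Z-Y-Z Euler composition and decomposition
#'
#' Active rotations `R = Rz(phi) Ry(theta) Rz(psi)`. Angles in radians;
#' `theta` is returned in \[0, pi\]. At the gimbal singularity
#' (`theta = 0` or `pi`) only `phi + psi` (resp. `phi - psi`) is determined;
#' `psi` is set to zero there.
#'
#' @param phi,theta,psi Euler angles, radians.
#' @return `euler_zyz()`: a 3 x 3 rotation matrix.
#' @export
euler_zyz <- function(phi, theta, psi) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                           3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)),
                           3, 3)
  rz(phi) %*% ry(theta) %*% rz(psi)
}

#' @rdname euler_zyz
#' @param R A 3 x 3 rotation matrix.
#' @return `decompose_zyz()`: named vector `c(phi, theta, psi)` in radians.
#' @export
decompose_zyz <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct)
  st <- sin(theta)
  # below ~1e-7 rad the off-diagonal entries that define phi and psi
  # individually are dominated by roundoff; read the well-conditioned
  # combined z-rotation from the upper-left block instead
  if (st > 1e-7) {
    phi <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else if (ct > 0) { # theta = 0: R = Rz(phi + psi)
    phi <- atan2(R[2, 1], R[1, 1])
    psi <- 0
  } else {             # theta = pi: R = Rz(phi - psi) * flip
    phi <- atan2(R[2, 1], R[1, 1])
    psi <- 0
  }
  c(phi = phi, theta = theta, psi = psi)
}

# Orthonormal basis whose third column is the given unit axis.
axis_basis <- function(z) {
  z <- unit(z)
  u <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(u - sum(u * z) * z)
  e2 <- cross3(z, e1)
  cbind(e1, e2, z)
}

#' Rotation (gamma) and tilt (theta) of a domain along a trajectory
#'
#' Implements the per-frame protocol: (1) align the frame to the reference
#' on the body selection; (2) fit the reference domain onto the aligned
#' frame's domain atoms; (3) decompose the resulting rotation in the
#' coordinate system whose Z axis is the Euler-Rodrigues axis, using the
#' active Z-Y-Z convention; (4) report the rotation angle
#' `gamma = phi + psi` (about the E-R axis) and the tilt `theta`
#' (orthogonal polar angle).
#'
#' @param traj An `sbm_trajectory`.
#' @param reference Reference structure (same topology as the trajectory).
#' @param body_selection,domain_selection Index vectors or selection strings
#'   resolved on `reference`. The body selection operationalizes
#'   "everything except the analysed domain".
#' @param er_axis Unit 3-vector defining the primary rotation axis, e.g.
#'   from [er_axis_from_structures()].
#' @param frames Optional logical or integer frame mask (e.g. frames whose
#'   cofactor-target distance is below a threshold).
#' @return Tibble with `frame`, `phi`, `psi`, `theta`, `gamma` (degrees).
#' @export
rotation_tilt_timeseries <- function(traj, reference, body_selection,
                                     domain_selection, er_axis,
                                     frames = NULL) {
  body <- if (is.character(body_selection)) {
    select_atoms(reference, body_selection)
  } else as.integer(body_selection)
  dom <- if (is.character(domain_selection)) {
    select_atoms(reference, domain_selection)
  } else as.integer(domain_selection)
  nf <- dim(traj$frames)[1]
  if (dim(traj$frames)[2] != nrow(reference)) {
    abort("trajectory and reference atom counts differ")
  }
  idx <- if (is.null(frames)) {
    seq_len(nf)
  } else if (is.logical(frames)) {
    which(frames)
  } else {
    as.integer(frames)
  }
  B <- axis_basis(er_axis)
  ref_xyz <- coords(reference)
  out <- purrr::map_dfr(idx, function(fr) {
    xyz <- traj$frames[fr, , ]
    fit_body <- kabsch_fit(ref_xyz, xyz, body)
    aligned <- apply_fit(fit_body, xyz)
    # rotation carrying the reference domain onto the frame's domain
    fit_dom <- kabsch_fit(aligned[dom, , drop = FALSE],
                          ref_xyz[dom, , drop = FALSE])
    Rp <- t(B) %*% fit_dom$rotation %*% B
    ang <- unname(decompose_zyz(Rp))
    tibble::tibble(frame = fr,
                   phi = deg(ang[1]), psi = deg(ang[3]),
                   theta = deg(ang[2]),
                   gamma = deg(wrap_angle(ang[1] + ang[3])))
  })
  class(out) <- c("euler_series", class(out))
  out
}

#' Euler-Rodrigues axis from two reference structures
#'
#' Aligns structure `pre` to structure `post` on the body selection, then
#' returns the axis and angle of the domain rotation between them.
#'
#' @param post,pre Structures with identical topology.
#' @param body_selection,domain_selection Selections resolved on `post`.
#' @return List with `axis`, `angle_deg`, `defined`.
#' @export
er_axis_from_structures <- function(post, pre, body_selection,
                                    domain_selection) {
  body <- select_atoms(post, body_selection)
  dom <- select_atoms(post, domain_selection)
  fit_body <- kabsch_fit(post, pre, body)
  pre_aligned <- apply_fit(fit_body, coords(pre))
  # orientation change of the domain: post -> aligned pre
  fit_dom <- kabsch_fit(pre_aligned[dom, , drop = FALSE],
                        coords(post)[dom, , drop = FALSE])
  er_axis_angle(diag(3), fit_dom$rotation)
}

#' Per-residue average spatial deviation
#'
#' For each frame, the domain is superposed onto the reference using
#' `fit_selection` (default: the domain's C-alpha atoms), and the deviation
#' of each residue's representative atom from its reference position is
#' recorded; values are averaged over frames. Aligning the domain onto
#' itself measures intramolecular deformation, not rigid-body motion.
#'
#' @param traj An `sbm_trajectory`.
#' @param reference Reference structure.
#' @param domain_selection Selection (string or indices) of the analysed
#'   domain.
#' @param fit_selection Selection used for the superposition (default:
#'   C-alpha atoms of the domain).
#' @param representative Atom name used per residue (default `"CA"`), or
#'   `"all"` to average over all domain atoms of the residue.
#' @return An `asd_profile` tibble: `chain`, `resid`, `resname`, `asd`.
#' @export
asd_per_residue <- function(traj, reference, domain_selection,
                            fit_selection = NULL, representative = "CA") {
  dom <- if (is.character(domain_selection)) {
    select_atoms(reference, domain_selection)
  } else as.integer(domain_selection)
  fit_idx <- if (is.null(fit_selection)) {
    dom[reference$name[dom] == "CA"]
  } else if (is.character(fit_selection)) {
    select_atoms(reference, fit_selection)
  } else as.integer(fit_selection)
  if (length(fit_idx) < 3) abort("fit selection needs at least 3 atoms")
  nf <- dim(traj$frames)[1]
  if (nf < 1) abort("trajectory has no frames")
  rep_idx <- if (identical(representative, "all")) {
    dom
  } else {
    dom[reference$name[dom] == representative]
  }
  if (length(rep_idx) == 0) abort("no representative atoms in the domain")
  ref_xyz <- coords(reference)
  dev_sum <- numeric(length(rep_idx))
  for (fr in seq_len(nf)) {
    xyz <- traj$frames[fr, , ]
    fit <- kabsch_fit(ref_xyz, xyz, fit_idx)
    aligned <- apply_fit(fit, xyz)
    dev_sum <- dev_sum +
      sqrt(rowSums((aligned[rep_idx, , drop = FALSE] -
                    ref_xyz[rep_idx, , drop = FALSE])^2))
  }
  per_atom <- tibble::tibble(
    chain = reference$chain[rep_idx],
    resid = reference$resid[rep_idx],
    resname = reference$resname[rep_idx],
    dev = dev_sum / nf
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_atom, .data$chain, .data$resid, .data$resname),
    asd = mean(.data$dev), .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$chain, .data$resid)
  class(out) <- c("asd_profile", class(out))
  out
}

#' Free energy as a function of tilt angle
#'
#' Histograms the tilt samples and applies Boltzmann inversion,
#' `F(theta) = -T ln P(theta)`, reported in units of k_B T and shifted so
#' the minimum over occupied bins is zero. Empty bins are undefined (`NA`),
#' not zero. An optional Jacobian correction divides `P` by `sin(theta)`.
#'
#' @param theta Tilt angles in degrees (e.g. the `theta` column of
#'   [rotation_tilt_timeseries()] output), or a data frame holding one.
#' @param temperature Reduced temperature the samples were generated at.
#' @param bin_width Bin width, degrees.
#' @param jacobian Divide the histogram density by `sin(theta)` before
#'   inversion.
#' @return An `fes_profile` tibble: `theta_mid` (deg), `count`,
#'   `free_energy_kT` and `free_energy` (eps units); attribute
#'   `temperature`.
#' @export
free_energy_vs_tilt <- function(theta, temperature = 0.5, bin_width = 1,
                                jacobian = FALSE) {
  if (is.data.frame(theta)) theta <- theta$theta
  theta <- theta[is.finite(theta)]
  if (length(theta) < 1) abort("need at least one tilt sample")
  if (temperature <= 0) abort("temperature must be positive")
  breaks <- seq(0, max(theta) + bin_width, by = bin_width)
  h <- graphics::hist(theta, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  if (jacobian) {
    jac <- sin(rad(pmax(h$mids, 1e-6)))
    p <- ifelse(p > 0, p / jac, 0)
  }
  f_kt <- ifelse(p > 0, -log(p), NA_real_)
  f_kt <- f_kt - min(f_kt, na.rm = TRUE)
  if (sum(p > 0) == 1) {
    warn("all tilt samples fall in a single bin; profile defined at one bin")
  }
  out <- tibble::tibble(theta_mid = h$mids, count = h$counts,
                        free_energy_kT = f_kt,
                        free_energy = f_kt * temperature)
  attr(out, "temperature") <- temperature
  class(out) <- c("fes_profile", class(out))
  out
}
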