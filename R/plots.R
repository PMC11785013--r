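#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a per-residue average spatial deviation profile
#'
#' @param object An `asd_profile` from [asd_per_residue()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.asd_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$resid, y = .data$asd)) +
    geom_line(colour = "grey40") +
    geom_point(size = 1) +
    labs(x = "Residue", y = "Average spatial deviation (Å)") +
    theme_minimal()
}

#' Plot a free-energy-vs-tilt profile
#'
#' @param object An `fes_profile` from [free_energy_vs_tilt()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fes_profile <- function(object, ...) {
  ggplot(object[!is.na(object$free_energy_kT), ],
         aes(x = .data$theta_mid, y = .data$free_energy_kT)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "Tilt angle θ (deg)",
         y = expression("Free energy (" * k[B] * "T)")) +
    theme_minimal()
}

#' Plot rotation/tilt samples
#'
#' @param object An `euler_series` from [rotation_tilt_timeseries()].
#' @param ... Unused.
#' @return A ggplot of tilt versus rotation angle per frame.
#' @export
autoplot.euler_series <- function(object, ...) {
  ggplot(object, aes(x = .data$gamma, y = .data$theta)) +
    geom_point(alpha = 0.4, size = 0.8) +
    labs(x = "Rotation γ (deg)", y = "Tilt θ (deg)") +
    theme_minimal()
}
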