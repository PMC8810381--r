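#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot phase-averaged Euler angles
#'
#' @param object tibble from [phase_average()].
#' @param ... unused.
#' @return a ggplot: the three Euler angles versus cycle phase t/T.
#' @export
autoplot.bw_angles <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("theta", "phi", "psi"),
                              names_to = "angle", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$value,
                                     colour = .data$angle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t/T", y = "angle (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an averaged wingbeat's Euler angles
#'
#' @param avg tibble from [phase_average()].
#' @return a ggplot.
#' @export
plot_angles <- function(avg) {
  class(avg) <- c("bw_angles", class(avg))
  autoplot.bw_angles(avg)
}

#' Plot the power budget over the cycle
#'
#' @param object a `power_breakdown`.
#' @param ... unused.
#' @return a ggplot of aerodynamic, inertial and total body-mass-specific
#'   power versus time.
#' @export
autoplot.power_breakdown <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series, c("p_aero", "p_inert", "p_total"),
                              names_to = "component", values_to = "power")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$power,
                                     colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (ms)", y = "body-mass-specific power (W/kg)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot body-pitch trajectories with and without elytra recoil
#'
#' @param object a `pitch_dynamics` result.
#' @param ... unused.
#' @return a ggplot of the two chi trajectories.
#' @export
autoplot.pitch_dynamics <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trajectories,
                              c("chi_with", "chi_without"),
                              names_to = "scenario", values_to = "chi")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$chi,
                                     colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(labels = c(chi_with = "with elytra recoil",
                                              chi_without = "without")) +
    ggplot2::labs(x = "t (ms)", y = "body pitch chi (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-part vertical-force account
#'
#' @param object a `vertical_breakdown`.
#' @param ... unused.
#' @return a ggplot bar chart of weight-equivalent vertical force per part.
#' @export
autoplot.vertical_breakdown <- function(object, ...) {
  ggplot2::ggplot(object$per_part,
                  ggplot2::aes(x = .data$part, y = .data$weight_equiv)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "cycle-mean vertical force (ug weight-equivalent)") +
    ggplot2::theme_minimal()
}

#' Plot the wing-tip trajectory in the sagittal projection
#'
#' @param kin tibble from [derive_kinematics()] (the Rg-point path), or
#'   any tibble with `x`, `z` columns in um.
#' @return a ggplot of the path in the x-z plane, coloured by phase;
#'   the figure-of-eight self-intersection is visible here.
#' @export
plot_tip_path <- function(kin) {
  ggplot2::ggplot(kin, ggplot2::aes(x = .data$x, y = .data$z,
                                    colour = .data$phase)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "z (um)", colour = "t/T") +
    ggplot2::theme_minimal()
}
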