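#' Inertial power of a rigid flapping wing
#'
#' Rate of change of rotational kinetic energy of the rigid wing about
#' its base: `P_inert = omega . (I alpha + omega x (I omega))`, with the
#' inertia tensor and the angular velocity/acceleration expressed in the
#' wing-fixed frame (the base frame the tensor was computed in). The
#' gyroscopic term contributes no power analytically but is retained for
#' fidelity to the torque expression.
#'
#' @param mass_props [mass_properties()] of the wing about its base, in
#'   wing-local axes.
#' @param omega n x 3 matrix (or data frame with columns `wlx, wly,
#'   wlz`) of wing-local angular velocity (rad/ms).
#' @param t sample times (ms).
#' @param alpha optional matching angular acceleration (rad/ms^2);
#'   computed by spline differentiation of `omega` when omitted
#'   (periodically when `periodic = TRUE`).
#' @param periodic whether the series covers exact periods (the last
#'   sample is the one just before the period closes).
#' @return tibble with `t` and `p_inert` (ug um^2/ms^3 = pW).
#' @export
inertial_power <- function(mass_props, omega, t, alpha = NULL, periodic = TRUE) {
  stopifnot(inherits(mass_props, "mass_properties"))
  w <- omega_matrix(omega, frame = "local")
  n <- nrow(w)
  stopifnot(length(t) == n)
  if (is.null(alpha)) {
    alpha <- matrix(0, n, 3)
    if (periodic) {
      Tt <- (t[2] - t[1]) * n # grid step times count = period
      ph <- (t - t[1]) / Tt
      # band-limit omega with the same filter used for its spectral
      # derivative, so that P = omega . I alpha is exactly the rate of
      # change of the kinetic energy of the (band-limited) motion and
      # its cycle integral vanishes to round-off
      for (k in 1:3) {
        alpha[, k] <- periodic_deriv(ph, w[, k]) / Tt
        w[, k] <- periodic_bandlimit(ph, w[, k])
      }
    } else {
      for (k in 1:3) alpha[, k] <- stats::splinefun(t, w[, k], method = "fmm")(t, deriv = 1)
    }
  } else {
    alpha <- omega_matrix(alpha, frame = "local")
  }
  I <- mass_props$inertia
  Iw <- w %*% I
  Ia <- alpha %*% I
  gyro <- cbind(w[, 2] * Iw[, 3] - w[, 3] * Iw[, 2],
                w[, 3] * Iw[, 1] - w[, 1] * Iw[, 3],
                w[, 1] * Iw[, 2] - w[, 2] * Iw[, 1])
  p <- rowSums(w * (Ia + gyro))
  tibble::tibble(t = t, p_inert = p)
}

omega_matrix <- function(omega, frame = c("local", "lab")) {
  if (is.matrix(omega)) return(omega)
  frame <- match.arg(frame)
  nm <- names(omega)
  sets <- list(local = c("wlx", "wly", "wlz"), lab = c("wx", "wy", "wz"))
  # preferred frame first, the other as fallback for plain series
  for (set in sets[c(frame, setdiff(names(sets), frame))]) {
    if (all(set %in% nm)) return(as.matrix(omega[, set]))
  }
  stop("omega must be an n x 3 matrix or have wx/wy/wz (or wlx/wly/wlz) columns",
       call. = FALSE)
}

#' Aerodynamic power of a flapping part
#'
#' Mechanical power the part delivers to the air: `P_aero = -tau_b .
#' omega`, with `tau_b` the aerodynamic torque about the part's base
#' pivot and `omega` the lab-frame angular velocity of the rigid part.
#' Positive values mean the wing does work on the air.
#'
#' @param forces force tibble whose torque columns (`tx, ty, tz`) are
#'   about the wing base (see the `reference` attribute).
#' @param omega n x 3 matrix or data frame with `wx, wy, wz` (rad/ms,
#'   lab frame).
#' @return tibble with `t` and `p_aero` (ug um^2/ms^3 = pW).
#' @export
aerodynamic_power <- function(forces, omega) {
  ref <- attr(forces, "reference")
  if (!is.null(ref) && !identical(ref, "wing_base")) {
    warning("torque reference is '", ref, "', expected 'wing_base'")
  }
  w <- omega_matrix(omega, frame = "lab")
  stopifnot(nrow(w) == nrow(forces))
  p <- -(forces$tx * w[, 1] + forces$ty * w[, 2] + forces$tz * w[, 3])
  tibble::tibble(t = forces$t, p_aero = p)
}

#' Power budget with elastic-storage scenarios
#'
#' Combines aerodynamic and inertial power into a body-mass-specific
#' budget (W per kg body mass) and evaluates the two elastic-storage
#' scenarios: without elastic storage the muscles cannot absorb negative
#' power, so the required mean is `mean(max(P_total, 0))`; with perfect
#' elastic storage all negative power is recovered, giving `mean(
#' P_total)`. When the total power remains positive during the entire
#' cycle the two coincide and elastic storage is obsolete - the
#' bristled-wing situation.
#'
#' @param p_aero,p_inert power series (ug um^2/ms^3) on a common grid,
#'   as from [aerodynamic_power()] and [inertial_power()]; numeric
#'   vectors or tibbles with `p_aero`/`p_inert` columns.
#' @param body_mass body mass (ug).
#' @param t sample times (ms); taken from `p_aero` when it is a tibble.
#' @return object of class `power_breakdown` with the specific series
#'   and scenario statistics; see [tidy.power_breakdown()].
#' @export
power_breakdown <- function(p_aero, p_inert, body_mass, t = NULL) {
  if (is.data.frame(p_aero)) {
    t <- t %||% p_aero$t
    p_aero <- p_aero$p_aero
  }
  if (is.data.frame(p_inert)) p_inert <- p_inert$p_inert
  stopifnot(length(p_aero) == length(p_inert), body_mass > 0)
  if (is.null(t)) t <- seq_along(p_aero)
  to_wkg <- function(p) specific_power_internal_to_si(p / body_mass)
  pa <- to_wkg(p_aero); pi_ <- to_wkg(p_inert)
  pt <- pa + pi_
  structure(
    list(series = tibble::tibble(t = t, p_aero = pa, p_inert = pi_, p_total = pt),
         scenarios = power_scenarios(pt),
         body_mass = body_mass),
    class = "power_breakdown"
  )
}

#' @rdname power_breakdown
#' @param p_total numeric total-power series over one full cycle (any
#'   unit; statistics come back in the same unit).
#' @return for `power_scenarios()`: one-row tibble with `mean_no_storage`,
#'   `mean_perfect_storage`, `peak`, `min` and the `always_positive` flag.
#' @export
power_scenarios <- function(p_total) {
  if (is.data.frame(p_total)) p_total <- p_total$p_total
  tibble::tibble(
    mean_no_storage = mean(pmax(p_total, 0)),
    mean_perfect_storage = mean(p_total),
    peak = max(p_total),
    min = min(p_total),
    always_positive = min(p_total) >= 0
  )
}

#' @export
print.power_breakdown <- function(x, ...) {
  s <- x$scenarios
  cat(sprintf("<power_breakdown> body-mass-specific power (W/kg):\n"))
  cat(sprintf("  mean %.3g (no storage) / %.3g (perfect storage), peak %.3g\n",
              s$mean_no_storage, s$mean_perfect_storage, s$peak))
  cat(sprintf("  total power %s during the cycle\n",
              if (s$always_positive) "remains positive" else "goes negative"))
  invisible(x)
}

#' Tidy a power breakdown
#'
#' @param x a `power_breakdown` object.
#' @param ... unused.
#' @return `tidy()`: the specific power series (W/kg); `glance()`: the
#'   scenario statistics with peaks of each component.
#' @export
tidy.power_breakdown <- function(x, ...) x$series

#' @rdname tidy.power_breakdown
#' @export
glance.power_breakdown <- function(x, ...) {
  dplyr::bind_cols(
    x$scenarios,
    tibble::tibble(
      mean_aero = mean(x$series$p_aero),
      mean_inert = mean(x$series$p_inert),
      peak_aero = max(x$series$p_aero),
      peak_inert_abs = max(abs(x$series$p_inert))
    )
  )
}
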