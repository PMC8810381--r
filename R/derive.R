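#' Fluid properties of air
#'
#' @param density air density (kg/m^3); default 1.197 (air at 25 C).
#' @param viscosity kinematic viscosity (m^2/s); default 1.54e-5.
#' @return object of class `fluid_properties` holding both SI and
#'   internal-unit values.
#' @export
fluid_properties <- function(density = 1.197, viscosity = 1.54e-5) {
  stopifnot(density > 0, viscosity > 0)
  structure(
    list(rho_si = density, nu_si = viscosity,
         rho = density_si_to_internal(density),
         nu = viscosity_si_to_internal(viscosity)),
    class = "fluid_properties"
  )
}

# Derivative of a 1-periodic signal sampled on a uniform phase grid,
# evaluated on its own grid, by spectral (FFT) differentiation.
# Two safeguards for estimated cycle data (e.g. noisy phase averages),
# which is not exactly periodic at the wrap point:
# * the seam jump - estimated from the second difference across the
#   wrap, which is O(h^2) for smooth periodic data - is removed as a
#   linear ramp before transforming;
# * harmonics above `max_harmonics` are discarded; phase averages of
#   video-rate recordings carry no legitimate content beyond the
#   per-cycle Nyquist of the original sampling, while the spurious seam
#   kink lives at the highest frequencies.
periodic_deriv <- function(phase, y, deriv = 1, max_harmonics = 16) {
  n <- length(y)
  jump <- (y[1] - y[n]) - (y[n] - y[n - 1])
  y <- y + jump * (seq_len(n) - 1) / n
  co <- stats::fft(y)
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  if (!is.null(max_harmonics)) co[abs(k) > max_harmonics] <- 0
  if (n %% 2 == 0) co[n / 2 + 1] <- 0 # unmatched Nyquist bin
  for (d in seq_len(deriv)) co <- co * (2i * pi * k)
  Re(stats::fft(co, inverse = TRUE)) / n
}

# band-limit a 1-periodic sampled signal with the same conventions as
# periodic_deriv (seam-jump ramp removal, harmonic truncation)
periodic_bandlimit <- function(phase, y, max_harmonics = 16) {
  n <- length(y)
  jump <- (y[1] - y[n]) - (y[n] - y[n - 1])
  ramp <- jump * (seq_len(n) - 1) / n
  y2 <- y + ramp
  co <- stats::fft(y2)
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  if (!is.null(max_harmonics)) co[abs(k) > max_harmonics] <- 0
  Re(stats::fft(co, inverse = TRUE)) / n
}

#' Kinematic derivatives: wing speed, angle of attack, Reynolds number
#'
#' From one phase-averaged wingbeat of Euler angles, computes for every
#' phase-grid point the wing angular velocity, the position and velocity
#' of the radius-of-gyration point on the span line, the geometric angle
#' of attack, and the instantaneous Reynolds number, plus the
#' cycle-averaged Reynolds number based on the mean speed at the radius
#' of gyration.
#'
#' The angle of attack is the angle between the wing chord plane and the
#' velocity direction at Rg: 0 deg for edge-on (feathered) motion, 90
#' deg for flat-on motion, signed by the chordwise velocity component
#' (so one stroke direction plots negative). At samples where the speed
#' vanishes the angle of attack is undefined and reported as `NA` with
#' the `gap` flag set; it is never interpolated.
#'
#' @param avg phase-averaged angles: tibble with `phase`, `theta`,
#'   `phi`, `psi` on a uniform phase grid (see [phase_average()]).
#' @param frame the [stroke_frame()] of the part.
#' @param planform one-row planform tibble from [wing_planform()].
#' @param fluid a [fluid_properties()] object.
#' @param f wingbeat frequency (kHz); default taken from the `f`
#'   attribute of `avg`.
#' @param speed_tol speed (um/ms) below which the sample is flagged as a
#'   zero-velocity gap.
#' @return tibble with columns `phase`, `t` (ms), the angles, angular
#'   velocity `wx, wy, wz` (rad/ms), Rg-point velocity `vx, vy, vz` and
#'   `speed` (um/ms), `speed_si` (m/s), signed `aoa` (deg), `re`, and
#'   `gap`; attributes `re_mean`, `re_peak`, `f`, `planform`, `fluid`,
#'   `frame`.
#' @export
derive_kinematics <- function(avg, frame, planform, fluid = fluid_properties(),
                              f = attr(avg, "f"), speed_tol = 1e-9) {
  stopifnot(inherits(frame, "stroke_frame"), inherits(fluid, "fluid_properties"))
  if (is.null(f)) stop("wingbeat frequency `f` is required (kHz)", call. = FALSE)
  phase <- avg$phase
  if (max(abs(diff(phase) - (phase[2] - phase[1]))) > 1e-9) {
    stop("`avg` must be on a uniform phase grid", call. = FALSE)
  }
  Tms <- 1 / f
  # angle rates in deg/ms: d/dt = f * d/dphase
  dth <- periodic_deriv(phase, avg$theta) * f
  dph <- periodic_deriv(phase, avg$phi) * f
  dps <- periodic_deriv(phase, avg$psi) * f
  w <- wing_angular_velocity(avg$theta, avg$phi, avg$psi, dth, dph, dps, frame)
  pose <- pose_from_angles(avg, frame, span = planform$Rg)
  rx <- pose$tipx - frame$origin[1]
  ry <- pose$tipy - frame$origin[2]
  rz <- pose$tipz - frame$origin[3]
  vx <- w[, "wy"] * rz - w[, "wz"] * ry
  vy <- w[, "wz"] * rx - w[, "wx"] * rz
  vz <- w[, "wx"] * ry - w[, "wy"] * rx
  speed <- sqrt(vx^2 + vy^2 + vz^2)
  gap <- speed < speed_tol
  sin_a <- (vx * pose$wnx + vy * pose$wny + vz * pose$wnz) / speed
  chordwise <- vx * pose$cx + vy * pose$cy + vz * pose$cz
  aoa <- rad2deg(asin(pmax(-1, pmin(1, abs(sin_a))))) *
    ifelse(chordwise >= 0, 1, -1)
  aoa[gap] <- NA_real_
  re <- speed * planform$cbar / fluid$nu
  # angular velocity in wing-local axes (span, chord, normal)
  wlx <- pose$sx * w[, "wx"] + pose$sy * w[, "wy"] + pose$sz * w[, "wz"]
  wly <- pose$cx * w[, "wx"] + pose$cy * w[, "wy"] + pose$cz * w[, "wz"]
  wlz <- pose$wnx * w[, "wx"] + pose$wny * w[, "wy"] + pose$wnz * w[, "wz"]
  out <- tibble::tibble(
    phase = phase, t = phase * Tms,
    theta = avg$theta, phi = avg$phi, psi = avg$psi,
    wx = w[, "wx"], wy = w[, "wy"], wz = w[, "wz"],
    wlx = wlx, wly = wly, wlz = wlz,
    x = pose$tipx, y = pose$tipy, z = pose$tipz,
    vx = vx, vy = vy, vz = vz,
    speed = speed, speed_si = speed_internal_to_si(speed),
    sx = pose$sx, sy = pose$sy, sz = pose$sz,
    cx = pose$cx, cy = pose$cy, cz = pose$cz,
    wnx = pose$wnx, wny = pose$wny, wnz = pose$wnz,
    aoa = aoa, re = re, gap = gap
  )
  attr(out, "re_mean") <- mean(speed) * planform$cbar / fluid$nu
  attr(out, "re_peak") <- max(re)
  attr(out, "f") <- f
  attr(out, "planform") <- planform
  attr(out, "fluid") <- fluid
  attr(out, "frame") <- frame
  out
}

#' Body speed from a centre-of-body track
#'
#' Finite-difference velocity of the tracked body centre, smoothed
#' component-wise by loess against time. The smoothed horizontal and
#' vertical speed components are reported in both internal units and
#' m/s.
#'
#' @param track data frame with columns `t` (ms) and `x`, `y`, `z` (um,
#'   lab frame, z up).
#' @param loess_span loess smoothing span (fraction of the series).
#' @return tibble with raw (`vx, vy, vz`) and smoothed (`vx_s, vy_s,
#'   vz_s`) velocity components (um/ms), `horizontal` and `vertical`
#'   smoothed components, and `horizontal_si`/`vertical_si` (m/s).
#' @export
body_speed <- function(track, loess_span = 0.25) {
  t <- track$t
  if (length(t) < 10) stop("need at least 10 track samples", call. = FALSE)
  fd <- function(p) {
    n <- length(p)
    v <- numeric(n)
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    v[1] <- (p[2] - p[1]) / (t[2] - t[1])
    v[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
    v
  }
  sm <- function(v) {
    fit <- stats::loess(v ~ t, span = loess_span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    unname(stats::predict(fit, newdata = data.frame(t = t)))
  }
  vx <- fd(track$x); vy <- fd(track$y); vz <- fd(track$z)
  vx_s <- sm(vx); vy_s <- sm(vy); vz_s <- sm(vz)
  tibble::tibble(
    t = t, vx = vx, vy = vy, vz = vz,
    vx_s = vx_s, vy_s = vy_s, vz_s = vz_s,
    horizontal = sqrt(vx_s^2 + vy_s^2), vertical = vz_s,
    horizontal_si = speed_internal_to_si(sqrt(vx_s^2 + vy_s^2)),
    vertical_si = speed_internal_to_si(vz_s)
  )
}

#' Minimum blade-tip separation during claps
#'
#' Distance between left and right wing (blade) tips, minimised over the
#' given phase windows (e.g. the ventral clap). Windows may wrap around
#' phase 1.
#'
#' @param left,right tibbles on a common `phase` grid with tip
#'   coordinate columns `tipx, tipy, tipz` (as from
#'   [pose_from_angles()]).
#' @param windows list of length-2 numeric vectors `c(lo, hi)` of phase
#'   in [0, 1); `lo > hi` denotes a window wrapping through 0. `NULL`
#'   uses the whole cycle.
#' @return one-row tibble with `distance` (um) and `phase` at the
#'   minimum.
#' @export
clap_distance <- function(left, right, windows = NULL) {
  if (nrow(left) != nrow(right) || max(abs(left$phase - right$phase)) > 1e-9) {
    stop("left and right poses must share the same phase grid", call. = FALSE)
  }
  d <- sqrt((left$tipx - right$tipx)^2 + (left$tipy - right$tipy)^2 +
              (left$tipz - right$tipz)^2)
  ph <- left$phase
  keep <- rep(is.null(windows), length(ph))
  if (!is.null(windows)) {
    for (w in windows) {
      keep <- keep | (if (w[1] <= w[2]) ph >= w[1] & ph <= w[2] else ph >= w[1] | ph <= w[2])
    }
  }
  if (!any(keep)) stop("no phase samples inside the clap windows", call. = FALSE)
  i <- which(keep)[which.min(d[keep])]
  tibble::tibble(distance = d[i], phase = ph[i])
}
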