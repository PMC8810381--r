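#' Body model for pitch dynamics
#'
#' @param mass body mass m_b (ug), > 0.
#' @param inertia pitch-axis moment of inertia I_b (ug um^2), > 0. Not
#'   printed for most study animals; a slender-body estimate
#'   `m L^2 / 12` is a reasonable default source.
#' @param com body centre of mass (um, lab frame).
#' @param g gravitational acceleration (um/ms^2).
#' @return object of class `body_model`.
#' @export
body_model <- function(mass, inertia, com = c(0, 0, 0), g = 9.81) {
  stopifnot(mass > 0, inertia > 0, g > 0)
  structure(list(mass = mass, inertia = inertia, com = as.numeric(com), g = g),
            class = "body_model")
}

# periodic interpolant of a cyclic series sampled on phase in [0, 1)
periodic_interp <- function(phase, y) {
  x3 <- c(phase - 1, phase, phase + 1)
  f <- stats::splinefun(x3, rep(y, 3), method = "fmm")
  function(p) f(p - floor(p))
}

#' Recoil torque of an oscillating appendage
#'
#' The inertial reaction an accelerating appendage (e.g. an elytron)
#' exerts on the body: minus the rate of change of the appendage's
#' angular momentum, `-d/dt (I omega)`, with the angular momentum
#' evaluated in the lab frame (`H = R I_local omega_local`). The pitch
#' (lab y) component is the one that brakes body-pitch oscillation;
#' lateral components cancel between bilateral appendage pairs.
#'
#' @param kin [derive_kinematics()] tibble for the appendage (provides
#'   the rotation and local angular velocity per phase sample).
#' @param mass_props appendage [mass_properties()] about its base in
#'   appendage-local axes.
#' @return tibble with `phase`, `t`, the lab-frame recoil torque
#'   components `rx, ry, rz` (ug um^2/ms^2) and `ty = ry` for
#'   convenience.
#' @export
recoil_torque <- function(kin, mass_props) {
  stopifnot(inherits(mass_props, "mass_properties"))
  n <- nrow(kin)
  I <- mass_props$inertia
  H <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R <- cbind(c(kin$sx[i], kin$sy[i], kin$sz[i]),
               c(kin$cx[i], kin$cy[i], kin$cz[i]),
               c(kin$wnx[i], kin$wny[i], kin$wnz[i]))
    wl <- c(kin$wlx[i], kin$wly[i], kin$wlz[i])
    H[i, ] <- R %*% (I %*% wl)
  }
  f <- attr(kin, "f")
  Tms <- 1 / f
  dH <- matrix(0, n, 3)
  for (k in 1:3) dH[, k] <- periodic_deriv(kin$phase, H[, k]) / Tms
  tibble::tibble(phase = kin$phase, t = kin$t,
                 rx = -dH[, 1], ry = -dH[, 2], rz = -dH[, 3],
                 ty = -dH[, 2])
}

#' Single-axis body-pitch simulation with and without elytra recoil
#'
#' Integrates the torque balance `I_b chi'' = tau_aero(t) +
#' tau_recoil(t)` about the pitch axis with a fixed-step classical
#' Runge-Kutta scheme (via `deSolve::rk4`), over `cycles` wingbeat
#' cycles of the periodic torque inputs. The same integration with the
#' recoil term zeroed gives the "without elytra" trajectory (the elytra
#' aerodynamic torque, which is negligible, stays in `tau_aero` unless
#' the caller removes it). The first cycle is discarded as a transient;
#' the remaining trajectory is detrended linearly (an undamped double
#' integrator accumulates a constant drift from the start-up) and
#' peak-to-peak amplitudes and their ratio are reported.
#'
#' Sign convention: torque about the lab y axis, nose-down positive.
#'
#' @param aero_torque tibble with `phase` and `ty`: total aerodynamic
#'   pitch torque about the body centre of mass, one cycle on a uniform
#'   phase grid (or a list of such tibbles, summed).
#' @param recoil tibble with `phase` and `ty`: elytra recoil torque, as
#'   from [recoil_torque()]; `NULL` for none.
#' @param body a [body_model()].
#' @param f wingbeat frequency (kHz).
#' @param cycles number of cycles to integrate (>= 2; >= 5 recommended).
#' @param steps_per_cycle integration steps per cycle; defaults to the
#'   torque grid resolution.
#' @param periodicity_tol relative cycle-boundary mismatch of the
#'   torque inputs above which a warning is issued (the series is still
#'   wrapped periodically).
#' @param trim_mean subtract the cycle-mean of the aerodynamic torque
#'   before integrating (default `TRUE`). A hovering animal is trimmed
#'   on average; a residual mean in a prescribed one-cycle torque would
#'   otherwise accumulate an unbounded quadratic drift in the undamped
#'   single-axis model, swamping the oscillation the simulation is
#'   meant to measure.
#' @return object of class `pitch_dynamics`: trajectories (deg),
#'   peak-to-peak amplitudes with and without recoil (deg), and their
#'   percentage ratio.
#' @export
pitch_simulation <- function(aero_torque, recoil = NULL, body, f,
                             cycles = 6, steps_per_cycle = NULL,
                             periodicity_tol = 0.05, trim_mean = TRUE) {
  stopifnot(inherits(body, "body_model"), cycles >= 2, f > 0)
  if (is.data.frame(aero_torque)) aero_torque <- list(aero_torque)
  phase <- aero_torque[[1]]$phase
  ty <- rowSums(vapply(aero_torque, function(a) a$ty, numeric(length(phase))))
  if (trim_mean) ty <- ty - mean(ty)
  check_periodic <- function(y, label) {
    scale <- max(abs(y), 1e-300)
    # seam jump compared against both the overall scale and the typical
    # adjacent-sample jump (so noisy-but-periodic series do not trip it)
    mism <- abs(y[1] - y[length(y)])
    typical <- stats::median(abs(diff(y)))
    if (mism > max(periodicity_tol * scale, 5 * typical)) {
      warning(label, " torque series is not cycle-periodic (boundary mismatch ",
              signif(mism / scale, 3),
              " relative); it is wrapped periodically anyway")
    }
  }
  check_periodic(ty, "aerodynamic")
  tau_aero <- periodic_interp(phase, ty)
  tau_rec <- function(p) 0
  if (!is.null(recoil)) {
    check_periodic(recoil$ty, "recoil")
    tau_rec <- periodic_interp(recoil$phase, recoil$ty)
  }
  Tms <- 1 / f
  n_steps <- steps_per_cycle %||% length(phase)
  times <- seq(0, cycles * Tms, by = Tms / n_steps)
  integrate_chi <- function(with_recoil) {
    rhs <- function(t, y, parms) {
      p <- t / Tms
      tau <- tau_aero(p) + if (with_recoil) tau_rec(p) else 0
      list(c(y[2], tau / body$inertia))
    }
    sol <- deSolve::rk4(c(chi = 0, dchi = 0), times, rhs, parms = NULL)
    sol[, "chi"]
  }
  chi_with <- integrate_chi(TRUE)
  chi_without <- integrate_chi(FALSE)
  # discard the first cycle as transient, then remove the start-up
  # drift: a line fitted through the per-cycle means (the cycle mean of
  # the periodic component is constant, so the line captures exactly
  # the linear drift of the undamped double integrator)
  p2p <- function(chi) {
    idx <- which(times >= Tms - 1e-12)
    ncyc <- cycles - 1
    per <- n_steps
    use <- idx[seq_len(ncyc * per)]
    cyc_id <- rep(seq_len(ncyc), each = per)
    mids <- tapply(times[use], cyc_id, mean)
    means <- tapply(chi[use], cyc_id, mean)
    if (length(mids) > 1) {
      fit <- stats::lm(means ~ mids)
      trend <- stats::coef(fit)[1] + stats::coef(fit)[2] * times[use]
    } else {
      trend <- means[1]
    }
    diff(range(chi[use] - trend))
  }
  amp_with <- rad2deg(p2p(chi_with))
  amp_without <- rad2deg(p2p(chi_without))
  structure(
    list(
      trajectories = tibble::tibble(
        t = times, phase = (times / Tms) %% 1,
        chi_with = rad2deg(chi_with), chi_without = rad2deg(chi_without)
      ),
      torque = tibble::tibble(phase = phase, aero = ty,
                              recoil = if (is.null(recoil)) 0 else recoil$ty),
      amplitude_with = amp_with,
      amplitude_without = amp_without,
      amplitude_ratio = 100 * amp_with / amp_without,
      f = f, cycles = cycles, body = body
    ),
    class = "pitch_dynamics"
  )
}

#' @export
print.pitch_dynamics <- function(x, ...) {
  cat(sprintf("<pitch_dynamics> peak-to-peak body pitch: %.3g deg with recoil, %.3g deg without\n",
              x$amplitude_with, x$amplitude_without))
  cat(sprintf("  amplitude ratio %.1f%% (recoil reduces pitch oscillation by %.1f%%)\n",
              x$amplitude_ratio, 100 - x$amplitude_ratio))
  invisible(x)
}

#' Tidy pitch-dynamics results
#'
#' @param x a `pitch_dynamics` object.
#' @param ... unused.
#' @return `tidy()`: the chi trajectories (deg); `glance()`: amplitudes
#'   and their ratio.
#' @export
tidy.pitch_dynamics <- function(x, ...) x$trajectories

#' @rdname tidy.pitch_dynamics
#' @export
glance.pitch_dynamics <- function(x, ...) {
  tibble::tibble(
    amplitude_with = x$amplitude_with,
    amplitude_without = x$amplitude_without,
    amplitude_ratio = x$amplitude_ratio
  )
}
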