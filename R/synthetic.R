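#' Synthetic wingbeat protocol specification
#'
#' Parameters of the seed-deterministic kinematics generator. The
#' default protocol emulates the wingbeat of a miniature featherwing
#' beetle hovering slowly: a large-amplitude positional sweep in a
#' stroke plane pitched to the horizon, a double-frequency stroke
#' deviation that turns the tip path into a self-intersecting
#' figure-of-eight, near-claps above and below the body at the stroke
#' reversals, fast flat-on power strokes (where the angle of attack
#' peaks) separated by slow feathered recovery phases, and elytra
#' whose pitch oscillates in antiphase to the wing sweep. The
#' down-moving half stroke is faster than the up-moving one (second
#' positional harmonic), which is what gives the cycle its net upward
#' drag-based force.
#'
#' Angles are finite Fourier series in the cycle phase x = t/T (at most
#' 8 harmonics), so generated protocols are exactly T-periodic. The
#' wingbeat frequency may be left `NULL`, in which case
#' [make_protocol()] calibrates it so that the cycle-averaged Reynolds
#' number equals `target_re` (about 9 for this flow regime); the
#' positional amplitude is likewise calibrated so the ventral near-clap
#' reaches `clap_gap`.
#'
#' @param f wingbeat frequency (kHz) or `NULL` to calibrate.
#' @param target_re cycle-averaged Reynolds number used when `f` is
#'   `NULL`.
#' @param n_cycles number of wingbeat cycles to generate.
#' @param sample_dt sampling step (ms); the default emulates a
#'   high-speed camera at 3,845 frames per second.
#' @param noise_sd i.i.d. Gaussian noise s.d. added to every angle
#'   sample (deg), emulating manual frame-by-frame pose registration
#'   error.
#' @param seed integer seed; two calls with the same spec are
#'   identical.
#' @param phi_amp positional amplitude (deg) or `NULL` to calibrate
#'   from `clap_gap`.
#' @param clap_gap target minimum blade-tip separation at the ventral
#'   clap (um).
#' @param phi_asym relative second-harmonic content of the positional
#'   angle (down-fast/up-slow asymmetry).
#' @param theta_amp stroke-deviation amplitude (deg), at twice the
#'   wingbeat frequency (the figure-of-eight).
#' @param theta_phase phase (deg) of the stroke-deviation harmonic;
#'   non-zero values keep the deviation rate small at the power-stroke
#'   centres so the angle of attack peaks there.
#' @param psi1,psi2 first/second cosine harmonics of the wing pitch
#'   angle (deg); together they set the flat-on angle of attack of the
#'   two power strokes (about 85 and 73 deg in magnitude).
#' @param beta stroke-plane pitch to the horizon (deg).
#' @param base_sep lateral separation of the wing bases (um).
#' @param power_windows,clap_windows phase windows (fractions of the
#'   cycle) labelling the power strokes and the dorsal/ventral claps;
#'   attached to the output as ground truth.
#' @param elytra list of elytron protocol parameters: `phi_mean`,
#'   `phi_amp` (deg, the open/close sweep), `phi_phase` (rad, phase of
#'   the sweep relative to the wing cycle), `psi_mean`, `psi_amp`
#'   (deg; the pitch oscillation is `-psi_amp * sin(2 pi x)`, in
#'   antiphase to the wing sweep, peak-to-peak about 52 deg).
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(f = NULL, target_re = 9, n_cycles = 4,
                          sample_dt = 1 / 3.845, noise_sd = 1, seed = 1L,
                          phi_amp = NULL, clap_gap = 30, phi_asym = 0.12,
                          theta_amp = 15, theta_phase = 50, psi1 = 86, psi2 = 3,
                          beta = 40, base_sep = 150,
                          power_windows = list(c(0.98, 0.16), c(0.38, 0.62)),
                          clap_windows = list(dorsal = c(0.15, 0.35),
                                              ventral = c(0.65, 0.85)),
                          elytra = list(phi_mean = 25, phi_amp = 40,
                                        phi_phase = 3.92, psi_mean = 20,
                                        psi_amp = 26)) {
  stopifnot(n_cycles >= 1, sample_dt > 0, noise_sd >= 0)
  ok_win <- function(w) all(vapply(w, function(x) all(x >= 0 & x < 1), TRUE))
  stopifnot(ok_win(power_windows), ok_win(clap_windows))
  structure(
    list(f = f, target_re = target_re, n_cycles = n_cycles,
         sample_dt = sample_dt, noise_sd = noise_sd, seed = as.integer(seed),
         phi_amp = phi_amp, clap_gap = clap_gap, phi_asym = phi_asym,
         theta_amp = theta_amp, theta_phase = theta_phase,
         psi1 = psi1, psi2 = psi2,
         beta = beta, base_sep = base_sep,
         power_windows = power_windows, clap_windows = clap_windows,
         elytra = elytra),
    class = "protocol_spec"
  )
}

# finite Fourier series: coef = list(a0, sin = a[1:8], cos = b[1:8])
fourier_eval <- function(coef, x) {
  y <- rep(coef$a0 %||% 0, length(x))
  for (k in seq_along(coef$sin)) y <- y + coef$sin[k] * sin(2 * pi * k * x)
  for (k in seq_along(coef$cos)) y <- y + coef$cos[k] * cos(2 * pi * k * x)
  y
}

fourier_mirror <- function(part_coefs) {
  neg <- function(coef) list(a0 = -(coef$a0 %||% 0), sin = -coef$sin, cos = -coef$cos)
  list(theta = neg(part_coefs$theta), phi = part_coefs$phi,
       psi = neg(part_coefs$psi))
}

# Fourier coefficient tables of the left-side parts implied by a spec
# (phi_amp must be resolved by then)
protocol_coefficients <- function(spec) {
  z <- rep(0, 2)
  el <- spec$elytra
  d <- deg2rad(spec$theta_phase %||% 0)
  list(
    left_wing = list(
      theta = list(a0 = 0,
                   sin = c(0, spec$theta_amp * cos(d)),
                   cos = c(0, spec$theta_amp * sin(d))),
      phi = list(a0 = 0,
                 sin = c(spec$phi_amp, -spec$phi_asym * spec$phi_amp),
                 cos = z),
      psi = list(a0 = 0, sin = z, cos = c(spec$psi1, spec$psi2))
    ),
    left_elytron = list(
      theta = list(a0 = 0, sin = z, cos = z),
      phi = list(a0 = el$phi_mean,
                 sin = c(el$phi_amp * cos(el$phi_phase), 0),
                 cos = c(el$phi_amp * sin(el$phi_phase), 0)),
      psi = list(a0 = el$psi_mean, sin = c(-el$psi_amp, 0), cos = z)
    )
  )
}

# stroke frames of all four parts; the right-side frame of a part is
# (M u, M v, -M n) for the sagittal mirror M, which keeps it
# right-handed and makes the mirror map on angles (theta, phi, psi) ->
# (-theta, phi, -psi)
protocol_frames <- function(spec) {
  b <- deg2rad(spec$beta)
  n_w <- c(sin(b), 0, cos(b))
  half <- spec$base_sep / 2
  mirror <- function(v) c(v[1], -v[2], v[3])
  lw <- stroke_frame(c(0, half, 0), n_w, u = c(0, 1, 0))
  rw <- stroke_frame(c(0, -half, 0), -mirror(n_w), u = c(0, -1, 0))
  le <- stroke_frame(c(-30, 40, 0), c(0, 1, 0), u = c(-1, 0, 0))
  re_ <- stroke_frame(c(-30, -40, 0), -mirror(c(0, 1, 0)), u = c(-1, 0, 0))
  list(left_wing = lw, right_wing = rw, left_elytron = le, right_elytron = re_)
}

#' Generate a synthetic Euler-angle protocol
#'
#' Evaluates the protocol's Fourier series on a video-rate time grid for
#' all four moving parts (left/right wing and elytron), adds i.i.d.
#' Gaussian angle noise, and attaches the generating truth: frequency,
#' cycle boundaries, phase windows, clean-angle evaluators, stroke
#' frames, and the noiseless minimum blade-tip clap separation.
#'
#' When the spec leaves `f` or `phi_amp` unresolved they are calibrated
#' here: `phi_amp` by root-finding on the noiseless ventral tip
#' separation (target `clap_gap`), and `f` linearly from the target
#' cycle-averaged Reynolds number (Re is exactly linear in f for a
#' fixed protocol shape).
#'
#' @param spec a [protocol_spec()].
#' @param planform wing planform tibble (see [wing_planform()]);
#'   required when `f` or `phi_amp` needs calibrating.
#' @param fluid a [fluid_properties()].
#' @return list with `series` (named list of tibbles `t`, `theta`,
#'   `phi`, `psi` per part), `frames`, and `truth` (list: `f`, `T`,
#'   `boundaries`, `phi_amp`, `power_windows`, `clap_windows`,
#'   `clap_distance`, `clean`, `spec`).
#' @export
make_protocol <- function(spec = protocol_spec(), planform = NULL,
                          fluid = fluid_properties()) {
  stopifnot(inherits(spec, "protocol_spec"))
  frames <- protocol_frames(spec)
  if (is.null(spec$phi_amp)) {
    if (is.null(planform)) stop("planform required to calibrate phi_amp", call. = FALSE)
    spec$phi_amp <- calibrate_phi_amp(spec, planform$R)
  }
  coefs_l <- protocol_coefficients(spec)
  coefs <- list(
    left_wing = coefs_l$left_wing,
    right_wing = fourier_mirror(coefs_l$left_wing),
    left_elytron = coefs_l$left_elytron,
    right_elytron = fourier_mirror(coefs_l$left_elytron)
  )
  if (is.null(spec$f)) {
    if (is.null(planform)) stop("planform required to calibrate f", call. = FALSE)
    spec$f <- calibrate_frequency(spec, coefs$left_wing, frames$left_wing,
                                  planform, fluid)
  }
  Tms <- 1 / spec$f
  # phase offset 0.9 puts the first rising phi zero crossing inside the
  # record rather than at its very first sample
  offset <- 0.9
  tmax <- (spec$n_cycles + 0.2) * Tms
  t <- seq(0, tmax, by = spec$sample_dt)
  x <- t / Tms + offset
  set.seed(spec$seed)
  series <- purrr::map(coefs, function(pc) {
    tibble::tibble(
      t = t,
      theta = fourier_eval(pc$theta, x) + stats::rnorm(length(t), 0, spec$noise_sd),
      phi = fourier_eval(pc$phi, x) + stats::rnorm(length(t), 0, spec$noise_sd),
      psi = fourier_eval(pc$psi, x) + stats::rnorm(length(t), 0, spec$noise_sd)
    )
  })
  boundaries <- (seq_len(spec$n_cycles + 1) - 1 + (1 - offset)) * Tms
  boundaries <- boundaries[boundaries <= tmax + 1e-9]
  R <- if (!is.null(planform)) planform$R else 493
  truth <- list(
    f = spec$f, T = Tms, boundaries = boundaries, phi_amp = spec$phi_amp,
    phase_offset = offset,
    power_windows = spec$power_windows, clap_windows = spec$clap_windows,
    clap_distance = noiseless_clap_distance(spec, coefs, frames, R),
    clean = function(part, phase) {
      pc <- coefs[[part]]
      tibble::tibble(phase = phase,
                     theta = fourier_eval(pc$theta, phase),
                     phi = fourier_eval(pc$phi, phase),
                     psi = fourier_eval(pc$psi, phase))
    },
    spec = spec
  )
  list(series = series, frames = frames, truth = truth)
}

# noiseless minimum blade-tip separation inside the ventral clap window
noiseless_clap_distance <- function(spec, coefs, frames, R, n = 4000) {
  win <- spec$clap_windows$ventral %||% spec$clap_windows[[length(spec$clap_windows)]]
  x <- seq(win[1], win[2], length.out = n)
  tip <- function(part) {
    pc <- coefs[[part]]
    ang <- tibble::tibble(theta = fourier_eval(pc$theta, x),
                          phi = fourier_eval(pc$phi, x),
                          psi = fourier_eval(pc$psi, x))
    pose_from_angles(ang, frames[[part]], span = R)
  }
  l <- tip("left_wing"); r <- tip("right_wing")
  min(sqrt((l$tipx - r$tipx)^2 + (l$tipy - r$tipy)^2 + (l$tipz - r$tipz)^2))
}

calibrate_phi_amp <- function(spec, R, lower = 85, upper = 120) {
  gap_at <- function(amp) {
    s2 <- spec; s2$phi_amp <- amp
    cl <- protocol_coefficients(s2)
    coefs <- list(left_wing = cl$left_wing,
                  right_wing = fourier_mirror(cl$left_wing))
    noiseless_clap_distance(s2, coefs, protocol_frames(s2), R, n = 1200) -
      spec$clap_gap
  }
  stats::uniroot(gap_at, lower = lower, upper = upper, tol = 1e-6)$root
}

# Re is linear in f for a fixed protocol shape: evaluate the mean Rg
# speed at f = 1 kHz and scale.
calibrate_frequency <- function(spec, wing_coefs, frame, planform, fluid,
                                n = 1024) {
  x <- (seq_len(n) - 1) / n
  ang <- tibble::tibble(phase = x,
                        theta = fourier_eval(wing_coefs$theta, x),
                        phi = fourier_eval(wing_coefs$phi, x),
                        psi = fourier_eval(wing_coefs$psi, x))
  kin <- derive_kinematics(ang, frame, planform, fluid, f = 1)
  re_at_1 <- attr(kin, "re_mean")
  spec$target_re / re_at_1
}

#' Synthetic wing-morphology specification
#'
#' Parameters of the composite bristled-wing fixture generator:
#' petiole and blade extents, the setal fringe (count, fan opening,
#' length profile), membrane thicknesses for the substitute wings, and
#' material constants. Defaults emulate the morphology of a miniature
#' featherwing beetle: wing length 493 um, setal linear density 0.96
#' ug/m, cuticle density 1,200 kg/m^3, substitute thicknesses taken
#' from the thinnest membranous wings known in similarly sized insects
#' (0.73, 0.85, 1.12 um), and a fringe occupying about 95% of the
#' aerodynamically effective area.
#'
#' @param wing_length wing length R (um), petiole base to seta tips.
#' @param n_setae number of fringe setae (>= 3).
#' @param petiole_length,petiole_halfwidth,petiole_thickness petiole
#'   rectangle dimensions (um).
#' @param blade_length,blade_halfwidth,blade_thickness blade lens
#'   dimensions (um): the blade runs from the petiole tip over
#'   `blade_length`, with half-width rising from the petiole half-width
#'   by `blade_halfwidth` at mid-blade.
#' @param fan_angle half-opening of the setal fan (deg).
#' @param seta_edge_fraction edge-seta length as a fraction of the
#'   longest (mid) seta.
#' @param linear_density setal linear density lambda (ug/um).
#' @param cuticle_density cuticle density (ug/um^3); measurement
#'   uncertainty is about +/- 100 kg/m^3, passable here for error
#'   propagation.
#' @param membrane_thicknesses thickness list (um) for the membranous
#'   substitutes.
#' @param elytron_length,elytron_halfwidth,elytron_thickness elytron
#'   ellipse dimensions (um).
#' @param jitter_sd optional seeded jitter (um) on seta tips, for
#'   randomized fixtures.
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @return object of class `morph_spec`.
#' @export
morph_spec <- function(wing_length = 493, n_setae = 45,
                       petiole_length = 70, petiole_halfwidth = 8,
                       petiole_thickness = 3,
                       blade_length = 130, blade_halfwidth = 27.5,
                       blade_thickness = 0.8,
                       fan_angle = 80, seta_edge_fraction = 0.4,
                       linear_density = 9.6e-7,
                       cuticle_density = density_si_to_internal(1200),
                       membrane_thicknesses = c(0.73, 0.85, 1.12),
                       elytron_length = 220, elytron_halfwidth = 45,
                       elytron_thickness = 10,
                       jitter_sd = 0, seed = 1L) {
  stopifnot(wing_length > 0, n_setae >= 3, linear_density > 0,
            cuticle_density > 0, all(membrane_thicknesses > 0))
  structure(as.list(environment()), class = "morph_spec")
}

#' Generate a synthetic bristled-wing morphology
#'
#' Builds a [wing_morphology()] fixture (petiole rectangle, lens-shaped
#' blade, fan of setae whose mid tip reaches the wing length), its
#' membranous substitutes at each requested thickness, an elytron
#' membrane patch, and the planform summary of the effective outline.
#' The fraction of the aerodynamically effective area occupied by the
#' setal fringe is computed and reported, not asserted.
#'
#' @param spec a [morph_spec()].
#' @return list with `wing`, `substitutes` (named by thickness),
#'   `elytron`, `outline` (substitute boundary), `planform`,
#'   `setae_area_fraction`, and `truth` (the spec and derived scalars).
#' @export
make_morphology <- function(spec = morph_spec()) {
  stopifnot(inherits(spec, "morph_spec"))
  pl <- spec$petiole_length; phw <- spec$petiole_halfwidth
  bl <- spec$blade_length; x1 <- pl + bl
  petiole <- membrane_patch(
    rbind(c(0, -phw), c(pl, -phw), c(pl, phw), c(0, phw)),
    thickness = spec$petiole_thickness, density = spec$cuticle_density
  )
  wfun <- function(x) phw + (spec$blade_halfwidth - phw) * sin(pi * (x - pl) / bl)
  xs <- seq(pl, x1, length.out = 12)
  blade_bnd <- rbind(cbind(xs, -wfun(xs)), cbind(rev(xs), wfun(rev(xs))))
  blade <- membrane_patch(blade_bnd, thickness = spec$blade_thickness,
                          density = spec$cuticle_density)
  # setal fan along the blade margin (trailing edge -> tip -> leading edge)
  ns <- spec$n_setae
  margin <- rbind(cbind(xs[-1], -wfun(xs[-1])),
                  c(x1, 0),
                  cbind(rev(xs[-12]), wfun(rev(xs[-12]))))
  seg <- sqrt(rowSums(diff(margin)^2))
  s_at <- c(0, cumsum(seg)) / sum(seg)
  s_grid <- seq(0.02, 0.98, length.out = ns)
  bx <- stats::approx(s_at, margin[, 1], xout = s_grid)$y
  by <- stats::approx(s_at, margin[, 2], xout = s_grid)$y
  ang <- deg2rad(-spec$fan_angle + 2 * spec$fan_angle * s_grid)
  l_mid <- spec$wing_length - x1
  len <- l_mid * (spec$seta_edge_fraction +
                    (1 - spec$seta_edge_fraction) * sin(pi * s_grid))
  if (spec$jitter_sd > 0) {
    set.seed(spec$seed)
    len <- pmax(len + stats::rnorm(ns, 0, spec$jitter_sd), 1)
  }
  setae <- purrr::map(seq_len(ns), function(k) {
    seta_rod(base = c(bx[k], by[k], 0),
             direction = c(cos(ang[k]), sin(ang[k]), 0),
             length = len[k], linear_density = spec$linear_density)
  })
  wing <- wing_morphology(petiole = petiole, blade = blade, setae = setae)
  subs <- purrr::map(spec$membrane_thicknesses, function(h) {
    membranous_substitute(wing, thickness = h)
  })
  names(subs) <- format(spec$membrane_thicknesses)
  outline <- subs[[1]]$boundary
  planform <- wing_planform(outline)
  a_eff <- polygon_moments(outline)$area
  a_solid <- polygon_moments(petiole$boundary)$area +
    polygon_moments(blade$boundary)$area
  # elytron: ellipse with its base (articulation) at the local origin
  tt <- seq(0, 2 * pi, length.out = 25)[-25]
  el_bnd <- cbind(spec$elytron_length / 2 * (1 + cos(tt)),
                  spec$elytron_halfwidth * sin(tt))
  elytron <- membrane_patch(el_bnd, thickness = spec$elytron_thickness,
                            density = spec$cuticle_density)
  list(
    wing = wing, substitutes = subs, elytron = elytron,
    outline = outline, planform = planform,
    setae_area_fraction = 1 - a_solid / a_eff,
    truth = list(spec = spec, effective_area = a_eff, solid_area = a_solid)
  )
}

#' Generate synthetic force series with labelled construction
#'
#' Builds per-part aerodynamic force fixtures whose vertical-force
#' peaks lie inside the power-stroke windows and whose drag/lift
#' construction is recorded as ground truth, for testing the
#' decomposition and vertical-force accounting.
#'
#' Modes:
#' * `drag_lift_mix`: force = drag term exactly anti-parallel to the
#'   Rg velocity plus lift term perpendicular to it (in the vertical
#'   plane through the velocity), with envelope bumps in the power
#'   windows, scaled so the cycle-averaged vertical force splits into
#'   `shares` (drag, lift) of `mean_vertical` exactly.
#' * `power_stroke_peaked`: purely vertical force with the same
#'   envelope, mean `mean_vertical`.
#'
#' @param kin [derive_kinematics()] tibble of the part (provides the
#'   velocity direction and the grid).
#' @param mode `"drag_lift_mix"` or `"power_stroke_peaked"`.
#' @param shares length-2 numeric (drag, lift), summing to 1.
#' @param mean_vertical target cycle-averaged vertical force (internal
#'   units = nN).
#' @param power_windows list of phase windows for the envelope bumps;
#'   defaults to the windows stored by [protocol_spec()].
#' @param part part label.
#' @return force tibble with attributes `truth` (construction record),
#'   `ref_point`, `reference`.
#' @export
make_forces <- function(kin, mode = c("drag_lift_mix", "power_stroke_peaked"),
                        shares = c(drag = 0.32, lift = 0.68),
                        mean_vertical = 12,
                        power_windows = list(c(0.98, 0.16), c(0.38, 0.62)),
                        part = "wing") {
  mode <- match.arg(mode)
  stopifnot(length(shares) == 2, abs(sum(shares) - 1) < 1e-9, all(shares >= 0))
  phase <- kin$phase
  env <- phase_window_envelope(phase, power_windows)
  n <- length(phase)
  F <- matrix(0, n, 3)
  if (mode == "power_stroke_peaked") {
    if (mean(env) > 0) F[, 3] <- env * mean_vertical / mean(env)
  } else {
    speed <- kin$speed
    ok <- speed > 1e-9
    if (any(ok)) {
      vhat <- cbind(kin$vx, kin$vy, kin$vz) / pmax(speed, 1e-300)
      wvec <- cbind(-vhat[, 1] * vhat[, 3], -vhat[, 2] * vhat[, 3],
                    1 - vhat[, 3]^2)
      wnorm <- sqrt(rowSums(wvec^2))
      what <- wvec / pmax(wnorm, 1e-300)
      what[wnorm < 1e-9, ] <- 0 # vertical flow: no vertical-lift direction
      e <- env * ok
      md <- mean(-e * vhat[, 3])
      ml <- mean(e * what[, 3])
      if (abs(md) < 1e-12 || abs(ml) < 1e-12) {
        stop("protocol gives no net vertical drag or lift; cannot realize shares",
             call. = FALSE)
      }
      a_d <- shares[1] * mean_vertical / md
      a_l <- shares[2] * mean_vertical / ml
      F <- a_d * e * (-vhat) + a_l * e * what
    }
  }
  frame <- attr(kin, "frame")
  r <- cbind(kin$x - frame$origin[1], kin$y - frame$origin[2],
             kin$z - frame$origin[3])
  tq <- cbind(r[, 2] * F[, 3] - r[, 3] * F[, 2],
              r[, 3] * F[, 1] - r[, 1] * F[, 3],
              r[, 1] * F[, 2] - r[, 2] * F[, 1])
  out <- tibble::tibble(t = kin$t, phase = phase,
                        fx = F[, 1], fy = F[, 2], fz = F[, 3],
                        tx = tq[, 1], ty = tq[, 2], tz = tq[, 3])
  attr(out, "part") <- part
  attr(out, "ref_point") <- frame$origin
  attr(out, "reference") <- "wing_base"
  attr(out, "truth") <- list(mode = mode, shares = shares,
                             mean_vertical = mean_vertical,
                             power_windows = power_windows)
  out
}

# raised-cosine bumps centred in each (possibly wrapping) phase window
phase_window_envelope <- function(phase, windows) {
  env <- numeric(length(phase))
  for (w in windows) {
    width <- if (w[1] <= w[2]) w[2] - w[1] else 1 - w[1] + w[2]
    centre <- (w[1] + width / 2) %% 1
    d <- abs(phase - centre)
    d <- pmin(d, 1 - d)
    env <- env + ifelse(d < width / 2, cos(pi * d / width)^2, 0)
  }
  env
}
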