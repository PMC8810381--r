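test_that("stroke-plane fit recovers exact and noisy planes", {
  base <- c(0, 75, 0)
  # points exactly in a plane through the base, tilted 40 deg
  b <- pi * 40 / 180
  n_true <- c(sin(b), 0, cos(b))
  u <- c(0, 1, 0); v <- c(-cos(b), 0, sin(b))
  th <- seq(0, 2 * pi, length.out = 50)
  tips <- t(sapply(th, function(a) base + 490 * (cos(a) * u + sin(a) * v)))
  fr <- fit_stroke_plane(tips, base)
  expect_equal(abs(sum(fr$normal * n_true)), 1, tolerance = 1e-12)
  expect_equal(fr$beta, 40, tolerance = 1e-9)
  resid <- apply(tips, 1, function(p) sum((p - base) * fr$normal))
  expect_lt(max(abs(resid)), 1e-9)

  # horizontal planar cloud: beta = 0
  flat <- cbind(stats::runif(30, -100, 100), stats::runif(30, -100, 100), 0)
  expect_equal(fit_stroke_plane(flat, c(0, 0, 0))$beta, 0, tolerance = 1e-9)

  # Monte-Carlo: noise sd = 2% of R still recovers the normal within 2 deg
  set.seed(42)
  worst <- 0
  for (rep in 1:20) {
    noisy <- tips + matrix(stats::rnorm(length(tips), 0, 0.02 * 490), ncol = 3)
    frn <- fit_stroke_plane(noisy, base)
    ang <- acos(min(1, abs(sum(frn$normal * n_true)))) * 180 / pi
    worst <- max(worst, ang)
  }
  expect_lt(worst, 2)

  # collinear cloud: plane undefined
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_stroke_plane(line, c(0, 0, 0)), "collinear")
})

test_that("pose maps angles to geometry per the stated conventions", {
  fr <- stroke_frame(c(0, 0, 0), c(0, 0, 1)) # horizontal stroke plane
  # theta = psi = 0, phi sweep: tip moves on a circle of radius R in-plane
  ang <- tibble::tibble(theta = 0, phi = seq(0, 350, by = 10), psi = 0)
  pose <- pose_from_angles(ang, fr, span = 490)
  expect_equal(pose$tipz, rep(0, nrow(pose)), tolerance = 1e-12)
  r <- sqrt(pose$tipx^2 + pose$tipy^2)
  expect_equal(r, rep(490, nrow(pose)), tolerance = 1e-9)
  # psi = 90: chord perpendicular to the stroke plane, any phi
  ang2 <- tibble::tibble(theta = 0, phi = c(0, 33, 120, 270), psi = 90)
  pose2 <- pose_from_angles(ang2, fr, span = 1)
  chord_dot_n <- pose2$cx * fr$normal[1] + pose2$cy * fr$normal[2] +
    pose2$cz * fr$normal[3]
  expect_equal(abs(chord_dot_n), rep(1, 4), tolerance = 1e-12)
})

test_that("angles -> pose -> angles round-trips to 1e-9 degrees", {
  fr <- stroke_frame(c(0, 75, 0), c(sin(0.7), 0, cos(0.7)), u = c(0, 1, 0))
  set.seed(3)
  ang <- tibble::tibble(theta = stats::runif(200, -80, 80),
                        phi = stats::runif(200, -179, 179),
                        psi = stats::runif(200, -179, 179))
  pose <- pose_from_angles(ang, fr)
  back <- angles_from_pose(pose, fr)
  expect_false(any(back$gimbal))
  expect_lt(max(abs(back$theta - ang$theta)), 1e-9)
  dphi <- (back$phi - ang$phi + 180) %% 360 - 180
  dpsi <- (back$psi - ang$psi + 180) %% 360 - 180
  expect_lt(max(abs(dphi)), 1e-9)
  expect_lt(max(abs(dpsi)), 1e-9)
})

test_that("gimbal lock at |theta| = 90 deg is flagged with NA phi", {
  fr <- stroke_frame(c(0, 0, 0), c(0, 0, 1))
  pose <- pose_from_angles(tibble::tibble(theta = 90, phi = 25, psi = 10), fr)
  expect_warning(back <- angles_from_pose(pose, fr), "gimbal")
  expect_true(back$gimbal[1])
  expect_true(is.na(back$phi[1]))
})

test_that("mirroring is an involution and mirrors the physical pose", {
  spec <- protocol_spec(noise_sd = 0)
  frames <- bristlewing:::protocol_frames(spec)
  ang <- tibble::tibble(theta = c(10, -25), phi = c(40, -80), psi = c(65, -12))
  expect_equal(mirror_angles(mirror_angles(ang)), ang)
  pl <- pose_from_angles(ang, frames$left_wing, span = 493)
  pr <- pose_from_angles(mirror_angles(ang), frames$right_wing, span = 493)
  # right tip is the sagittal mirror image of the left tip
  expect_equal(pr$tipx, pl$tipx, tolerance = 1e-12)
  expect_equal(pr$tipy, -pl$tipy, tolerance = 1e-12)
  expect_equal(pr$tipz, pl$tipz, tolerance = 1e-12)
})

test_that("uniform resampling preserves nodes and reproduces polynomials", {
  t <- seq(0, 5, by = 0.25)
  s <- tibble::tibble(t = t, phi = 3 + 2 * t - 0.5 * t^2 + 0.1 * t^3)
  out <- resample_uniform(s, dt = 0.05)
  # cubic input reproduced exactly everywhere
  expect_equal(out$phi, 3 + 2 * out$t - 0.5 * out$t^2 + 0.1 * out$t^3,
               tolerance = 1e-10)
  # already-uniform series: identical values at the original nodes
  out2 <- resample_uniform(s, dt = 0.25)
  expect_equal(out2$phi, s$phi, tolerance = 1e-12)

  # sine at 20 samples/period, resampled x10: max error < 1e-3 amplitude
  tp <- seq(0, 2, by = 1 / 20)
  sin_s <- tibble::tibble(t = tp, phi = sin(2 * pi * tp))
  fine <- resample_uniform(sin_s, dt = 1 / 200)
  expect_lt(max(abs(fine$phi - sin(2 * pi * fine$t))), 1e-3)

  expect_error(resample_uniform(tibble::tibble(t = c(0, 1, 1, 2), phi = 1:4), 0.1),
               "increasing")
  expect_error(resample_uniform(tibble::tibble(t = 0:2, phi = 1:3), 0.1),
               "4 samples")
})

test_that("cycle detection recovers the frequency of a pure sine exactly", {
  f0 <- 0.21
  t <- seq(0, 25, by = 0.1)
  s <- tibble::tibble(t = t, phi = 80 * sin(2 * pi * f0 * t + 1))
  cyc <- detect_cycles(s)
  expect_equal(cyc$f, f0, tolerance = 1e-6)
  expect_equal(diff(cyc$boundaries), rep(1 / f0, cyc$n_cycles), tolerance = 1e-6)

  expect_error(detect_cycles(tibble::tibble(t = t, phi = rep(5, length(t)))),
               "crossings")
  expect_error(detect_cycles(tibble::tibble(t = 0:10, phi = c(-1, rep(1, 10)))),
               "crossings")
})

test_that("phase averaging respects identity, symmetry and noise scaling", {
  proto <- default_protocol()
  tr <- proto$truth
  # exact periodic series: the average equals any single cycle
  t <- seq(0, 5 * tr$T, by = tr$T / 64)
  x <- t / tr$T
  mk <- function(part) {
    cl <- tr$clean(part, x)
    tibble::tibble(t = t, theta = cl$theta, phi = cl$phi, psi = cl$psi)
  }
  left <- mk("left_wing")
  avg <- phase_average(left, n_phase = 128)
  truth <- tr$clean("left_wing", avg$phase)
  expect_equal(avg$phi, truth$phi, tolerance = 1e-6)
  expect_equal(avg$theta, truth$theta, tolerance = 1e-4)

  # left/right exact mirrors average to the canonical left-side form
  right <- mk("right_wing")
  avg2 <- phase_average(left, right, n_phase = 128)
  expect_equal(avg2$psi, truth$psi, tolerance = 1e-4)

  # averaging already-averaged data is idempotent: replay the averaged
  # cycle twice on a grid aligned with the phase grid and re-average
  idx <- 1 + (0:(2 * 128) %% 128)
  t2 <- (0:(2 * 128)) * tr$T / 128
  again <- tibble::tibble(t = t2, theta = avg$theta[idx],
                          phi = avg$phi[idx], psi = avg$psi[idx])
  avg3 <- phase_average(again, n_phase = 128)
  expect_equal(avg3$phi, avg$phi, tolerance = 1e-3)
  expect_equal(avg3$psi, avg$psi, tolerance = 1e-3)
})
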