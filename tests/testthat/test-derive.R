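test_that("angle of attack follows the feathered/flat-on convention", {
  m <- default_morph()
  fr <- stroke_frame(c(0, 0, 0), c(0, 0, 1))
  n <- 256
  x <- (0:(n - 1)) / n
  # psi = 0: chord lies in the stroke plane; in-plane sweep moves the
  # wing parallel to its own chord -> feathered, AoA = 0
  avg0 <- tibble::tibble(phase = x, theta = 0, phi = 60 * sin(2 * pi * x), psi = 0)
  k0 <- derive_kinematics(avg0, fr, m$planform, f = 0.2)
  expect_lt(max(abs(k0$aoa[!k0$gap])), 1e-9)
  # psi = 90: chord perpendicular to the plane; the same sweep hits the
  # wing surface flat-on, AoA = +/-90
  avg90 <- tibble::tibble(phase = x, theta = 0, phi = 60 * sin(2 * pi * x), psi = 90)
  k90 <- derive_kinematics(avg90, fr, m$planform, f = 0.2)
  expect_equal(abs(k90$aoa[!k90$gap]), rep(90, sum(!k90$gap)), tolerance = 1e-6)
  # intermediate fixed pitch: AoA magnitude equals psi for in-plane motion
  avg45 <- tibble::tibble(phase = x, theta = 0, phi = 60 * sin(2 * pi * x), psi = 37)
  k45 <- derive_kinematics(avg45, fr, m$planform, f = 0.2)
  expect_equal(abs(k45$aoa[!k45$gap]), rep(37, sum(!k45$gap)), tolerance = 1e-6)
})

test_that("mean Reynolds number matches the closed form for a sine stroke", {
  m <- default_morph()
  fr <- stroke_frame(c(0, 0, 0), c(0, 0, 1))
  fluid <- fluid_properties()
  n <- 2048
  x <- (0:(n - 1)) / n
  Phi <- 70; f <- 0.25
  avg <- tibble::tibble(phase = x, theta = 0, phi = Phi * sin(2 * pi * x), psi = 20)
  kin <- derive_kinematics(avg, fr, m$planform, fluid, f = f)
  # mean |dphi/dt| of a sine = 4 * Phi * f (rad/ms); speed = Rg * |dphi/dt|
  u_mean <- 4 * (Phi * pi / 180) * f * m$planform$Rg
  re_closed <- u_mean * m$planform$cbar / fluid$nu
  expect_equal(attr(kin, "re_mean"), re_closed, tolerance = 1e-3)
})

test_that("Re scales linearly with frequency and mean chord", {
  m <- default_morph()
  proto <- default_protocol()
  x <- (0:255) / 256
  ang <- proto$truth$clean("left_wing", x)
  k1 <- derive_kinematics(ang, proto$frames$left_wing, m$planform, f = 0.2)
  k2 <- derive_kinematics(ang, proto$frames$left_wing, m$planform, f = 0.4)
  expect_equal(attr(k2, "re_mean") / attr(k1, "re_mean"), 2, tolerance = 1e-9)
  pf <- m$planform
  pf$cbar <- pf$cbar * 1.5
  k3 <- derive_kinematics(ang, proto$frames$left_wing, pf, f = 0.2)
  expect_equal(attr(k3, "re_mean") / attr(k1, "re_mean"), 1.5, tolerance = 1e-9)
})

test_that("zero-velocity samples are flagged as gaps, never interpolated", {
  m <- default_morph()
  fr <- stroke_frame(c(0, 0, 0), c(0, 0, 1))
  x <- (0:63) / 64
  still <- tibble::tibble(phase = x, theta = 0, phi = 0, psi = 30)
  kin <- derive_kinematics(still, fr, m$planform, f = 0.2)
  expect_true(all(kin$gap))
  expect_true(all(is.na(kin$aoa)))
})

test_that("body speed recovers linear motion exactly and filters jitter", {
  t <- seq(0, 30, by = 0.26)
  v0 <- c(0.06, 0.01, 0.04) # um/ms
  track <- tibble::tibble(t = t, x = 100 + v0[1] * t, y = v0[2] * t,
                          z = -50 + v0[3] * t)
  bs <- body_speed(track)
  expect_equal(bs$vx_s, rep(v0[1], length(t)), tolerance = 1e-9)
  expect_equal(bs$horizontal, rep(sqrt(v0[1]^2 + v0[2]^2), length(t)),
               tolerance = 1e-9)
  expect_equal(bs$vertical, rep(v0[3], length(t)), tolerance = 1e-9)

  # vertical ascent only: horizontal component identically zero
  up <- tibble::tibble(t = t, x = 0, y = 0, z = 10 * t)
  expect_equal(body_speed(up)$horizontal, rep(0, length(t)), tolerance = 1e-12)

  # i.i.d. position jitter: smoothing shrinks the velocity noise well
  # below the raw finite-difference noise level
  set.seed(5)
  sd_pos <- 2
  noisy <- tibble::tibble(t = t, x = 100 + v0[1] * t + rnorm(length(t), 0, sd_pos),
                          y = 0, z = 0)
  bsn <- body_speed(noisy)
  raw_rmse <- sqrt(mean((bsn$vx - v0[1])^2))
  smooth_rmse <- sqrt(mean((bsn$vx_s - v0[1])^2))
  expect_lt(smooth_rmse, raw_rmse / 3)
  expect_error(body_speed(track[1:5, ]), "10")
})

test_that("clap distance matches the generator's ground truth", {
  m <- default_morph()
  proto <- default_protocol()
  tr <- proto$truth
  x <- (0:1023) / 1024
  al <- tr$clean("left_wing", x)
  lw <- pose_from_angles(al, proto$frames$left_wing, span = m$planform$R)
  rw <- pose_from_angles(mirror_angles(al), proto$frames$right_wing,
                         span = m$planform$R)
  res <- clap_distance(lw, rw, windows = list(tr$clap_windows$ventral))
  expect_equal(res$distance, tr$clap_distance, tolerance = 1e-2)
  # mirrored wings touching: force phi to reach the meeting angle
  touch <- tibble::tibble(theta = 0, phi = 104.49, psi = 0)
  # solve: tips meet when tip_y = 0
  phi_touch <- acos(-proto$truth$spec$base_sep / 2 / m$planform$R) * 180 / pi
  touch$phi <- phi_touch
  lt <- pose_from_angles(touch, proto$frames$left_wing, span = m$planform$R)
  rt <- pose_from_angles(mirror_angles(touch), proto$frames$right_wing,
                         span = m$planform$R)
  expect_equal(sqrt(sum((lt[1, c("tipx", "tipy", "tipz")] -
                           rt[1, c("tipx", "tipy", "tipz")])^2)), 0,
               tolerance = 1e-9)
  # a non-clapping protocol stays far apart: bound by base separation
  open_ang <- tibble::tibble(phase = x, theta = 0,
                             phi = 45 * sin(2 * pi * x), psi = 0)
  lo <- pose_from_angles(open_ang, proto$frames$left_wing, span = m$planform$R)
  ro <- pose_from_angles(mirror_angles(open_ang), proto$frames$right_wing,
                         span = m$planform$R)
  res2 <- clap_distance(lo, ro)
  min_possible <- proto$truth$spec$base_sep +
    2 * m$planform$R * cos(pi / 180 * 45) - 2 * m$planform$R
  expect_gt(res2$distance, max(min_possible, 100))
})
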