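test_that("force series round-trip through the exchange format", {
  kin <- clean_kin(n = 64)
  fs <- quasisteady_surrogate(kin, part = "left_wing")
  path <- withr::local_tempfile(fileext = ".csv")
  write_force_series(fs, path)
  back <- load_force_series(path)
  for (cl in c("t", "fx", "fy", "fz", "tx", "ty", "tz")) {
    expect_equal(back[[cl]], fs[[cl]], tolerance = 1e-9)
  }
  expect_equal(attr(back, "ref_point"), attr(fs, "ref_point"), tolerance = 1e-9)
  expect_identical(attr(back, "part"), "left_wing")
})

test_that("force files with missing metadata or bad columns are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,Fx,Fy,Fz,Tx,Ty,Tz", "0,1,0,0,0,0,0", "1,1,0,0,0,0,0"), path)
  expect_error(load_force_series(path), "force_unit")
  writeLines(c("# force_unit: ug_um_ms2", "# torque_unit: ug_um2_ms2",
               "# reference_point_um: 0 0 0",
               "t,Fx,Fy,Fz", "0,1,0,0", "1,1,0,0"), path)
  expect_error(load_force_series(path), "missing columns")
  writeLines(c("# force_unit: ug_um_ms2", "# torque_unit: ug_um2_ms2",
               "# reference_point_um: 0 0 0",
               "t,Fx,Fy,Fz,Tx,Ty,Tz", "1,1,0,0,0,0,0", "0,1,0,0,0,0,0"), path)
  expect_error(load_force_series(path), "increasing")
})

test_that("SI force units convert on load and constant series average to themselves", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# part: body", "# force_unit: N", "# torque_unit: N_m",
               "# reference_point_um: 0 0 0",
               "t,Fx,Fy,Fz,Tx,Ty,Tz",
               paste(0:9, 2e-9, 0, 3e-9, 0, 0, 1e-15, sep = ",")), path)
  fs <- load_force_series(path)
  expect_equal(mean(fs$fz), 3, tolerance = 1e-12) # 3 nN in internal units
  expect_equal(mean(fs$fx), 2, tolerance = 1e-12)
  expect_equal(mean(fs$tz), 1, tolerance = 1e-12)
})

test_that("surrogate forces vanish with the motion and scale as U^2", {
  kin <- clean_kin(n = 128)
  # zero velocity everywhere -> zero force
  still <- kin
  still$speed <- 0
  still[c("vx", "vy", "vz")] <- 0
  still$gap <- TRUE
  fs0 <- quasisteady_surrogate(still)
  expect_true(all(abs(c(fs0$fx, fs0$fy, fs0$fz)) == 0))
  # doubling the speed (same AoA, no Re inflation) quadruples the force
  co <- surrogate_coefficients()
  f1 <- quasisteady_surrogate(kin, coeffs = co, low_re_k = 0)
  fast <- kin
  fast[c("vx", "vy", "vz")] <- kin[c("vx", "vy", "vz")] * 2
  fast$speed <- kin$speed * 2
  fast$re <- kin$re * 2
  f2 <- quasisteady_surrogate(fast, coeffs = co, low_re_k = 0)
  mag1 <- sqrt(f1$fx^2 + f1$fy^2 + f1$fz^2)
  mag2 <- sqrt(f2$fx^2 + f2$fy^2 + f2$fz^2)
  expect_equal(mag2, 4 * mag1, tolerance = 1e-9)
  expect_error(quasisteady_surrogate(kin,
                                     coeffs = surrogate_coefficients(cd0 = -1)),
               "negative")
})

test_that("surrogate drag is anti-aligned with velocity and peaks in power strokes", {
  kin <- clean_kin(n = 512)
  fs <- quasisteady_surrogate(kin)
  dc <- decompose(fs, kin)
  ok <- !dc$gap
  # drag component anti-parallel to velocity: drag . v <= 0
  ddotv <- dc$dx * kin$vx + dc$dy * kin$vy + dc$dz * kin$vz
  expect_true(all(ddotv[ok] <= 1e-9))
  # vertical-force peaks lie inside the power-stroke windows
  pw <- default_protocol()$truth$power_windows
  big <- abs(fs$fz) >= stats::quantile(abs(fs$fz), 0.9)
  expect_gte(mean(in_windows(kin$phase[big], pw)), 0.9)
  # net cycle-averaged vertical force is positive (asymmetry reproduced)
  expect_gt(mean(fs$fz), 0)
})

test_that("decomposition handles parallel, perpendicular and random forces", {
  n <- 64
  v <- tibble::tibble(vx = rep(1, n), vy = 0, vz = 0)
  f_par <- tibble::tibble(fx = seq_len(n), fy = 0, fz = 0)
  d1 <- decompose(f_par, v)
  expect_equal(d1$dx, as.numeric(seq_len(n)))
  expect_true(all(abs(c(d1$lx, d1$ly, d1$lz)) < 1e-12))
  f_perp <- tibble::tibble(fx = 0, fy = 0, fz = rep(2, n))
  d2 <- decompose(f_perp, v)
  expect_true(all(abs(c(d2$dx, d2$dy, d2$dz)) < 1e-12))
  expect_equal(d2$lz, rep(2, n))

  set.seed(9)
  m <- 1e4
  F <- matrix(stats::rnorm(3 * m), m, 3)
  V <- matrix(stats::rnorm(3 * m), m, 3)
  dd <- decompose(tibble::tibble(fx = F[, 1], fy = F[, 2], fz = F[, 3]),
                  tibble::tibble(vx = V[, 1], vy = V[, 2], vz = V[, 3]))
  recon <- cbind(dd$dx + dd$lx, dd$dy + dd$ly, dd$dz + dd$lz) - F
  rel <- sqrt(rowSums(recon^2)) / sqrt(rowSums(F^2))
  expect_lt(max(rel), 1e-12)
  vhat <- V / sqrt(rowSums(V^2))
  orth <- abs(rowSums(cbind(dd$lx, dd$ly, dd$lz) * vhat)) / sqrt(rowSums(F^2))
  expect_lt(max(orth), 1e-12)
})

test_that("zero-velocity samples become decomposition gaps", {
  v <- tibble::tibble(vx = c(1, 0, 2), vy = 0, vz = 0)
  f <- tibble::tibble(fx = c(1, 1, 1), fy = 0, fz = 0)
  d <- decompose(f, v)
  expect_identical(d$gap, c(FALSE, TRUE, FALSE))
  expect_true(is.na(d$dx[2]))
})

test_that("vertical breakdown reproduces hover balance and injected shares", {
  n <- 128
  g <- 9.81
  mb <- 2.43
  grid <- tibble::tibble(t = seq_len(n), fz = rep(mb * g / 2, n),
                         fx = 0, fy = 0)
  vb <- vertical_breakdown(list(left = grid, right = grid),
                           body_mass = mb, g = g)
  expect_equal(vb$vertical_acceleration, 0, tolerance = 1e-12)
  expect_equal(vb$total_weight_equiv, mb, tolerance = 1e-12)

  # lift-free fixture: all vertical force is drag
  kin <- clean_kin(n = 256)
  f_drag <- make_forces(kin, mode = "drag_lift_mix", shares = c(1, 0))
  dcd <- decompose(f_drag, kin)
  vb2 <- vertical_breakdown(list(w = f_drag), list(w = dcd), body_mass = mb)
  expect_equal(vb2$drag_share, 100, tolerance = 1e-6)

  # drag and lift injected 1:3 -> shares 25%/75%
  f_mix <- make_forces(kin, shares = c(0.25, 0.75))
  dcm <- decompose(f_mix, kin)
  vb3 <- vertical_breakdown(list(w = f_mix), list(w = dcm), body_mass = mb)
  expect_equal(vb3$drag_share, 25, tolerance = 1e-6)
  expect_equal(vb3$lift_share, 75, tolerance = 1e-6)
  expect_equal(vb3$drag_share + vb3$lift_share, 100, tolerance = 1e-9)
})

test_that("cycle-average accounting is linear in the force series", {
  kin <- clean_kin(n = 128)
  f1 <- make_forces(kin, shares = c(0.4, 0.6), mean_vertical = 10)
  f2 <- make_forces(kin, shares = c(0.4, 0.6), mean_vertical = 5)
  fsum <- f1
  for (cl in c("fx", "fy", "fz", "tx", "ty", "tz")) fsum[[cl]] <- f1[[cl]] + f2[[cl]]
  vb_sum <- vertical_breakdown(list(w = fsum), body_mass = 2.43)
  vb1 <- vertical_breakdown(list(w = f1), body_mass = 2.43)
  vb2 <- vertical_breakdown(list(w = f2), body_mass = 2.43)
  expect_equal(vb_sum$total_vertical, vb1$total_vertical + vb2$total_vertical,
               tolerance = 1e-12)
})

test_that("torque reference shifts follow the moment-transfer law", {
  kin <- clean_kin(n = 64)
  fs <- quasisteady_surrogate(kin)
  com <- c(40, 0, -30)
  shifted <- shift_torque_reference(fs, com)
  # direct recomputation: tau_com = r_com->P x F with P the application
  # point; equivalently tau_base + (base - com) x F
  d <- attr(fs, "ref_point") - com
  ty2 <- fs$ty + d[3] * fs$fx - d[1] * fs$fz
  expect_equal(shifted$ty, ty2, tolerance = 1e-12)
  expect_equal(attr(shifted, "ref_point"), com)
})

test_that("synthetic force construction recovers its recorded truth", {
  kin <- clean_kin(n = 256)
  f32 <- make_forces(kin, shares = c(0.32, 0.68), mean_vertical = 12)
  dc <- decompose(f32, kin)
  vb <- vertical_breakdown(list(w = f32), list(w = dc), body_mass = 2.43)
  expect_equal(vb$drag_share, 32, tolerance = 1e-6)
  expect_equal(vb$lift_share, 68, tolerance = 1e-6)
  expect_equal(mean(f32$fz), 12, tolerance = 1e-9)
  # peaked mode: mean matches, peaks inside the windows
  fp <- make_forces(kin, mode = "power_stroke_peaked", mean_vertical = 7)
  expect_equal(mean(fp$fz), 7, tolerance = 1e-9)
  pw <- attr(fp, "truth")$power_windows
  big <- fp$fz >= stats::quantile(fp$fz, 0.9)
  expect_true(all(in_windows(kin$phase[big], pw)))
  # a zero-amplitude protocol produces zero forces
  still <- clean_kin(n = 64)
  still[c("vx", "vy", "vz")] <- 0
  still$speed <- rep(0, 64)
  f0 <- make_forces(still, mode = "drag_lift_mix")
  expect_true(all(c(f0$fx, f0$fy, f0$fz) == 0))
})
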