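test_that("thin-rod mass properties match classical closed forms", {
  lam <- 9.6e-7
  # rod along the x axis through the origin: no moment about its own axis
  s <- seta_rod(base = c(0, 0, 0), direction = c(1, 0, 0), length = 300,
                linear_density = lam)
  mp <- mass_properties(s, origin = c(0, 0, 0))
  expect_equal(mp$mass, lam * 300)
  expect_equal(mp$inertia[1, 1], 0, tolerance = 1e-12)
  # perpendicular rod with base at the origin: I about transverse axes = mL^2/3
  expect_equal(mp$inertia[2, 2], mp$mass * 300^2 / 3, tolerance = 1e-12)
  expect_equal(mp$inertia[3, 3], mp$mass * 300^2 / 3, tolerance = 1e-12)
  expect_equal(mp$com, c(150, 0, 0))
  validate_mass_properties(mp)
})

test_that("oblique rod tensor matches a 1e6-point-mass discretisation", {
  s <- seta_rod(base = c(10, 5, 0), direction = c(0.6, 0.8, 0), length = 400,
                linear_density = 9.6e-4)
  mp <- mass_properties(s, origin = c(0, 0, 0))
  orc <- rod_oracle(s, c(0, 0, 0), n = 1e6)
  expect_tensor_close(mp, orc, 1e-3)
})

test_that("zero-length and invalid rods are rejected", {
  expect_error(seta_rod(c(0, 0, 0), tip = c(0, 0, 0)), "zero-length")
  expect_error(seta_rod(c(0, 0, 0), direction = c(1, 0, 0), length = 0),
               "zero-length")
  expect_error(seta_rod(c(0, 0, 0), direction = c(1, 0, 0), length = 10,
                        linear_density = -1), "linear density")
})

test_that("membrane quadrature reproduces rectangle closed forms", {
  a <- 200; b <- 60; h <- 1.2
  rho <- density_si_to_internal(1200)
  # rectangle centred at the origin
  patch <- membrane_patch(rbind(c(-a / 2, -b / 2), c(a / 2, -b / 2),
                                c(a / 2, b / 2), c(-a / 2, b / 2)),
                          thickness = h, density = rho)
  mp <- mass_properties(patch, origin = c(0, 0, 0), step = min(a, b) / 50)
  m_exact <- rho * h * a * b
  expect_equal(mp$mass, m_exact, tolerance = 2e-3)
  expect_equal(mp$inertia[3, 3], m_exact * (a^2 + b^2) / 12, tolerance = 5e-3)
  expect_equal(mp$inertia[1, 1], m_exact * b^2 / 12, tolerance = 5e-3)
  expect_lt(max(abs(mp$com)), 0.2)
  # a step that tiles the rectangle exactly gives the closed form to
  # machine precision (the fine-step limit)
  mp1 <- mass_properties(patch, origin = c(0, 0, 0), step = 1)
  expect_equal(mp1$mass, m_exact, tolerance = 1e-12)
})

test_that("right-triangle patch agrees with exact polygon moment integrals", {
  a <- 150; b <- 90; h <- 1
  rho <- 1.2e-6
  patch <- membrane_patch(rbind(c(0, 0), c(a, 0), c(0, b)),
                          thickness = h, density = rho)
  mp <- mass_properties(patch, origin = c(0, 0, 0), step = 1.5)
  sig <- rho * h
  # analytic moments of the right triangle about the origin
  area <- a * b / 2
  expect_equal(mp$mass, sig * area, tolerance = 5e-3)
  expect_equal(mp$inertia[2, 2], sig * a^3 * b / 12, tolerance = 5e-3) # int x^2
  expect_equal(mp$inertia[1, 1], sig * a * b^3 / 12, tolerance = 5e-3) # int y^2
  expect_equal(mp$inertia[1, 2], -sig * a^2 * b^2 / 24, tolerance = 5e-3) # -int xy
  expect_equal(mp$com[1:2], c(a / 3, b / 3), tolerance = 5e-3)
})

test_that("degenerate membranes raise explicit errors", {
  # collinear (zero-area) boundary
  expect_error(membrane_patch(rbind(c(0, 0), c(100, 0), c(200, 0)),
                              thickness = 1), "degenerate|self-intersect")
  # bow-tie
  expect_error(membrane_patch(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)),
                              thickness = 1), "self-intersect")
  expect_error(membrane_patch(rbind(c(0, 0), c(1, 0), c(1, 1)), thickness = 0),
               "thickness")
  # quadrature step coarser than the polygon
  p <- membrane_patch(rbind(c(0, 0), c(10, 0), c(10, 8), c(0, 8)), thickness = 1)
  expect_error(mass_properties(p, step = 50), "step")
})

test_that("parallel-axis shifts are self-consistent to machine precision", {
  set.seed(7)
  s <- seta_rod(base = stats::runif(3, -50, 50),
                direction = stats::rnorm(3), length = 320,
                linear_density = 9.6e-7)
  o1 <- c(0, 0, 0); o2 <- c(37, -12, 80)
  direct <- mass_properties(s, origin = o2)
  shifted <- shift_origin(mass_properties(s, origin = o1), o2)
  expect_equal(shifted$inertia, direct$inertia, tolerance = 1e-12)
  expect_equal(shifted$mass, direct$mass)
})

test_that("rotating the geometry maps the tensor as R I R^T", {
  set.seed(11)
  for (rep in 1:3) {
    R <- random_rotation()
    s <- seta_rod(base = stats::runif(3, -100, 100),
                  direction = stats::rnorm(3), length = 250,
                  linear_density = 2e-6)
    s_rot <- seta_rod(base = as.numeric(R %*% s$base),
                      direction = as.numeric(R %*% s$direction),
                      length = s$length, linear_density = s$linear_density)
    I0 <- mass_properties(s, origin = c(0, 0, 0))$inertia
    I1 <- mass_properties(s_rot, origin = c(0, 0, 0))$inertia
    expect_equal(I1, R %*% I0 %*% t(R), tolerance = 1e-10)
  }
})

test_that("wing assembly is additive over components", {
  m <- default_morph()
  wing <- m$wing
  mp_all <- mass_properties(wing, step = 4)
  mp_pet <- mass_properties(wing$petiole, step = 4)
  mp_blade <- mass_properties(wing$blade, step = 4)
  mp_setae <- purrr::map(wing$setae, mass_properties)
  m_sum <- mp_pet$mass + mp_blade$mass + sum(purrr::map_dbl(mp_setae, "mass"))
  expect_equal(mp_all$mass, m_sum, tolerance = 1e-12)
  i_sum <- mp_pet$inertia + mp_blade$inertia +
    Reduce(`+`, purrr::map(mp_setae, "inertia"))
  expect_equal(mp_all$inertia, i_sum, tolerance = 1e-12)

  # wing of a single seta and no patches reduces to the rod result
  lone <- wing_morphology(setae = wing$setae[1])
  expect_equal(mass_properties(lone)$inertia,
               mass_properties(wing$setae[[1]], origin = c(0, 0, 0))$inertia)

  # planar wing in the xy-plane: Izz is the largest diagonal entry
  expect_true(mp_all$inertia[3, 3] >= max(diag(mp_all$inertia)) - 1e-12)
  validate_mass_properties(mp_all)
})

test_that("membranous substitute mass is exactly linear in thickness", {
  m <- default_morph()
  s1 <- membranous_substitute(m$wing, 0.73)
  s2 <- membranous_substitute(m$wing, 1.12)
  mp1 <- mass_properties(s1, step = 4)
  mp2 <- mass_properties(s2, step = 4)
  expect_equal(mp1$mass / mp2$mass, 0.73 / 1.12, tolerance = 1e-12)
  # same outline, so the whole tensor scales identically
  expect_equal(mp1$inertia, (0.73 / 1.12) * mp2$inertia, tolerance = 1e-12)
})

test_that("substitute outline contains the blade for a convex fan", {
  m <- default_morph()
  sub <- membranous_substitute(m$wing, 1)
  a_sub <- bristlewing:::polygon_moments(sub$boundary)$area
  a_blade <- bristlewing:::polygon_moments(m$wing$blade$boundary)$area
  expect_gt(a_sub, a_blade)
  # every blade vertex lies inside the substitute outline
  bv <- m$wing$blade$boundary
  inside <- bristlewing:::points_in_polygon(bv[, 1], bv[, 2], sub$boundary)
  expect_true(all(inside))
})

test_that("self-intersecting tip polylines are rejected with segment ids", {
  m <- default_morph()
  wing <- m$wing
  # swap two setae to force a bow-tie in the tip polyline
  wing$setae[c(10, 30)] <- wing$setae[c(30, 10)]
  expect_error(membranous_substitute(wing, 1), "segments \\d+ and \\d+")
})

test_that("morphology round-trips through the YAML config format", {
  m <- default_morph()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_morphology(m$wing, path)
  back <- read_morphology(path)
  mp1 <- mass_properties(m$wing, step = 6)
  mp2 <- mass_properties(back, step = 6)
  expect_equal(mp2$mass, mp1$mass, tolerance = 1e-6)
  expect_equal(mp2$inertia, mp1$inertia, tolerance = 1e-6)
})
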