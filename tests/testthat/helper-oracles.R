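# Independent brute-force oracles used across the suite. These
# deliberately avoid the package's own quadrature/inertia code paths.

# point-mass properties of a set of points with weights
point_mass_properties <- function(pts, w, origin) {
  m <- sum(w)
  com <- colSums(pts * w) / m
  r <- sweep(pts, 2, origin)
  r2 <- rowSums(r^2)
  I <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    I[a, b] <- sum(w * (if (a == b) r2 - r[, a]^2 else -r[, a] * r[, b]))
  }
  list(mass = m, com = com, inertia = I)
}

# thin rod discretised into n point masses at segment midpoints
rod_oracle <- function(seta, origin, n = 1e6) {
  s <- (seq_len(n) - 0.5) / n * seta$length
  pts <- cbind(seta$base[1] + s * seta$direction[1],
               seta$base[2] + s * seta$direction[2],
               seta$base[3] + s * seta$direction[3])
  w <- rep(seta$linear_density * seta$length / n, n)
  point_mass_properties(pts, w, origin)
}

# stand-alone even-odd ray casting (horizontal ray), vectorised over points
raycast_inside <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# membrane patch discretised on a deterministic grid of ~n points
patch_oracle <- function(patch, origin, n = 1e6) {
  poly <- patch$boundary
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  aspect <- diff(yr) / diff(xr)
  nx <- max(2, round(sqrt(n / aspect)))
  ny <- max(2, round(nx * aspect))
  gx <- seq(xr[1], xr[2], length.out = nx + 1); gx <- (gx[-1] + gx[-(nx + 1)]) / 2
  gy <- seq(yr[1], yr[2], length.out = ny + 1); gy <- (gy[-1] + gy[-(ny + 1)]) / 2
  px <- rep(gx, times = ny); py <- rep(gy, each = nx)
  keep <- raycast_inside(px, py, poly)
  px <- px[keep]; py <- py[keep]
  cell <- (diff(xr) / nx) * (diff(yr) / ny)
  p3 <- cbind(px, py, 0) %*% t(patch$rotation)
  p3 <- sweep(p3, 2, -patch$offset, "-")
  w <- rep(patch$density * patch$thickness * cell, length(px))
  point_mass_properties(p3, w, origin)
}

# exact polygon area moments about the origin for simple hand fixtures,
# via dense point sampling (used only on small shapes)
expect_tensor_close <- function(mp, oracle, tol) {
  scale <- max(abs(oracle$inertia))
  expect_lt(max(abs(mp$inertia - oracle$inertia)) / scale, tol)
  expect_lt(abs(mp$mass - oracle$mass) / oracle$mass, tol)
  expect_lt(max(abs(mp$com - oracle$com)), tol * max(1, max(abs(oracle$com))))
}

random_rotation <- function() {
  # QR of a random normal matrix, det forced to +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# shared default morphology, built once per test session
default_morph <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_morphology()
    cache
  }
})

default_protocol <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_protocol(protocol_spec(noise_sd = 0), default_morph()$planform)
    }
    cache
  }
})

# clean one-cycle kinematics of a part on an n-point phase grid
clean_kin <- function(part = "left_wing", n = 512, proto = default_protocol(),
                      planform = NULL) {
  x <- (seq_len(n) - 1) / n
  ang <- proto$truth$clean(part, x)
  if (is.null(planform)) {
    planform <- if (grepl("wing", part)) default_morph()$planform
                else wing_planform(default_morph()$elytron)
  }
  derive_kinematics(ang, proto$frames[[part]], planform, f = proto$truth$f)
}

in_windows <- function(phase, windows) {
  keep <- rep(FALSE, length(phase))
  for (w in windows) {
    keep <- keep | (if (w[1] <= w[2]) phase >= w[1] & phase <= w[2]
                    else phase >= w[1] | phase <= w[2])
  }
  keep
}
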