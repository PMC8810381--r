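#' Setal rod
#'
#' A seta (bristle) of the wing fringe, modelled as a thin straight rod
#' with uniform linear mass density. This is the standard reduction for
#' ptiliid wing bristles: the secondary outgrowths covering each seta are
#' not resolved geometrically but absorbed into the linear density.
#'
#' @param base numeric 3-vector, rod base point (um), in wing base-frame
#'   coordinates.
#' @param direction numeric 3-vector, rod direction; normalised
#'   internally. Give either `direction` + `length` or `tip`.
#' @param tip numeric 3-vector, rod tip point (um); alternative to
#'   `direction`/`length`.
#' @param length rod length L (um), > 0.
#' @param linear_density linear mass density lambda (ug/um), > 0. The
#'   default 9.6e-7 ug/um corresponds to 0.96 ug/m, a measured value for
#'   featherwing-beetle setae with secondary outgrowths.
#' @return object of class `seta_rod`.
#' @export
seta_rod <- function(base, direction = NULL, tip = NULL, length = NULL,
                     linear_density = 9.6e-7) {
  base <- as.numeric(base)
  stopifnot(length(base) == 3)
  if (!is.null(tip)) {
    tip <- as.numeric(tip)
    stopifnot(length(tip) == 3)
    d <- tip - base
    length <- sqrt(sum(d^2))
    if (length <= 0) stop("zero-length seta rod: tip equals base", call. = FALSE)
    direction <- d / length
  } else {
    if (is.null(direction) || is.null(length)) {
      stop("give either `tip` or both `direction` and `length`", call. = FALSE)
    }
    direction <- as.numeric(direction)
    stopifnot(length(direction) == 3)
    nrm <- sqrt(sum(direction^2))
    if (nrm == 0) stop("seta direction must be non-zero", call. = FALSE)
    direction <- direction / nrm
  }
  if (!is.numeric(length) || length <= 0) {
    stop("zero-length seta rod rejected: length must be > 0", call. = FALSE)
  }
  if (!is.numeric(linear_density) || linear_density <= 0) {
    stop("seta linear density must be > 0", call. = FALSE)
  }
  structure(
    list(base = base, direction = direction, length = as.numeric(length),
         linear_density = as.numeric(linear_density)),
    class = "seta_rod"
  )
}

#' Membrane patch
#'
#' A planar cuticle membrane of constant thickness bounded by a simple
#' polygon, used for the petiole and the wing blade (and for membranous
#' substitute wings). The polygon lives in a local 2-D plane; `rotation`
#' and `offset` place it in the wing base frame (identity placement puts
#' it in the frame's xy-plane).
#'
#' @param boundary n x 2 matrix/data frame of ordered vertices (um);
#'   closed implicitly, must be simple (non-self-intersecting).
#' @param thickness membrane thickness h (um), > 0.
#' @param density cuticle volume density rho_c (ug/um^3), > 0. Default
#'   1.2e-6 ug/um^3 = 1200 kg/m^3, the usual insect-cuticle value.
#' @param rotation 3x3 rotation placing the patch plane in the base
#'   frame; `offset` numeric 3-vector translation (um).
#' @return object of class `membrane_patch`.
#' @export
membrane_patch <- function(boundary, thickness,
                           density = density_si_to_internal(1200),
                           rotation = diag(3), offset = c(0, 0, 0)) {
  xy <- as_polygon_matrix(boundary)
  bad <- polygon_self_intersection(xy)
  if (!is.null(bad)) {
    stop(sprintf("membrane boundary self-intersects: edges %d and %d cross",
                 bad[1], bad[2]), call. = FALSE)
  }
  polygon_moments(xy) # errors on degenerate (zero-area) boundaries
  if (!is.numeric(thickness) || thickness <= 0) {
    stop("membrane thickness must be > 0", call. = FALSE)
  }
  if (!is.numeric(density) || density <= 0) {
    stop("cuticle density must be > 0", call. = FALSE)
  }
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)))
  structure(
    list(boundary = xy, thickness = as.numeric(thickness),
         density = as.numeric(density), rotation = rotation,
         offset = as.numeric(offset)),
    class = "membrane_patch"
  )
}

#' Wing morphology
#'
#' Composite rigid-wing geometry of a bristled wing: a petiole (stalk), a
#' narrow wing blade, and a fringe of setae, all expressed in a common
#' wing base frame whose origin is the articulation point and whose x
#' axis is spanwise, y chordwise, z wing-normal.
#'
#' @param petiole,blade [membrane_patch()] objects (either may be `NULL`
#'   for degenerate test geometries).
#' @param setae list of [seta_rod()] objects.
#' @param base_frame list with `origin` (3-vector, um) and `axes` (3x3
#'   orthonormal matrix, columns = x/y/z axes in lab coordinates).
#'   Defaults to the identity frame.
#' @param seta_base_tol tolerance (um) for checking that seta bases lie
#'   on the blade boundary; `Inf` disables the check.
#' @return object of class `wing_morphology`.
#' @export
wing_morphology <- function(petiole = NULL, blade = NULL, setae = list(),
                            base_frame = NULL, seta_base_tol = 15) {
  if (is.null(base_frame)) {
    base_frame <- list(origin = c(0, 0, 0), axes = diag(3))
  }
  ax <- as.matrix(base_frame$axes)
  if (max(abs(crossprod(ax) - diag(3))) > 1e-8) {
    stop("base_frame axes must be orthonormal", call. = FALSE)
  }
  stopifnot(is.list(setae))
  for (s in setae) {
    if (!inherits(s, "seta_rod")) stop("setae must be seta_rod objects", call. = FALSE)
  }
  if (!is.null(blade) && length(setae) > 0 && is.finite(seta_base_tol)) {
    bnd <- patch_boundary_3d(blade)
    for (k in seq_along(setae)) {
      d <- point_polyline_distance(setae[[k]]$base, bnd)
      if (d > seta_base_tol) {
        stop(sprintf("seta %d base lies %.1f um from the blade boundary (tol %.1f um)",
                     k, d, seta_base_tol), call. = FALSE)
      }
    }
  }
  structure(
    list(petiole = petiole, blade = blade, setae = setae,
         base_frame = list(origin = as.numeric(base_frame$origin), axes = ax)),
    class = "wing_morphology"
  )
}

# closed boundary of a patch mapped to base-frame 3-D coordinates
patch_boundary_3d <- function(patch) {
  xy <- patch$boundary
  p3 <- cbind(xy, 0) %*% t(patch$rotation)
  sweep(p3, 2, -patch$offset, "-")
}

point_polyline_distance <- function(p, poly) {
  n <- nrow(poly)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  dmin <- Inf
  for (k in seq_len(n)) {
    a <- poly[idx[k, 1], ]; b <- poly[idx[k, 2], ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
    t <- min(max(t, 0), 1)
    dmin <- min(dmin, sqrt(sum((p - (a + t * ab))^2)))
  }
  dmin
}

new_mass_properties <- function(mass, com, inertia, origin) {
  inertia <- (inertia + t(inertia)) / 2 # enforce exact symmetry
  structure(
    list(mass = mass, com = as.numeric(com), inertia = inertia,
         origin = as.numeric(origin)),
    class = "mass_properties"
  )
}

#' @export
print.mass_properties <- function(x, ...) {
  cat(sprintf("<mass_properties> m = %.4g ug, com = (%.4g, %.4g, %.4g) um\n",
              x$mass, x$com[1], x$com[2], x$com[3]))
  cat("inertia tensor (ug um^2) about origin (",
      paste(signif(x$origin, 4), collapse = ", "), "):\n", sep = "")
  print(signif(x$inertia, 6))
  invisible(x)
}

#' Validate a mass-properties object
#'
#' Checks positivity of the mass, symmetry and positive semi-definiteness
#' of the inertia tensor, and the triangle inequalities on the principal
#' moments (I1 + I2 >= I3 and permutations), which any physical mass
#' distribution must satisfy.
#'
#' @param x a `mass_properties` object.
#' @param tol relative tolerance for the checks.
#' @return `x`, invisibly; errors when a check fails.
#' @export
validate_mass_properties <- function(x, tol = 1e-8) {
  stopifnot(inherits(x, "mass_properties"))
  if (!(x$mass > 0)) stop("mass must be > 0", call. = FALSE)
  s <- max(abs(x$inertia), 1)
  if (max(abs(x$inertia - t(x$inertia))) > tol * s) {
    stop("inertia tensor is not symmetric", call. = FALSE)
  }
  ev <- eigen(x$inertia, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * s) stop("inertia tensor is not positive semi-definite", call. = FALSE)
  ev <- sort(ev, decreasing = TRUE)
  if (ev[2] + ev[3] < ev[1] - tol * s) {
    stop("principal moments violate the triangle inequality", call. = FALSE)
  }
  invisible(x)
}

# I about `origin` given I about the centre of mass (parallel-axis theorem)
shift_inertia_from_com <- function(i_com, mass, com, origin) {
  d <- as.numeric(com) - as.numeric(origin)
  i_com + mass * (sum(d^2) * diag(3) - outer(d, d))
}

#' Mass properties of wing components
#'
#' Computes mass, centre of mass, and the 3x3 inertia tensor (ug um^2)
#' about a reference `origin` in wing base-frame axes.
#'
#' * For a [seta_rod()], the thin-rod formula is used: m = lambda L,
#'   I_com = (m L^2 / 12)(E - u u^T) for unit direction u, shifted to the
#'   origin with the parallel-axis theorem.
#' * For a [membrane_patch()], a midpoint quadrature over a square grid
#'   of the given `step` is used; grid cells cut by the boundary are
#'   weighted by the area fraction inside (estimated on a `subdiv` x
#'   `subdiv` subgrid). The result converges to the exact polygon
#'   integrals as `step -> 0`.
#' * For a [wing_morphology()], contributions of petiole, blade and all
#'   setae are summed about the common base-frame origin.
#'
#' @param x object to measure.
#' @param origin numeric 3-vector (um), reference point for the inertia
#'   tensor, in base-frame coordinates.
#' @param step quadrature step (um) for membrane patches. The default
#'   2 um resolves even the ~30 um petiole; coarser steps (e.g. 50 um)
#'   may be supplied for quick estimates.
#' @param subdiv boundary-cell area-fraction subdivision.
#' @param ... passed between methods.
#' @return a `mass_properties` object.
#' @export
mass_properties <- function(x, ...) UseMethod("mass_properties")

#' @rdname mass_properties
#' @export
mass_properties.seta_rod <- function(x, origin = c(0, 0, 0), ...) {
  m <- x$linear_density * x$length
  com <- x$base + (x$length / 2) * x$direction
  u <- x$direction
  i_com <- (m * x$length^2 / 12) * (diag(3) - outer(u, u))
  new_mass_properties(m, com, shift_inertia_from_com(i_com, m, com, origin), origin)
}

#' @rdname mass_properties
#' @export
mass_properties.membrane_patch <- function(x, origin = c(0, 0, 0), step = 2,
                                           subdiv = 4, ...) {
  if (!is.numeric(step) || step <= 0) stop("quadrature step must be > 0", call. = FALSE)
  q <- membrane_quadrature(x, step = step, subdiv = subdiv)
  if (sum(q$w) <= 0) stop("degenerate polygon: quadrature found no interior", call. = FALSE)
  sigma <- x$density * x$thickness # surface density, ug/um^2
  w <- q$w * sigma
  pts <- q$points
  m <- sum(w)
  com <- colSums(pts * w) / m
  r <- sweep(pts, 2, as.numeric(origin))
  r2 <- rowSums(r^2)
  imat <- matrix(0, 3, 3)
  for (a in 1:3) {
    for (b in a:3) {
      v <- sum(w * (if (a == b) r2 - r[, a]^2 else -r[, a] * r[, b]))
      imat[a, b] <- v; imat[b, a] <- v
    }
  }
  new_mass_properties(m, com, imat, origin)
}

# Midpoint quadrature nodes (3-D, base frame) and area weights (um^2).
membrane_quadrature <- function(patch, step, subdiv = 4) {
  xy <- patch$boundary
  m <- polygon_moments(xy) # also validates non-degeneracy
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  if (xr[1] + step / 2 > xr[2] || yr[1] + step / 2 > yr[2]) {
    stop("quadrature step larger than the polygon; reduce `step`", call. = FALSE)
  }
  gx <- seq(xr[1] + step / 2, xr[2], by = step)
  gy <- seq(yr[1] + step / 2, yr[2], by = step)
  cx <- rep(gx, times = length(gy))
  cy <- rep(gy, each = length(gx))
  half <- step / 2
  # classify cells by their corners: all-in -> full weight, all-out and
  # far from boundary -> skipped, else subdivide
  corner_in <- matrix(FALSE, length(cx), 4)
  dx <- c(-half, half, -half, half); dy <- c(-half, -half, half, half)
  for (k in 1:4) corner_in[, k] <- points_in_polygon(cx + dx[k], cy + dy[k], xy)
  n_in <- rowSums(corner_in)
  centre_in <- points_in_polygon(cx, cy, xy)
  full <- n_in == 4
  partial <- !full & (n_in > 0 | centre_in)
  w <- numeric(length(cx))
  w[full] <- step^2
  if (any(partial)) {
    off <- (seq_len(subdiv) - 0.5) / subdiv * step - half
    sx <- rep(off, times = subdiv); sy <- rep(off, each = subdiv)
    px <- rep(cx[partial], each = subdiv^2) + rep(sx, times = sum(partial))
    py <- rep(cy[partial], each = subdiv^2) + rep(sy, times = sum(partial))
    inside <- points_in_polygon(px, py, xy)
    frac <- colSums(matrix(inside, nrow = subdiv^2)) / subdiv^2
    w[partial] <- frac * step^2
  }
  keep <- w > 0
  p3 <- cbind(cx[keep], cy[keep], 0) %*% t(patch$rotation)
  p3 <- sweep(p3, 2, -patch$offset, "-")
  list(points = p3, w = w[keep])
}

#' @rdname mass_properties
#' @export
mass_properties.wing_morphology <- function(x, origin = c(0, 0, 0), step = 2,
                                            ...) {
  parts <- list()
  if (!is.null(x$petiole)) parts <- c(parts, list(mass_properties(x$petiole, origin, step = step, ...)))
  if (!is.null(x$blade)) parts <- c(parts, list(mass_properties(x$blade, origin, step = step, ...)))
  for (s in x$setae) parts <- c(parts, list(mass_properties(s, origin)))
  if (length(parts) == 0) stop("wing has no components", call. = FALSE)
  combine_mass_properties(parts)
}

#' Combine mass properties of rigid components
#'
#' Masses add, centres of mass combine mass-weighted, and inertia tensors
#' about a common origin add. All inputs must share the same origin.
#'
#' @param parts list of `mass_properties` objects about a common origin.
#' @return a `mass_properties` object.
#' @export
combine_mass_properties <- function(parts) {
  org <- parts[[1]]$origin
  for (p in parts) {
    if (max(abs(p$origin - org)) > 1e-9) {
      stop("all components must share the same reference origin", call. = FALSE)
    }
  }
  m <- sum(vapply(parts, function(p) p$mass, 0))
  com <- Reduce(`+`, lapply(parts, function(p) p$mass * p$com)) / m
  imat <- Reduce(`+`, lapply(parts, function(p) p$inertia))
  new_mass_properties(m, com, imat, org)
}

#' Re-reference an inertia tensor to a new origin
#'
#' Applies the parallel-axis theorem twice: from the stored origin to the
#' centre of mass and from there to `origin`.
#'
#' @param x a `mass_properties` object.
#' @param origin new reference point (um).
#' @return a `mass_properties` object about `origin`.
#' @export
shift_origin <- function(x, origin) {
  stopifnot(inherits(x, "mass_properties"))
  d <- x$com - x$origin
  i_com <- x$inertia - x$mass * (sum(d^2) * diag(3) - outer(d, d))
  new_mass_properties(x$mass, x$com,
                      shift_inertia_from_com(i_com, x$mass, x$com, origin),
                      origin)
}

#' Membranous substitute wing
#'
#' Builds the outline of a hypothetical membranous wing with the same
#' aerodynamically effective shape as a bristled wing: the perimeter is
#' the proximal margin (wing-root edge) continued by the polyline through
#' the seta tips, in the order the setae are listed. The cuticle density
#' is inherited from the blade. Substitute mass is exactly linear in the
#' chosen thickness.
#'
#' @param wing a [wing_morphology()] with at least 3 setae.
#' @param thickness membrane thickness (um) of the substitute.
#' @param margin optional n x 2 matrix of proximal outline points (um)
#'   preceding the tip polyline; defaults to the two petiole root
#'   vertices nearest the base-frame origin (or the origin itself when no
#'   petiole is present). The caller is responsible for margin order.
#' @return a [membrane_patch()] for the substitute membrane.
#' @export
membranous_substitute <- function(wing, thickness, margin = NULL) {
  stopifnot(inherits(wing, "wing_morphology"))
  if (length(wing$setae) < 3) stop("need at least 3 setae to form a substitute outline", call. = FALSE)
  tips <- t(vapply(wing$setae, function(s) s$base + s$length * s$direction, numeric(3)))
  tips2 <- tips[, 1:2, drop = FALSE]
  if (is.null(margin)) {
    margin <- default_root_margin(wing)
  }
  boundary <- rbind(as.matrix(margin), tips2)
  bad <- polygon_self_intersection(boundary)
  if (!is.null(bad)) {
    stop(sprintf(paste0("substitute outline self-intersects: boundary segments ",
                        "%d and %d cross; check seta ordering"),
                 bad[1], bad[2]), call. = FALSE)
  }
  dens <- if (!is.null(wing$blade)) wing$blade$density else density_si_to_internal(1200)
  membrane_patch(boundary, thickness = thickness, density = dens)
}

default_root_margin <- function(wing) {
  if (is.null(wing$petiole)) return(matrix(0, 1, 2))
  xy <- wing$petiole$boundary
  d <- sqrt(rowSums(xy^2))
  idx <- order(d)[1:2]
  # order the two root vertices so the outline runs root -> tips -> root
  xy[sort(idx, decreasing = TRUE), , drop = FALSE]
}

#' Aerodynamic planform summary of a wing outline
#'
#' Reduces an effective wing outline (typically the membranous-substitute
#' boundary) to the scalars used in aerodynamic scaling: wing length R,
#' area S, mean chord `cbar = S/R`, and the area-based radius of gyration
#' `Rg = sqrt(int r^2 dS / S)` with r the in-plane distance from the wing
#' base. Rg is the representative span station for wing velocity.
#'
#' @param outline n x 2 vertex matrix (um) of the effective outline,
#'   with the wing base at the local origin, or a [membrane_patch()].
#' @param R optional wing length (um); defaults to the largest vertex
#'   distance from the origin.
#' @return a tibble with one row: `R`, `S`, `cbar`, `Rg` (um, um^2, um, um).
#' @export
wing_planform <- function(outline, R = NULL) {
  if (inherits(outline, "membrane_patch")) outline <- outline$boundary
  xy <- as_polygon_matrix(outline)
  mom <- polygon_moments(xy)
  if (is.null(R)) R <- max(sqrt(rowSums(xy^2)))
  S <- mom$area
  rg <- sqrt((mom$ixx + mom$iyy) / S) # polar second moment about the base
  if (!(rg < R && rg > 0)) stop("invalid planform: Rg must lie in (0, R)", call. = FALSE)
  tibble::tibble(R = R, S = S, cbar = S / R, Rg = rg)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mass-properties object
#'
#' @param x a `mass_properties` object.
#' @param ... unused.
#' @return one-row tibble with mass (ug), centre-of-mass coordinates (um)
#'   and the six distinct inertia-tensor entries (ug um^2).
#' @export
tidy.mass_properties <- function(x, ...) {
  tibble::tibble(
    mass = x$mass,
    com_x = x$com[1], com_y = x$com[2], com_z = x$com[3],
    ixx = x$inertia[1, 1], iyy = x$inertia[2, 2], izz = x$inertia[3, 3],
    ixy = x$inertia[1, 2], ixz = x$inertia[1, 3], iyz = x$inertia[2, 3]
  )
}
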