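#' Stroke-plane reference frame
#'
#' The stroke plane is the best-fit plane of the wingtip path through the
#' wing base; all Euler angles are measured in its frame. The frame is a
#' right-handed orthonormal triple (u, v, n): `u` and `v` span the plane
#' (by default `u` is the horizontal in-plane direction and `v` points
#' up-slope), `n` is the plane normal. `beta` is the pitch of the stroke
#' plane to the horizon in degrees (0 for a horizontal plane).
#'
#' For the right-hand side of a bilaterally symmetric animal, pass the
#' mirrored `u` and `normal` explicitly (e.g. `u = c(0, -1, 0)` and the
#' negated normal); the constructor only requires right-handedness.
#'
#' @param origin wing-base point (um, lab frame).
#' @param normal plane unit normal (normalised internally).
#' @param u optional in-plane unit axis; default: horizontal in-plane
#'   direction `z x n` (or the lab x axis for a horizontal plane).
#' @return object of class `stroke_frame` with fields `origin`, `u`,
#'   `v`, `normal`, `beta`.
#' @export
stroke_frame <- function(origin, normal, u = NULL) {
  origin <- as.numeric(origin)
  n <- as.numeric(normal)
  n <- n / sqrt(sum(n^2))
  if (is.null(u)) {
    zxn <- c(-n[2], n[1], 0)
    if (sqrt(sum(zxn^2)) < 1e-9) {
      u <- c(1, 0, 0)
    } else {
      u <- zxn / sqrt(sum(zxn^2))
    }
  } else {
    u <- as.numeric(u)
    u <- u - sum(u * n) * n
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) stop("`u` must not be parallel to the plane normal", call. = FALSE)
    u <- u / nu
  }
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1]) # v = n x u so that u x v = n
  beta <- rad2deg(acos(min(1, abs(n[3]))))
  structure(list(origin = origin, u = u, v = v, normal = n, beta = beta),
            class = "stroke_frame")
}

#' @export
print.stroke_frame <- function(x, ...) {
  cat(sprintf("<stroke_frame> beta = %.2f deg, origin = (%.3g, %.3g, %.3g) um\n",
              x$beta, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

frame_basis <- function(frame) cbind(frame$u, frame$v, frame$normal)

#' Fit the stroke plane to a wingtip point cloud
#'
#' Total-least-squares (major-axis) fit: the plane through the wing base
#' whose normal is the smallest-variance principal direction of the tip
#' coordinates. This is preferred over an ordinary linear trend when the
#' tip trajectory forms a wide scatter, as in wide figure-of-eight
#' wingbeats.
#'
#' @param tips n x 3 matrix (or data frame with columns x, y, z) of
#'   wingtip positions (um, lab frame).
#' @param base wing-base point (um, lab frame).
#' @param collinear_tol relative tolerance below which the cloud is
#'   treated as collinear (plane undefined).
#' @return a [stroke_frame()].
#' @export
fit_stroke_plane <- function(tips, base, collinear_tol = 1e-8) {
  pts <- as.matrix(as.data.frame(tips)[, 1:3])
  if (nrow(pts) < 3) stop("need at least 3 tip points", call. = FALSE)
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  sdev <- pc$sdev
  if (sdev[2] <= collinear_tol * max(sdev[1], 1e-300)) {
    stop("tip cloud is collinear: stroke plane undefined", call. = FALSE)
  }
  n <- pc$rotation[, 3]
  if (n[3] < 0) n <- -n
  stroke_frame(origin = base, normal = n)
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# Wing rotation in stroke-frame coordinates. Convention (fixed for this
# package, the standard hovering-insect order): positional angle phi
# about the plane normal, then stroke deviation theta out of the plane,
# then pitch psi about the spanwise (base-apex) axis. Local wing axes:
# x = span, y = chord, z = wing surface normal.
wing_rotation_frame <- function(theta, phi, psi) {
  rot_z(phi) %*% rot_y(-theta) %*% rot_x(psi)
}

#' Wing pose from Euler angles
#'
#' Maps Euler angles (degrees) to the wing pose in the lab frame: unit
#' span, chord and wing-normal vectors and the tip position. The
#' rotation order is positional `phi` about the stroke-plane normal,
#' then deviation `theta` out of the plane, then pitch `psi` about the
#' spanwise axis. With theta = psi = 0 and increasing phi the tip moves
#' on a circle of radius `span` in the stroke plane; psi = 90 deg puts
#' the chord perpendicular to the stroke plane.
#'
#' @param angles data frame with columns `theta`, `phi`, `psi` (deg);
#'   a column `t` or `phase` is carried through if present.
#' @param frame a [stroke_frame()].
#' @param span wing length R (um) used for the tip position.
#' @return tibble with the input time/phase columns plus span (`sx, sy,
#'   sz`), chord (`cx, cy, cz`), wing normal (`wnx, wny, wnz`) unit
#'   vectors and tip coordinates (`tipx, tipy, tipz`, um, lab frame).
#' @export
pose_from_angles <- function(angles, frame, span = 1) {
  stopifnot(inherits(frame, "stroke_frame"))
  th <- deg2rad(angles$theta); ph <- deg2rad(angles$phi); ps <- deg2rad(angles$psi)
  B <- frame_basis(frame)
  n <- length(th)
  out <- matrix(NA_real_, n, 9)
  for (i in seq_len(n)) {
    R <- B %*% wing_rotation_frame(th[i], ph[i], ps[i])
    out[i, ] <- c(R[, 1], R[, 2], R[, 3])
  }
  res <- tibble::as_tibble(as.data.frame(out))
  names(res) <- c("sx", "sy", "sz", "cx", "cy", "cz", "wnx", "wny", "wnz")
  res$tipx <- frame$origin[1] + span * res$sx
  res$tipy <- frame$origin[2] + span * res$sy
  res$tipz <- frame$origin[3] + span * res$sz
  for (keep in intersect(c("t", "phase"), names(angles))) {
    res[[keep]] <- angles[[keep]]
  }
  dplyr::relocate(res, dplyr::any_of(c("t", "phase")))
}

#' Euler angles from a wing pose
#'
#' Exact inverse of [pose_from_angles()] away from gimbal lock. At
#' `|theta| = 90` deg (span along the plane normal) the positional angle
#' is indeterminate and is returned as `NA` with a warning.
#'
#' @param pose data frame with span (`sx, sy, sz`) and chord (`cx, cy,
#'   cz`) unit-vector columns in lab coordinates.
#' @param frame a [stroke_frame()].
#' @return tibble with columns `theta`, `phi`, `psi` (deg) and a logical
#'   `gimbal` flag.
#' @export
angles_from_pose <- function(pose, frame) {
  stopifnot(inherits(frame, "stroke_frame"))
  B <- frame_basis(frame)
  n <- nrow(pose)
  th <- ph <- ps <- numeric(n)
  gim <- logical(n)
  for (i in seq_len(n)) {
    s <- crossprod(B, c(pose$sx[i], pose$sy[i], pose$sz[i]))[, 1]
    cv <- crossprod(B, c(pose$cx[i], pose$cy[i], pose$cz[i]))[, 1]
    th[i] <- asin(max(-1, min(1, s[3])))
    if (abs(cos(th[i])) < 1e-9) {
      gim[i] <- TRUE
      ph[i] <- NA_real_
      # chord still fixes psi + phi jointly; report psi relative to phi = 0
      ps[i] <- atan2(cv[3] * sign(s[3]), cv[2])
      next
    }
    ph[i] <- atan2(s[2], s[1])
    M <- rot_y(th[i]) %*% rot_z(-ph[i])
    c_local <- M %*% cv
    ps[i] <- atan2(c_local[3], c_local[2])
  }
  if (any(gim)) {
    warning("gimbal lock at |theta| = 90 deg: positional angle indeterminate, returned NA")
  }
  tibble::tibble(theta = rad2deg(th), phi = rad2deg(ph), psi = rad2deg(ps),
                 gimbal = gim)
}

#' Mirror Euler angles across the sagittal plane
#'
#' Left and right wings are described in their own (mirror-image,
#' right-handed) stroke frames. A motion that is the exact mirror of a
#' left-wing motion has the same positional angle but opposite deviation
#' and pitch in the right-wing frame. This map brings right-wing angles
#' into the left-wing convention (it is an involution).
#'
#' @param angles data frame with columns `theta`, `phi`, `psi`.
#' @return the same data frame with `theta` and `psi` negated.
#' @export
mirror_angles <- function(angles) {
  angles$theta <- -angles$theta
  angles$psi <- -angles$psi
  angles
}

# Lab-frame angular velocity (rad/ms) of a wing from Euler angles and
# their time derivatives (deg, deg/ms).
wing_angular_velocity <- function(theta, phi, psi, dtheta, dphi, dpsi, frame) {
  B <- frame_basis(frame)
  n <- length(theta)
  th <- deg2rad(theta); ph <- deg2rad(phi)
  dth <- deg2rad(dtheta); dph <- deg2rad(dphi); dps <- deg2rad(dpsi)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    w_f <- dph[i] * c(0, 0, 1) +
      rot_z(ph[i]) %*% c(0, -dth[i], 0) +
      rot_z(ph[i]) %*% rot_y(-th[i]) %*% c(dps[i], 0, 0)
    out[i, ] <- (B %*% w_f)[, 1]
  }
  colnames(out) <- c("wx", "wy", "wz")
  out
}
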