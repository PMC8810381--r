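#' Read and write per-part force/torque series
#'
#' The exchange dialect for aerodynamic load series (the format a CFD
#' export would be written to): a delimited text file with `#`-prefixed
#' metadata lines declaring the part, the units and the torque reference
#' point, followed by a header `t,Fx,Fy,Fz,Tx,Ty,Tz`. Units must be
#' declared; `force_unit` may be `ug_um_ms2` (internal, = nN) or `N`,
#' `torque_unit` may be `ug_um2_ms2` (internal) or `N_m`.
#'
#' @param path file path.
#' @param grid optional data frame with a `t` column (ms): when given,
#'   the series is cubic-spline resampled onto it.
#' @return tibble with columns `t`, `fx`, `fy`, `fz`, `tx`, `ty`, `tz`
#'   in internal units, with attributes `part`, `ref_point` (um) and
#'   `reference`.
#' @export
load_force_series <- function(path, grid = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[trimws(key)]] <- val
  }
  for (req in c("force_unit", "torque_unit", "reference_point_um")) {
    if (is.null(meta[[req]])) {
      stop(sprintf("force file %s: missing required metadata line '# %s: ...'",
                   path, req), call. = FALSE)
    }
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  need <- c("t", "Fx", "Fy", "Fz", "Tx", "Ty", "Tz")
  if (!all(need %in% names(df))) {
    stop(sprintf("force file %s: missing columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  }
  if (any(diff(df$t) <= 0)) {
    stop(sprintf("force file %s: time column must be strictly increasing", path),
         call. = FALSE)
  }
  fconv <- switch(meta$force_unit,
                  ug_um_ms2 = 1, N = force_si_to_internal(1),
                  stop("unknown force_unit: ", meta$force_unit, call. = FALSE))
  tconv <- switch(meta$torque_unit,
                  ug_um2_ms2 = 1, N_m = torque_si_to_internal(1),
                  stop("unknown torque_unit: ", meta$torque_unit, call. = FALSE))
  out <- tibble::tibble(
    t = df$t,
    fx = df$Fx * fconv, fy = df$Fy * fconv, fz = df$Fz * fconv,
    tx = df$Tx * tconv, ty = df$Ty * tconv, tz = df$Tz * tconv
  )
  if (!is.null(grid)) {
    tg <- grid$t
    res <- tibble::tibble(t = tg)
    for (cl in c("fx", "fy", "fz", "tx", "ty", "tz")) {
      res[[cl]] <- stats::splinefun(out$t, out[[cl]], method = "fmm")(tg)
    }
    if ("phase" %in% names(grid)) res$phase <- grid$phase
    out <- res
  }
  attr(out, "part") <- meta$part %||% "unknown"
  attr(out, "ref_point") <- as.numeric(strsplit(meta$reference_point_um, "\\s+")[[1]])
  attr(out, "reference") <- meta$reference %||% "unspecified"
  out
}

#' @rdname load_force_series
#' @param forces force tibble in internal units (columns `t`, `fx` ...
#'   `tz`) with the attributes set as produced by package functions.
#' @export
write_force_series <- function(forces, path) {
  rp <- attr(forces, "ref_point") %||% c(0, 0, 0)
  hdr <- c(
    sprintf("# part: %s", attr(forces, "part") %||% "unknown"),
    "# force_unit: ug_um_ms2",
    "# torque_unit: ug_um2_ms2",
    sprintf("# reference_point_um: %s", paste(format(rp, digits = 15), collapse = " ")),
    sprintf("# reference: %s", attr(forces, "reference") %||% "unspecified")
  )
  df <- data.frame(t = forces$t, Fx = forces$fx, Fy = forces$fy, Fz = forces$fz,
                   Tx = forces$tx, Ty = forces$ty, Tz = forces$tz)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quasi-steady surrogate coefficient table
#'
#' A flat-plate-like drag/lift coefficient table versus angle of attack
#' at a reference Reynolds number of about 10: `cd` rises monotonically
#' from edge-on to flat-on, `cl` peaks near 45 deg. These defaults are a
#' desk-scale stand-in calibrated to nothing in particular - they are
#' meant to give force series with the right phase structure and
#' magnitude ordering, not CFD-grade values - and every entry can be
#' replaced by the caller.
#'
#' @param aoa grid of angle-of-attack magnitudes (deg).
#' @param cd0,cd90 edge-on and flat-on drag coefficients.
#' @param clmax maximum lift coefficient (at 45 deg).
#' @return tibble with columns `aoa`, `cd`, `cl`.
#' @export
surrogate_coefficients <- function(aoa = seq(0, 90, by = 5),
                                   cd0 = 0.8, cd90 = 3.4, clmax = 0.9) {
  a <- deg2rad(aoa)
  tibble::tibble(aoa = aoa,
                 cd = cd0 + (cd90 - cd0) * sin(a)^2,
                 cl = clmax * sin(2 * a))
}

#' Quasi-steady blade-element force surrogate
#'
#' Generates a per-part aerodynamic force/torque series from derived
#' kinematics, for desk-scale work when no computed (CFD) force file is
#' available. The model is a single blade element at the radius of
#' gyration: a drag force of magnitude `0.5 rho cd(AoA) S U^2` exactly
#' anti-aligned with the local velocity, plus a lift force of magnitude
#' `0.5 rho cl(AoA) S U^2` perpendicular to the velocity in the
#' chord-velocity plane, pushing away from the side the flow strikes.
#' Coefficients are inflated at low instantaneous Reynolds number by
#' `(1 + k/Re) / (1 + k/re_ref)`.
#'
#' @param kin tibble from [derive_kinematics()].
#' @param coeffs coefficient table as from [surrogate_coefficients()];
#'   negative entries are rejected.
#' @param low_re_k low-Reynolds inflation constant k.
#' @param re_ref reference Reynolds number of the table.
#' @param part part label recorded on the output.
#' @return force tibble (`t`, `phase`, `fx` ... `tz`) in internal units;
#'   torque is about the wing base (the stroke-frame origin), which is
#'   recorded in the `ref_point` attribute.
#' @export
quasisteady_surrogate <- function(kin, coeffs = surrogate_coefficients(),
                                  low_re_k = 10, re_ref = 10,
                                  part = "wing") {
  if (any(coeffs$cd < 0) || any(coeffs$cl < 0)) {
    stop("negative aerodynamic coefficients rejected", call. = FALSE)
  }
  planform <- attr(kin, "planform")
  fluid <- attr(kin, "fluid")
  frame <- attr(kin, "frame")
  cd_fun <- stats::approxfun(coeffs$aoa, coeffs$cd, rule = 2)
  cl_fun <- stats::approxfun(coeffs$aoa, coeffs$cl, rule = 2)
  n <- nrow(kin)
  F <- matrix(0, n, 3)
  speed <- kin$speed
  ok <- !kin$gap & speed > 0
  q <- 0.5 * fluid$rho * planform$S * speed^2
  infl <- (1 + low_re_k / pmax(kin$re, 1e-12)) / (1 + low_re_k / re_ref)
  vhat <- cbind(kin$vx, kin$vy, kin$vz) / pmax(speed, 1e-300)
  nw <- cbind(kin$wnx, kin$wny, kin$wnz)
  ndotv <- rowSums(nw * vhat)
  lvec <- nw - ndotv * vhat
  lnorm <- sqrt(rowSums(lvec^2))
  lhat <- lvec / pmax(lnorm, 1e-300)
  lhat <- lhat * (-sign(ndotv)) # push away from the struck face
  aoa_mag <- abs(kin$aoa)
  drag_mag <- q * cd_fun(aoa_mag) * infl
  lift_mag <- q * cl_fun(aoa_mag) * infl
  lift_mag[lnorm < 1e-9] <- 0 # flow along the wing normal: pure drag
  F[ok, ] <- -drag_mag[ok] * vhat[ok, , drop = FALSE] +
    lift_mag[ok] * lhat[ok, , drop = FALSE]
  # applied at the Rg point; torque about the wing base
  r <- cbind(kin$x - frame$origin[1], kin$y - frame$origin[2],
             kin$z - frame$origin[3])
  tq <- cbind(r[, 2] * F[, 3] - r[, 3] * F[, 2],
              r[, 3] * F[, 1] - r[, 1] * F[, 3],
              r[, 1] * F[, 2] - r[, 2] * F[, 1])
  out <- tibble::tibble(
    t = kin$t, phase = kin$phase,
    fx = F[, 1], fy = F[, 2], fz = F[, 3],
    tx = tq[, 1], ty = tq[, 2], tz = tq[, 3]
  )
  attr(out, "part") <- part
  attr(out, "ref_point") <- frame$origin
  attr(out, "reference") <- "wing_base"
  attr(out, "model") <- "quasisteady_surrogate"
  out
}

#' Shift the torque reference point of a force series
#'
#' `tau_new = tau_ref + (r_ref - r_new) x F`, using the concurrent force
#' samples.
#'
#' @param forces force tibble with `ref_point` attribute.
#' @param to new reference point (um, lab frame).
#' @param reference label for the new reference point.
#' @return force tibble about `to`.
#' @export
shift_torque_reference <- function(forces, to, reference = "body_com") {
  from <- attr(forces, "ref_point")
  if (is.null(from)) stop("force series has no recorded reference point", call. = FALSE)
  d <- as.numeric(from) - as.numeric(to)
  out <- forces
  out$tx <- forces$tx + d[2] * forces$fz - d[3] * forces$fy
  out$ty <- forces$ty + d[3] * forces$fx - d[1] * forces$fz
  out$tz <- forces$tz + d[1] * forces$fy - d[2] * forces$fx
  attr(out, "ref_point") <- as.numeric(to)
  attr(out, "reference") <- reference
  out
}

#' Lift/drag decomposition of an aerodynamic force series
#'
#' The drag component of the total instantaneous force is its projection
#' on the direction of the wing velocity at the radius of gyration,
#' `drag = (F . vhat) vhat`; the lift component is the vector remainder
#' `lift = F - drag`. By construction drag is parallel to the velocity,
#' lift is perpendicular to it, and their sum reconstructs the total
#' exactly; these invariants are asserted on every call. Both components
#' are also projected on the vertical (z) axis. At samples where the
#' velocity vanishes the decomposition is undefined; such samples are
#' reported as gaps (`NA`), never interpolated.
#'
#' @param forces force tibble (columns `fx`, `fy`, `fz`).
#' @param velocity tibble on the same grid with columns `vx`, `vy`,
#'   `vz` and optionally `gap` (as from [derive_kinematics()]).
#' @param speed_tol speed below which a sample is treated as a gap.
#' @return tibble with drag (`dx, dy, dz`), lift (`lx, ly, lz`), their
#'   vertical components `drag_z`, `lift_z`, and `gap`.
#' @export
decompose <- function(forces, velocity, speed_tol = 1e-9) {
  if (nrow(forces) != nrow(velocity)) {
    stop("forces and velocity must be on a common grid", call. = FALSE)
  }
  v <- cbind(velocity$vx, velocity$vy, velocity$vz)
  speed <- sqrt(rowSums(v^2))
  gap <- speed < speed_tol
  if (!is.null(velocity[["gap"]])) gap <- gap | velocity[["gap"]]
  vhat <- v / pmax(speed, 1e-300)
  F <- cbind(forces$fx, forces$fy, forces$fz)
  proj <- rowSums(F * vhat)
  drag <- proj * vhat
  lift <- F - drag
  drag[gap, ] <- NA_real_
  lift[gap, ] <- NA_real_
  # exactness and orthogonality invariants
  ok <- !gap
  if (any(ok)) {
    scale <- pmax(sqrt(rowSums(F[ok, , drop = FALSE]^2)), 1e-300)
    recon <- sqrt(rowSums((drag[ok, , drop = FALSE] + lift[ok, , drop = FALSE] -
                             F[ok, , drop = FALSE])^2)) / scale
    orth <- abs(rowSums(lift[ok, , drop = FALSE] * vhat[ok, , drop = FALSE])) / scale
    if (max(recon) > 1e-9 || max(orth) > 1e-9) {
      stop("decomposition invariant violated (numerical failure)", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    dx = drag[, 1], dy = drag[, 2], dz = drag[, 3],
    lx = lift[, 1], ly = lift[, 2], lz = lift[, 3],
    drag_z = drag[, 3], lift_z = lift[, 3], gap = gap
  )
  if (!is.null(forces[["phase"]])) out <- tibble::add_column(out, phase = forces[["phase"]], .before = 1)
  out
}

#' Cycle-averaged vertical-force accounting
#'
#' Averages the vertical aerodynamic force of every body part over the
#' wingbeat cycle, expresses each as a weight-equivalent mass (force /
#' g, in ug), splits the winged parts' vertical force into its drag and
#' lift shares (percent, summing to 100), and reports the implied
#' steady vertical acceleration `(F_total - m g) / m`.
#'
#' @param forces named list of force tibbles (e.g. `left_wing`,
#'   `right_wing`, `left_elytron`, `right_elytron`, `body`), all on a
#'   full-cycle grid.
#' @param decompositions named list of [decompose()] results for the
#'   parts whose drag/lift split is wanted (typically the wings).
#' @param body_mass body mass (ug).
#' @param g gravitational acceleration (um/ms^2, numerically m/s^2).
#' @return object of class `vertical_breakdown`; see [tidy.vertical_breakdown()].
#' @export
vertical_breakdown <- function(forces, decompositions = list(),
                               body_mass, g = 9.81) {
  stopifnot(is.list(forces), length(forces) > 0, body_mass > 0, g > 0)
  per_part <- purrr::imap(forces, function(fs, nm) {
    tibble::tibble(part = nm, mean_vertical = mean(fs$fz),
                   weight_equiv = mean(fs$fz) / g)
  })
  per_part <- dplyr::bind_rows(per_part)
  total <- sum(per_part$mean_vertical)
  drag_sum <- lift_sum <- 0
  for (nm in names(decompositions)) {
    dc <- decompositions[[nm]]
    fs <- forces[[nm]]
    if (any(dc$gap)) {
      bad <- which(dc$gap)
      fmag <- sqrt(fs$fx[bad]^2 + fs$fy[bad]^2 + fs$fz[bad]^2)
      if (any(fmag > 1e-9)) {
        stop("decomposition gaps with non-zero force: drag/lift shares undefined",
             call. = FALSE)
      }
    }
    drag_sum <- drag_sum + mean(ifelse(dc$gap, 0, dc$drag_z))
    lift_sum <- lift_sum + mean(ifelse(dc$gap, 0, dc$lift_z))
  }
  shares <- c(drag = NA_real_, lift = NA_real_)
  if (length(decompositions) > 0) {
    tot_w <- drag_sum + lift_sum
    shares <- 100 * c(drag = drag_sum, lift = lift_sum) / tot_w
  }
  structure(
    list(per_part = per_part, total_vertical = total,
         total_weight_equiv = total / g,
         drag_share = shares[["drag"]], lift_share = shares[["lift"]],
         vertical_acceleration = (total - body_mass * g) / body_mass,
         body_mass = body_mass, g = g),
    class = "vertical_breakdown"
  )
}

#' @export
print.vertical_breakdown <- function(x, ...) {
  cat(sprintf("<vertical_breakdown> total mean vertical force = %.4g nN (%.3g ug weight-equivalent)\n",
              x$total_vertical, x$total_weight_equiv))
  if (!is.na(x$drag_share)) {
    cat(sprintf("  wing vertical force: %.1f%% drag / %.1f%% lift\n",
                x$drag_share, x$lift_share))
  }
  cat(sprintf("  vertical acceleration: %.3g m/s^2\n", x$vertical_acceleration))
  invisible(x)
}

#' Tidy a vertical-force breakdown
#'
#' @param x a `vertical_breakdown` object.
#' @param ... unused.
#' @return tibble with one row per part: mean vertical force (internal
#'   units = nN) and weight-equivalent mass (ug).
#' @export
tidy.vertical_breakdown <- function(x, ...) x$per_part

#' @rdname tidy.vertical_breakdown
#' @export
glance.vertical_breakdown <- function(x, ...) {
  tibble::tibble(
    total_vertical = x$total_vertical,
    total_weight_equiv = x$total_weight_equiv,
    drag_share = x$drag_share, lift_share = x$lift_share,
    vertical_acceleration = x$vertical_acceleration
  )
}
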