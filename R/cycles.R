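#' Resample an angle series on a uniform time grid
#'
#' Cubic-spline interpolation (Forsythe-Malcolm-Moler end conditions, so
#' polynomials up to cubic are reproduced exactly) of every non-time
#' column onto the grid `seq(min(t), max(t), by = dt)`. The first sample
#' time is preserved exactly.
#'
#' @param series data frame with a strictly increasing `t` column (ms)
#'   and numeric value columns (e.g. `theta`, `phi`, `psi` in degrees).
#' @param dt target time step (ms). The default 0.0026 ms corresponds to
#'   the fine grid used for phase analysis (about 1,600 samples per
#'   wingbeat at typical miniature-beetle frequencies).
#' @return tibble on the uniform grid with the same columns.
#' @export
resample_uniform <- function(series, dt = 0.0026) {
  t <- series$t
  if (is.null(t)) stop("series must have a `t` column", call. = FALSE)
  if (length(t) < 4) stop("need at least 4 samples to resample", call. = FALSE)
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  grid <- seq(t[1], t[length(t)], by = dt)
  cols <- setdiff(names(series), "t")
  out <- tibble::tibble(t = grid)
  for (cl in cols) {
    if (!is.numeric(series[[cl]])) next
    out[[cl]] <- stats::splinefun(t, series[[cl]], method = "fmm")(grid)
  }
  out
}

#' Detect wingbeat cycles from the positional angle
#'
#' Cycle boundaries are the rising zero crossings of `phi(t)`, located
#' by root-finding on a cubic-spline interpolant (the convention: any
#' consistent crossing direction defines cycles; rising is fixed here).
#' The cycle period `T` is the mean boundary spacing and the wingbeat
#' frequency is `f = 1/T`.
#'
#' @param series data frame with columns `t` (ms) and `phi` (deg).
#' @param min_gap minimum spacing between crossings, as a fraction of
#'   the median spacing, used to discard duplicate near-zero chatter.
#' @return object of class `cycle_set`: list with `boundaries` (ms),
#'   `T` (ms), `f` (kHz = 1/ms) and `n_cycles`.
#' @export
detect_cycles <- function(series, min_gap = 0.2) {
  t <- series$t; phi <- series$phi
  if (is.null(t) || is.null(phi)) stop("series must have `t` and `phi` columns", call. = FALSE)
  fun <- stats::splinefun(t, phi, method = "fmm")
  up <- which(phi[-length(phi)] < 0 & phi[-1] >= 0)
  if (length(up) < 2) {
    stop("fewer than 2 rising zero crossings of phi: cannot define cycles", call. = FALSE)
  }
  roots <- vapply(up, function(i) {
    stats::uniroot(fun, lower = t[i], upper = t[i + 1], tol = 1e-12)$root
  }, 0)
  if (length(roots) > 2) {
    med <- stats::median(diff(roots))
    keep <- c(TRUE, diff(roots) > min_gap * med)
    roots <- roots[keep]
  }
  if (length(roots) < 2) {
    stop("fewer than 2 well-separated rising zero crossings of phi", call. = FALSE)
  }
  Tm <- mean(diff(roots))
  structure(list(boundaries = roots, T = Tm, f = 1 / Tm,
                 n_cycles = length(roots) - 1L),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycles, T = %.5g ms, f = %.5g kHz\n",
              x$n_cycles, x$T, x$f))
  invisible(x)
}

#' Phase-average Euler-angle cycles across wingbeats and sides
#'
#' Each detected cycle of each side is spline-resampled onto a common
#' phase grid t/T in [0, 1), averaged across cycles, and then the two
#' sides are averaged after mirroring the right side into the left-side
#' convention (see [mirror_angles()]).
#'
#' @param left data frame with columns `t`, `theta`, `phi`, `psi` for
#'   the left-side part.
#' @param right optional matching data frame for the right side.
#' @param cycles optional [detect_cycles()] result; detected from the
#'   left side's `phi` when omitted.
#' @param n_phase number of phase-grid points.
#' @param mirror_right whether to apply [mirror_angles()] to the right
#'   side before averaging (the package's documented convention).
#' @return tibble with columns `phase`, `theta`, `phi`, `psi`;
#'   attributes `T` (ms), `f` (kHz) and `n_cycles`.
#' @export
phase_average <- function(left, right = NULL, cycles = NULL, n_phase = 512,
                          mirror_right = TRUE) {
  if (is.null(cycles)) cycles <- detect_cycles(left)
  stopifnot(inherits(cycles, "cycle_set"))
  grid <- (seq_len(n_phase) - 1) / n_phase
  sides <- list(left)
  if (!is.null(right)) {
    sides <- c(sides, list(if (mirror_right) mirror_angles(right) else right))
  }
  acc <- matrix(0, n_phase, 3)
  n_acc <- 0L
  b <- cycles$boundaries
  for (s in sides) {
    fth <- stats::splinefun(s$t, s$theta, method = "fmm")
    fph <- stats::splinefun(s$t, s$phi, method = "fmm")
    fps <- stats::splinefun(s$t, s$psi, method = "fmm")
    for (k in seq_len(length(b) - 1)) {
      tk <- b[k] + grid * (b[k + 1] - b[k])
      if (tk[1] < min(s$t) - 1e-9 || tk[length(tk)] > max(s$t) + 1e-9) next
      acc <- acc + cbind(fth(tk), fph(tk), fps(tk))
      n_acc <- n_acc + 1L
    }
  }
  if (n_acc == 0L) stop("no complete cycles covered by the series", call. = FALSE)
  acc <- acc / n_acc
  out <- tibble::tibble(phase = grid, theta = acc[, 1], phi = acc[, 2],
                        psi = acc[, 3])
  attr(out, "T") <- cycles$T
  attr(out, "f") <- cycles$f
  attr(out, "n_cycles") <- cycles$n_cycles
  out
}
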