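#' Internal unit system
#'
#' All computations inside bristlewing use a micro-scale unit system in
#' which the numbers describing a sub-millimetre insect are of order one:
#' mass in micrograms (ug), length in micrometres (um) and time in
#' milliseconds (ms). Derived units follow directly:
#'
#' * velocity: um/ms (= 1e-3 m/s)
#' * acceleration: um/ms^2 (= 1 m/s^2, so g = 9.81 in internal units)
#' * force: ug um/ms^2 (= 1 nN)
#' * torque: ug um^2/ms^2 (= 1e-15 N m)
#' * power: ug um^2/ms^3 (= 1 pW)
#' * body-mass-specific power: um^2/ms^3 (= 1e-3 W/kg)
#' * density: ug/um^3 (1200 kg/m^3 = 1.2e-6 ug/um^3)
#' * kinematic viscosity: um^2/ms (1.54e-5 m^2/s = 1.54e4 um^2/ms)
#'
#' The helpers below convert between SI and internal units exactly; they
#' are pure scale factors.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
density_si_to_internal <- function(x) x * 1e-9 # kg/m^3 -> ug/um^3

#' @rdname units
#' @export
density_internal_to_si <- function(x) x * 1e9

#' @rdname units
#' @export
viscosity_si_to_internal <- function(x) x * 1e9 # m^2/s -> um^2/ms

#' @rdname units
#' @export
viscosity_internal_to_si <- function(x) x * 1e-9

#' @rdname units
#' @export
speed_internal_to_si <- function(x) x * 1e-3 # um/ms -> m/s

#' @rdname units
#' @export
speed_si_to_internal <- function(x) x * 1e3

#' @rdname units
#' @export
force_internal_to_si <- function(x) x * 1e-9 # ug um/ms^2 -> N

#' @rdname units
#' @export
force_si_to_internal <- function(x) x * 1e9

#' @rdname units
#' @export
torque_internal_to_si <- function(x) x * 1e-15 # ug um^2/ms^2 -> N m

#' @rdname units
#' @export
torque_si_to_internal <- function(x) x * 1e15

#' @rdname units
#' @export
specific_power_internal_to_si <- function(x) x * 1e-3 # um^2/ms^3 -> W/kg

#' @rdname units
#' @export
specific_power_si_to_internal <- function(x) x * 1e3

#' @rdname units
#' @export
frequency_internal_to_si <- function(x) x * 1e3 # 1/ms (kHz) -> Hz

#' @rdname units
#' @export
frequency_si_to_internal <- function(x) x * 1e-3

# gravitational acceleration, um/ms^2 (numerically equal to m/s^2)
.g_default <- 9.81

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
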