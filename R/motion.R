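#' Motion models for one-dimensional target trajectories
#'
#' Three parametric trajectories along the superior--inferior axis are
#' supported, all evaluable at arbitrary times via [displacement()]:
#'
#' * `motion_sinusoidal()`: `d(t) = A sin(2 pi f t + phi)`, the cyclic
#'   pattern used to emulate respiration. Frequency may be given in Hz or in
#'   cycles per minute (exactly one of the two).
#' * `motion_constant()`: `d(t) = VP t`, unidirectional constant speed.
#' * `motion_sampled()`: piecewise-linear interpolation of a measured
#'   `(time, displacement)` table; defined only on the sampled time support.
#'
#' @param amplitude_mm Motion amplitude `A`, mm (half the range of motion).
#' @param frequency_hz Frequency in Hz.
#' @param frequency_cpm Frequency in cycles per minute (converted to Hz).
#' @param phase_rad Phase offset `phi`, radians.
#' @param speed_mm_s Constant speed `VP`, mm/s (may be negative for inferior
#'   travel).
#' @param time_s,displacement_mm Sample times (strictly increasing, s) and
#'   displacements (mm) for a sampled trajectory.
#' @return An object of class `cbct_motion`.
#' @examples
#' displacement(motion_sinusoidal(20, frequency_hz = 0.25), 1)  # 20
#' displacement(motion_constant(0.5), 10)                       # 5
#' @export
motion_sinusoidal <- function(amplitude_mm, frequency_hz = NULL,
                              frequency_cpm = NULL, phase_rad = 0) {
  check_number(amplitude_mm, "amplitude_mm", lower = 0)
  if (is.null(frequency_hz) == is.null(frequency_cpm)) {
    config_error("give exactly one of `frequency_hz` or `frequency_cpm`")
  }
  if (is.null(frequency_hz)) {
    check_number(frequency_cpm, "frequency_cpm", lower = 0, strict = TRUE)
    frequency_hz <- frequency_cpm / 60
  } else {
    check_number(frequency_hz, "frequency_hz", lower = 0, strict = TRUE)
  }
  check_number(phase_rad, "phase_rad")
  structure(list(kind = "sinusoidal", amplitude_mm = amplitude_mm,
                 frequency_hz = frequency_hz, phase_rad = phase_rad),
            class = "cbct_motion")
}

#' @rdname motion_sinusoidal
#' @export
motion_constant <- function(speed_mm_s) {
  check_number(speed_mm_s, "speed_mm_s")
  structure(list(kind = "constant_speed", speed_mm_s = speed_mm_s),
            class = "cbct_motion")
}

#' @rdname motion_sinusoidal
#' @export
motion_sampled <- function(time_s, displacement_mm) {
  if (!is.numeric(time_s) || !is.numeric(displacement_mm) ||
      length(time_s) != length(displacement_mm) || length(time_s) < 2 ||
      any(!is.finite(time_s)) || any(!is.finite(displacement_mm))) {
    config_error("`time_s` and `displacement_mm` must be finite numerics of equal length >= 2")
  }
  if (any(diff(time_s) <= 0)) config_error("`time_s` must be strictly increasing")
  structure(list(kind = "sampled", time_s = time_s,
                 displacement_mm = displacement_mm),
            class = "cbct_motion")
}

#' @export
print.cbct_motion <- function(x, ...) {
  desc <- switch(x$kind,
    sinusoidal = sprintf("sinusoidal A=%g mm, f=%g Hz, phi=%g rad",
                         x$amplitude_mm, x$frequency_hz, x$phase_rad),
    constant_speed = sprintf("constant speed %g mm/s", x$speed_mm_s),
    sampled = sprintf("sampled trajectory on [%g, %g] s",
                      min(x$time_s), max(x$time_s)))
  cat("<cbct_motion> ", desc, "\n", sep = "")
  invisible(x)
}

#' Evaluate a trajectory
#'
#' @param motion A `cbct_motion`.
#' @param t_s Time(s), seconds; non-negative, and within the sampled support
#'   for sampled trajectories.
#' @return Displacement(s) in mm.
#' @export
displacement <- function(motion, t_s) {
  if (!inherits(motion, "cbct_motion")) config_error("`motion` must be a cbct_motion")
  if (!is.numeric(t_s) || any(!is.finite(t_s))) config_error("`t_s` must be finite numeric")
  if (any(t_s < 0)) range_error("`t_s` must be >= 0")
  switch(motion$kind,
    sinusoidal = motion$amplitude_mm *
      sin(2 * pi * motion$frequency_hz * t_s + motion$phase_rad),
    constant_speed = motion$speed_mm_s * t_s,
    sampled = {
      if (any(t_s < min(motion$time_s)) || any(t_s > max(motion$time_s))) {
        range_error(sprintf(
          "sampled trajectory queried outside its time support [%g, %g] s",
          min(motion$time_s), max(motion$time_s)))
      }
      stats::approx(motion$time_s, motion$displacement_mm, xout = t_s)$y
    })
}

#' Zero-motion model (stationary target)
#' @return A `cbct_motion` whose displacement is identically 0.
#' @export
motion_none <- function() motion_constant(0)

# Largest |d(t)| over [0, duration]; used for view checks in helpers.
max_excursion <- function(motion, duration_s) {
  switch(motion$kind,
    sinusoidal = motion$amplitude_mm,
    constant_speed = abs(motion$speed_mm_s) * duration_s,
    sampled = max(abs(motion$displacement_mm)))
}
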