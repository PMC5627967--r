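#' Quantize a signal to an ADC grid
#'
#' Mid-tread uniform quantizer over `±full_scale` with `2^bits - 1` steps,
#' followed by clipping to the full-scale range.
#'
#' @param x Numeric vector, standard gravities.
#' @param full_scale Range, ± standard gravities.
#' @param bits ADC resolution.
#' @return Quantized vector on the ADC grid.
#' @export
quantize_adc <- function(x, full_scale = 3, bits = 16) {
  step <- 2 * full_scale / (2^bits - 1)
  k_max <- floor((2^bits - 1) / 2)   # largest code of the mid-tread grid
  pmin(pmax(round(x / step), -k_max), k_max) * step
}

#' Virtual single-axis accelerometer reading
#'
#' Converts point kinematics to what a MEMS accelerometer strapped to that
#' point reports: the specific force (point acceleration minus the gravity
#' vector) projected onto the sensor axis that is horizontal when the rig
#' hangs at rest — the tangential axis of the carrying segment. Additive
#' Gaussian noise, quantization and clipping model the sensing chain. For a
#' point at radius `d` on the rigid pendulum this equals
#' `(d * thetaacc + g * sin(theta)) / g` before noise.
#'
#' @param point_acc N x 2 matrix (or length-2 vector) of point acceleration
#'   in the x-horizontal/y-up plane, m/s^2.
#' @param segment_angle Angle(s) of the carrying segment from the hanging
#'   vertical, radians.
#' @param sensor A [sensor_spec()].
#' @param gravity Gravitational acceleration, m/s^2.
#' @param noise If `TRUE`, add Gaussian noise of sd `sensor$noise_sd` (drawn
#'   from the current RNG stream).
#' @return Readings in standard gravities, quantized and clipped.
#' @examples
#' s <- sensor_spec("R1", 0.57, noise_sd = 0)
#' virtual_accelerometer(c(0, 0), 0, s)        # hanging at rest: 0
#' virtual_accelerometer(c(0, 0), pi / 2, s)   # held horizontal: 1 g
#' @export
virtual_accelerometer <- function(point_acc, segment_angle, sensor,
                                  gravity = 9.81, noise = TRUE) {
  if (is.null(dim(point_acc))) point_acc <- matrix(point_acc, ncol = 2)
  if (!all(is.finite(point_acc)) || !all(is.finite(segment_angle))) {
    stop("non-finite kinematics passed to virtual_accelerometer", call. = FALSE)
  }
  if (gravity <= 0) {
    # degenerate zero-g case: specific force projection per unit "g" is taken
    # with the standard gravity constant so units stay standard gravities
    gravity_unit <- 9.80665
    specific <- point_acc[, 1] * cos(segment_angle) +
      point_acc[, 2] * sin(segment_angle)
    raw <- specific / gravity_unit
  } else {
    # (a - g_vec) . e_t(phi) with g_vec = (0, -g): a_x cos + a_y sin + g sin
    raw <- (point_acc[, 1] * cos(segment_angle) +
              point_acc[, 2] * sin(segment_angle) +
              gravity * sin(segment_angle)) / gravity
  }
  if (noise && sensor$noise_sd > 0) {
    raw <- raw + stats::rnorm(length(raw), 0, sensor$noise_sd)
  }
  quantize_adc(raw, sensor$full_scale, sensor$adc_bits)
}
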