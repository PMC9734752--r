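#' Global configuration of the virtual player
#'
#' Bundles the constants of the two-oscillator virtual player: the coupling
#' gains, the radius-noise amplitude, the sample rate, the geometry of the
#' movement plane and the trial duration. The time step used everywhere is
#' `1 / sample_rate`.
#'
#' @param k_inter Inter-player coupling gain towards the human partner's
#'   hands, in rad/s^2. `0.0075` in the coupling condition, `0` in the
#'   no-coupling condition.
#' @param k_intra Coupling gain between the virtual player's own two hands,
#'   in rad/s^2 (default `0.005`).
#' @param noise_amplitude Half-range of the Perlin radius noise, in metres
#'   (default `0.085`).
#' @param sample_rate Simulation and recording rate in Hz (default `50`).
#' @param plane_offset Distance of the movement plane from the character
#'   origin along the facing axis, in metres (default `0.343`).
#' @param partner_distance Distance between the character and the participant
#'   along the facing axis, in metres (default `1.246`).
#' @param duration Trial duration in seconds (default `60`).
#'
#' @return An object of class `model_config` (a named list).
#' @examples
#' cfg <- model_config(k_inter = 0.0075)
#' cfg$dt # 0.02 s
#' @export
model_config <- function(k_inter = 0,
                         k_intra = 0.005,
                         noise_amplitude = 0.085,
                         sample_rate = 50,
                         plane_offset = 0.343,
                         partner_distance = 1.246,
                         duration = 60) {
  stopifnot(
    is.numeric(k_inter), length(k_inter) == 1L, is.finite(k_inter), k_inter >= 0,
    is.numeric(k_intra), length(k_intra) == 1L, is.finite(k_intra), k_intra >= 0,
    is.numeric(noise_amplitude), length(noise_amplitude) == 1L,
    is.finite(noise_amplitude), noise_amplitude >= 0,
    is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0,
    is.numeric(duration), length(duration) == 1L, duration > 0,
    is.numeric(plane_offset), length(plane_offset) == 1L, is.finite(plane_offset),
    is.numeric(partner_distance), length(partner_distance) == 1L,
    is.finite(partner_distance)
  )
  structure(
    list(
      k_inter = k_inter,
      k_intra = k_intra,
      noise_amplitude = noise_amplitude,
      sample_rate = sample_rate,
      plane_offset = plane_offset,
      partner_distance = partner_distance,
      duration = duration,
      dt = 1 / sample_rate
    ),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  k_inter  = %g rad/s^2, k_intra = %g rad/s^2\n",
              x$k_inter, x$k_intra))
  cat(sprintf("  noise    = +/-%g m, sample_rate = %g Hz (dt = %g s)\n",
              x$noise_amplitude, x$sample_rate, x$dt))
  cat(sprintf("  geometry: plane at %g m, partner at %g m\n",
              x$plane_offset, x$partner_distance))
  cat(sprintf("  duration = %g s (%d samples)\n",
              x$duration, n_samples(x)))
  invisible(x)
}

#' Number of samples on the trial grid, including t = 0
#' @param config A [model_config()].
#' @return Integer sample count `duration * sample_rate + 1`.
#' @export
n_samples <- function(config) {
  as.integer(round(config$duration * config$sample_rate)) + 1L
}

#' Kinematic parameters of one hand
#'
#' Centre, baseline radius and baseline angular velocity of the circular
#' motion of one hand, typically estimated from a training trajectory with
#' [estimate_params()].
#'
#' @param center Numeric 3-vector, circle centre in metres (x = facing axis,
#'   y = vertical, z = lateral).
#' @param radius0 Baseline radius in metres; must be positive.
#' @param omega0 Baseline angular velocity in rad/s; must be finite.
#' @param side `"right"` or `"left"`. The left hand counter-rotates in z
#'   (its position uses `-cos(theta)` on the lateral axis).
#'
#' @return An object of class `hand_params`.
#' @examples
#' hand_params(c(0.343, 1.2, 0.25), radius0 = 0.163, omega0 = 2.695, side = "right")
#' @export
hand_params <- function(center, radius0, omega0, side = c("right", "left")) {
  side <- match.arg(side)
  center <- as.numeric(center)
  stopifnot(
    length(center) == 3L, all(is.finite(center)),
    is.numeric(radius0), length(radius0) == 1L, is.finite(radius0), radius0 > 0,
    is.numeric(omega0), length(omega0) == 1L, is.finite(omega0)
  )
  structure(
    list(center = center, radius0 = radius0, omega0 = omega0, side = side),
    class = "hand_params"
  )
}

#' @export
print.hand_params <- function(x, ...) {
  cat(sprintf("<hand_params %s> center = (%.3f, %.3f, %.3f) m, r0 = %.3f m, omega0 = %.3f rad/s\n",
              x$side, x$center[1], x$center[2], x$center[3], x$radius0, x$omega0))
  invisible(x)
}

#' Default hand parameters at the magnitudes of the study population
#'
#' Convenience constructor returning right/left [hand_params()] at the mean
#' training-trial estimates (radius about 0.16 m, angular velocity about
#' 2.7 rad/s), hands centred 0.5 m apart on the movement plane.
#'
#' @param config A [model_config()] supplying the plane offset.
#' @return List with elements `right` and `left`.
#' @export
default_hands <- function(config = model_config()) {
  list(
    right = hand_params(center = c(config$plane_offset, 1.20, 0.25),
                        radius0 = 0.163, omega0 = 2.695, side = "right"),
    left = hand_params(center = c(config$plane_offset, 1.20, -0.25),
                       radius0 = 0.161, omega0 = 2.698, side = "left")
  )
}
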