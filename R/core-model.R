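#' Evolving state of the virtual player's two oscillators
#'
#' Phases are kept wrapped to (-pi, pi]; time is carried as an integer step
#' index `k` so that `t = k / sample_rate` is computed identically whether a
#' trajectory is produced step by step or in one vectorised run.
#'
#' @param omega_right,omega_left Angular velocities in rad/s.
#' @param theta_right,theta_left Phases in rad (wrapped on construction).
#' @param k Integer step index (`t = k / sample_rate`).
#' @param noise_seed Integer seed of the trial's radius-noise streams.
#' @param sample_rate Hz, used to derive `t` from `k`.
#'
#' @return An object of class `oscillator_state`.
#' @export
oscillator_state <- function(omega_right, omega_left,
                             theta_right = 0, theta_left = 0,
                             k = 0L, noise_seed = 0L, sample_rate = 50) {
  stopifnot(is.finite(omega_right), is.finite(omega_left),
            is.finite(theta_right), is.finite(theta_left),
            k >= 0, sample_rate > 0)
  structure(
    list(theta_right = wrap_phase(theta_right),
         theta_left = wrap_phase(theta_left),
         omega_right = omega_right, omega_left = omega_left,
         k = as.integer(k), t = as.integer(k) / sample_rate,
         sample_rate = sample_rate,
         noise_seed = as.integer(noise_seed)),
    class = "oscillator_state"
  )
}

#' Instantaneous circle radius of one hand
#'
#' Baseline radius plus the hand's Perlin noise stream. The right and left
#' hands draw from independent streams derived from `(seed, side)`.
#'
#' @param hand A [hand_params()].
#' @param t Time in seconds (vectorised), `t >= 0`.
#' @param config A [model_config()] supplying the noise amplitude.
#' @param seed Integer trial seed.
#' @return Radius in metres, within `radius0 +/- noise_amplitude`.
#' @export
radius_at <- function(hand, t, config, seed) {
  stopifnot(all(t >= 0))
  hand$radius0 + perlin_noise(t, noise_stream_seed(seed, hand$side),
                              config$noise_amplitude)
}

# stream 1 = right hand, stream 2 = left hand
noise_stream_seed <- function(seed, side) {
  derive_seed(seed, if (identical(side, "right")) 1 else 2)
}

#' Hand position on the movement circle
#'
#' Circular kinematics in the movement (y-z) plane: the right hand traces
#' `center + r cos(theta) z + r sin(theta) y`, the left hand counter-rotates
#' laterally, `center - r cos(theta) z + r sin(theta) y`. The component
#' along the plane normal (x) always equals the centre's.
#'
#' @param hand A [hand_params()] (only `center` and `side` are used).
#' @param theta Phase in rad (vectorised).
#' @param radius Radius in metres, positive (vectorised or scalar).
#' @return For scalar input a length-3 vector; otherwise an `n x 3` matrix.
#' @export
position_of <- function(hand, theta, radius) {
  stopifnot(all(radius > 0))
  zsign <- if (hand$side == "right") 1 else -1
  x <- rep(hand$center[1], length(theta))
  y <- hand$center[2] + radius * sin(theta)
  z <- hand$center[3] + zsign * radius * cos(theta)
  if (length(theta) == 1L) c(x, y, z) else cbind(x = x, y = y, z = z)
}

#' Angular acceleration of the two virtual hands
#'
#' The coupling law of the virtual player: each virtual hand is attracted to
#' the phase of the human's *opposite* hand (mirror pairing: human left drives
#' virtual right and vice versa) with gain `k_inter`, and to the virtual
#' player's own other hand with gain `k_intra`:
#' \deqn{\dot\omega_R = K_{inter}\sin(\theta_L^H - \theta_R^V) +
#'       K_{intra}\sin(\theta_L^V - \theta_R^V)}
#' \deqn{\dot\omega_L = K_{inter}\sin(\theta_R^H - \theta_L^V) +
#'       K_{intra}\sin(\theta_R^V - \theta_L^V)}
#'
#' @param state An [oscillator_state()].
#' @param human_theta_right,human_theta_left Human hand phases in rad. Ignored
#'   (any sentinel, e.g. `NA`, is accepted) when `k_inter = 0`.
#' @param config A [model_config()] supplying the gains.
#' @return Named numeric vector `c(right = , left = )` in rad/s^2.
#' @export
angular_accel <- function(state, human_theta_right, human_theta_left, config) {
  if (config$k_inter > 0 &&
      (!is.finite(human_theta_right) || !is.finite(human_theta_left)))
    stop("non-finite human phases with k_inter > 0", call. = FALSE)
  inter_r <- if (config$k_inter > 0)
    config$k_inter * sin(wrap_phase(human_theta_left - state$theta_right)) else 0
  inter_l <- if (config$k_inter > 0)
    config$k_inter * sin(wrap_phase(human_theta_right - state$theta_left)) else 0
  intra_r <- config$k_intra * sin(wrap_phase(state$theta_left - state$theta_right))
  intra_l <- config$k_intra * sin(wrap_phase(state$theta_right - state$theta_left))
  c(right = inter_r + intra_r, left = inter_l + intra_l)
}

#' Advance the virtual player by one sample
#'
#' Explicit Euler update at `dt = 1 / sample_rate`: the acceleration is
#' evaluated on the current (previous-tick) phases, the angular velocity is
#' updated first and the phase then advances with the *new* velocity
#' (`omega(t_k) = omega(t_{k-1}) + acc dt`;
#' `theta(t_k) = theta(t_{k-1}) + omega(t_k) dt`, wrapped). Positions are
#' emitted at the new time via [radius_at()] and [position_of()].
#'
#' @inheritParams angular_accel
#' @param hands List with [hand_params()] elements `right` and `left`.
#' @return List with the advanced `state` and the new `right_pos` and
#'   `left_pos` (3-vectors, metres).
#' @export
step_oscillator <- function(state, human_theta_right, human_theta_left,
                            hands, config) {
  acc <- angular_accel(state, human_theta_right, human_theta_left, config)
  omega_r <- state$omega_right + acc[["right"]] * config$dt
  omega_l <- state$omega_left + acc[["left"]] * config$dt
  theta_r <- wrap_phase(state$theta_right + omega_r * config$dt)
  theta_l <- wrap_phase(state$theta_left + omega_l * config$dt)
  k_new <- state$k + 1L
  t_new <- k_new / config$sample_rate
  new_state <- oscillator_state(
    omega_right = omega_r, omega_left = omega_l,
    theta_right = theta_r, theta_left = theta_l,
    k = k_new, noise_seed = state$noise_seed,
    sample_rate = config$sample_rate
  )
  list(
    state = new_state,
    right_pos = position_of(hands$right, theta_r,
                            radius_at(hands$right, t_new, config, state$noise_seed)),
    left_pos = position_of(hands$left, theta_l,
                           radius_at(hands$left, t_new, config, state$noise_seed))
  )
}

#' Simulate the virtual player over a full trial
#'
#' Integrates both oscillators over `duration` seconds at `sample_rate`,
#' producing `duration * sample_rate + 1` samples per hand (the initial state
#' is emitted at t = 0). When `k_inter > 0` a `phase_source` must supply the
#' human phases; it is called with the *previous* tick's time (one-tick
#' delay, as in a networked real-time loop) and must return
#' `c(theta_right_human, theta_left_human)` in rad. With `k_inter = 0` the
#' phase source is ignored entirely and the output depends only on the hand
#' parameters, config and seed.
#'
#' @param hands List with [hand_params()] elements `right` and `left`;
#'   initial angular velocities are taken from their `omega0`.
#' @param config A [model_config()].
#' @param phase_source `NULL`, or `function(t)` returning the two human
#'   phases at time `t`.
#' @param seed Integer seed for the radius-noise streams.
#' @param theta0 Initial phases `c(right, left)` in rad.
#'
#' @return An object of class `virtual_simulation`: a list with
#'   [hand_trajectory()] elements `right` and `left`, the internal phase and
#'   angular-velocity series (`phases`, `omegas`, each with `right`/`left`
#'   numeric vectors), the time grid `times`, and the `config` and `seed`
#'   used.
#' @examples
#' cfg <- model_config(k_inter = 0, noise_amplitude = 0, duration = 5)
#' sim <- simulate_virtual(default_hands(cfg), cfg, seed = 1)
#' length(sim$right$times) # 5 * 50 + 1
#' @export
simulate_virtual <- function(hands, config, phase_source = NULL, seed = 0L,
                             theta0 = c(0, 0)) {
  if (config$k_inter > 0 && is.null(phase_source))
    stop("k_inter > 0 requires a human phase source", call. = FALSE)
  n <- n_samples(config)
  times <- (0:(n - 1L)) / config$sample_rate
  th_r <- om_r <- th_l <- om_l <- numeric(n)
  th_r[1] <- wrap_phase(theta0[1]); th_l[1] <- wrap_phase(theta0[2])
  om_r[1] <- hands$right$omega0; om_l[1] <- hands$left$omega0
  coupled <- config$k_inter > 0
  k_inter <- config$k_inter; k_intra <- config$k_intra; dt <- config$dt
  for (k in 2:n) {
    # phases and human input from tick k-1 drive the update to tick k
    if (coupled) {
      h <- phase_source(times[k - 1L])
      if (!all(is.finite(h)))
        stop("non-finite human phases with k_inter > 0", call. = FALSE)
      acc_r <- k_inter * sin(wrap_phase(h[2] - th_r[k - 1L])) +
        k_intra * sin(wrap_phase(th_l[k - 1L] - th_r[k - 1L]))
      acc_l <- k_inter * sin(wrap_phase(h[1] - th_l[k - 1L])) +
        k_intra * sin(wrap_phase(th_r[k - 1L] - th_l[k - 1L]))
    } else {
      acc_r <- k_intra * sin(wrap_phase(th_l[k - 1L] - th_r[k - 1L]))
      acc_l <- k_intra * sin(wrap_phase(th_r[k - 1L] - th_l[k - 1L]))
    }
    om_r[k] <- om_r[k - 1L] + acc_r * dt
    om_l[k] <- om_l[k - 1L] + acc_l * dt
    th_r[k] <- wrap_phase(th_r[k - 1L] + om_r[k] * dt)
    th_l[k] <- wrap_phase(th_l[k - 1L] + om_l[k] * dt)
  }
  r_r <- radius_at(hands$right, times, config, seed)
  r_l <- radius_at(hands$left, times, config, seed)
  structure(
    list(
      right = hand_trajectory("right", times, position_of(hands$right, th_r, r_r)),
      left = hand_trajectory("left", times, position_of(hands$left, th_l, r_l)),
      phases = list(right = th_r, left = th_l),
      omegas = list(right = om_r, left = om_l),
      times = times, config = config, seed = as.integer(seed)
    ),
    class = "virtual_simulation"
  )
}

#' @export
print.virtual_simulation <- function(x, ...) {
  cat(sprintf("<virtual_simulation> %d samples, k_inter = %g, k_intra = %g, seed = %d\n",
              length(x$times), x$config$k_inter, x$config$k_intra, x$seed))
  invisible(x)
}

#' Estimate hand parameters from training trajectories
#'
#' Recovers the circle centre, baseline radius and baseline angular velocity
#' of each hand from a recorded training trial, the quantities the virtual
#' player is parameterised with: the centre is the time-average position, the
#' radius the time-average distance from that centre, and the angular
#' velocity the (positive) time-average derivative of the unwrapped extracted
#' phase.
#'
#' @param training_right,training_left [hand_trajectory()] objects with at
#'   least 2 s of data.
#' @param r_min Degeneracy guard in metres: estimation fails if the mean
#'   radial spread is below this (default 0.03 m).
#' @return List with [hand_params()] elements `right` and `left`.
#' @examples
#' cfg <- model_config(noise_amplitude = 0, duration = 10)
#' sim <- simulate_virtual(default_hands(cfg), cfg, seed = 1)
#' estimate_params(sim$right, sim$left)
#' @export
estimate_params <- function(training_right, training_left, r_min = 0.03) {
  list(right = estimate_one_hand(training_right, r_min),
       left = estimate_one_hand(training_left, r_min))
}

estimate_one_hand <- function(traj, r_min) {
  stopifnot(inherits(traj, "hand_trajectory"))
  n <- length(traj$times)
  if (traj$times[n] - traj$times[1] < 2)
    stop("estimation requires at least 2 s of data", call. = FALSE)
  center <- colMeans(traj$positions)
  rel <- sweep(traj$positions, 2, center)
  d <- sqrt(rowSums(rel^2))
  if (mean(d) < r_min)
    stop(sprintf("estimation failure: near-stationary trajectory (mean radial spread %.4f m < %.3f m)",
                 mean(d), r_min), call. = FALSE)
  zsign <- if (traj$side == "right") 1 else -1
  theta <- atan2(rel[, 2], zsign * rel[, 3])
  uw <- unwrap_phase(theta)
  dt <- mean(diff(traj$times))
  omega0 <- abs(mean(diff(uw)) / dt)
  hand_params(center = center, radius0 = mean(d), omega0 = omega0,
              side = traj$side)
}
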