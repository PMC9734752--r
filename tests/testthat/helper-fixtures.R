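# shared fixture builders (everything generated in code; nothing on disk)

# noiseless circle trajectory with known centre / radius / angular velocity
make_circle <- function(side = "right", center = c(0.343, 1.2, 0.25),
                        radius = 0.163, omega = 2.695, duration = 10,
                        sample_rate = 50, phase0 = 0) {
  times <- seq(0, duration, by = 1 / sample_rate)
  hp <- hand_params(center, radius, omega, side)
  theta <- phase0 + omega * times
  hand_trajectory(side, times, position_of(hp, theta, radius))
}

# open-loop virtual run against a constant-angular-velocity driver; returns
# the unwrapped relative phase (driver - virtual right hand)
drive_virtual <- function(detuning, k_inter = 0.0075, duration = 600,
                          seed = 1) {
  cfg <- model_config(k_inter = k_inter, k_intra = 0, noise_amplitude = 0,
                      duration = duration)
  hands <- default_hands(cfg)
  omega_h <- hands$right$omega0 + detuning
  src <- function(t) c(omega_h * t, omega_h * t)
  sim <- simulate_virtual(hands, cfg, phase_source = src, seed = seed)
  unwrap_phase(wrap_phase(omega_h * sim$times - sim$phases$right))
}

# lock classification used on both the package route and the ode oracle:
# bounded relative phase (range < 2*pi) after discarding the first third
is_locked_series <- function(rel, times) {
  post <- times > max(times) / 3
  diff(range(rel[post])) < 2 * pi
}

# bisect a lock/drift boundary on [lo, hi] given a predicate locked(x)
bisect_threshold <- function(locked, lo, hi, iters = 10) {
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (locked(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# zero-effect questionnaire effect matrix
zero_effects <- function() {
  matrix(0, 10, 3, dimnames = list(NULL, c("human", "no_coupling",
                                           "coupling")))
}
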