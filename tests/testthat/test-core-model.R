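test_that("radius is the baseline plus bounded per-side noise", {
  cfg0 <- model_config(noise_amplitude = 0)
  h <- hand_params(c(0.343, 1.2, 0.25), 0.163, 2.695, "right")
  tg <- seq(0, 60, by = 0.02)
  expect_equal(radius_at(h, tg, cfg0, seed = 9), rep(0.163, length(tg)))

  cfg <- model_config() # default amplitude 0.085
  hl <- hand_params(c(0.343, 1.2, -0.25), 0.161, 2.698, "left")
  r <- radius_at(hl, tg, cfg, seed = 4)
  expect_true(all(r >= 0.161 - 0.085 & r <= 0.161 + 0.085))

  # distinct seeds: different series, same bounds
  r2 <- radius_at(hl, tg, cfg, seed = 5)
  expect_gt(max(abs(r - r2)), 0.01)
  expect_true(all(abs(r2 - 0.161) <= 0.085))

  # the two sides of one trial use independent noise streams
  hr <- hand_params(c(0.343, 1.2, 0.25), 0.161, 2.695, "right")
  expect_gt(max(abs(radius_at(hr, tg, cfg, seed = 4) - r)), 0.01)
})

test_that("positions sit on the circle with the left hand counter-rotating", {
  hr <- hand_params(c(0.3, 1.0, 0.2), 0.15, 2.7, "right")
  hl <- hand_params(c(0.3, 1.0, -0.2), 0.15, 2.7, "left")
  expect_equal(position_of(hr, 0, 0.15), c(0.3, 1.0, 0.2 + 0.15))
  expect_equal(position_of(hl, 0, 0.15), c(0.3, 1.0, -0.2 - 0.15))
  # pi/2 puts both hands straight up
  expect_equal(position_of(hr, pi / 2, 0.15), c(0.3, 1.15, 0.2))
  expect_equal(position_of(hl, pi / 2, 0.15), c(0.3, 1.15, -0.2))
  # on-circle identity and plane-normal component for arbitrary phases
  theta <- seq(-pi, pi, length.out = 1001)
  for (h in list(hr, hl)) {
    p <- position_of(h, theta, 0.15)
    expect_equal(sqrt(rowSums(sweep(p, 2, h$center)^2)),
                 rep(0.15, length(theta)), tolerance = 1e-12)
    expect_equal(p[, 1], rep(h$center[1], length(theta)))
  }
})

test_that("coupling law: gains, mirror pairing and vanishing configurations", {
  st <- oscillator_state(2.695, 2.698, theta_right = 0.4, theta_left = -0.2)
  cfg00 <- model_config(k_inter = 0, k_intra = 0)
  expect_equal(angular_accel(st, 1.0, 2.0, cfg00),
               c(right = 0, left = 0))
  # aligned phases: all sines vanish
  st2 <- oscillator_state(2.7, 2.7, theta_right = 0.5, theta_left = 0.5)
  cfg <- model_config(k_inter = 0.0075, k_intra = 0.005)
  expect_equal(angular_accel(st2, 0.5, 0.5, cfg), c(right = 0, left = 0))
  # quarter-turn lead of the human left hand drives the virtual right at
  # exactly the inter gain
  st3 <- oscillator_state(2.7, 2.7, theta_right = 0, theta_left = 0)
  cfgi <- model_config(k_inter = 0.0075, k_intra = 0)
  expect_equal(angular_accel(st3, 0, pi / 2, cfgi)[["right"]], 0.0075)
  # the human right hand drives the virtual LEFT hand (crossed pairing)
  expect_equal(angular_accel(st3, pi / 2, 0, cfgi)[["left"]], 0.0075)
  expect_equal(angular_accel(st3, pi / 2, 0, cfgi)[["right"]], 0)
  # non-finite human phases rejected only when the coupling is active
  expect_error(angular_accel(st3, NaN, 0, cfgi), "non-finite")
  expect_silent(angular_accel(st3, NaN, NaN, cfg00))
})

test_that("one Euler step applies acceleration then advances the phase", {
  cfg <- model_config(k_inter = 0.0075, k_intra = 0, noise_amplitude = 0)
  hands <- default_hands(cfg)
  st <- oscillator_state(2.695, 2.698, noise_seed = 1,
                         sample_rate = cfg$sample_rate)
  # human left a quarter turn ahead: acceleration exactly k_inter
  out <- step_oscillator(st, 0, pi / 2, hands, cfg)
  expect_equal(out$state$omega_right, 2.695 + 0.0075 * 0.02)
  expect_equal(out$state$theta_right,
               wrap_phase((2.695 + 0.0075 * 0.02) * 0.02))
  expect_equal(out$state$t, 0.02)
  expect_equal(out$state$k, 1L)
  # emitted positions respect the on-circle identity
  expect_equal(sqrt(sum((out$right_pos - hands$right$center)^2)),
               hands$right$radius0, tolerance = 1e-12)
})

test_that("uncoupled noiseless run conserves frequency and closes its circle", {
  cfg <- model_config(k_inter = 0, k_intra = 0, noise_amplitude = 0,
                      duration = 60)
  hands <- default_hands(cfg)
  sim <- simulate_virtual(hands, cfg, seed = 2)
  expect_length(sim$right$times, 3001L)
  expect_identical(sim$omegas$right, rep(2.695, 3001))
  expect_identical(sim$omegas$left, rep(2.698, 3001))
  # period 2*pi/2.695 = 2.3314 s: phase advances by exactly omega * t
  period <- 2 * pi / 2.695
  expect_equal(wrap_phase(sim$phases$right - 2.695 * sim$times),
               rep(0, 3001), tolerance = 1e-9)
  # positions nearly repeat one period apart
  i <- which.min(abs(sim$times - period))
  expect_lt(sqrt(sum((sim$right$positions[i, ] - sim$right$positions[1, ])^2)),
            2.695 * 0.163 * 0.02) # at most one sample step of arc
})

test_that("a full coupled run equals iterated single steps bit for bit", {
  cfg <- model_config(k_inter = 0.0075, k_intra = 0.005, duration = 5)
  hands <- default_hands(cfg)
  src <- function(t) c(2.8 * t, 2.8 * t + 0.3)
  sim <- simulate_virtual(hands, cfg, phase_source = src, seed = 17)

  st <- oscillator_state(hands$right$omega0, hands$left$omega0,
                         noise_seed = 17, sample_rate = cfg$sample_rate)
  n <- length(sim$times)
  for (k in 2:n) {
    h <- src(sim$times[k - 1L])
    out <- step_oscillator(st, h[1], h[2], hands, cfg)
    st <- out$state
    expect_identical(st$theta_right, sim$phases$right[k])
    expect_identical(st$omega_right, sim$omegas$right[k])
    expect_identical(as.numeric(out$right_pos),
                     as.numeric(sim$right$positions[k, ]))
    expect_identical(as.numeric(out$left_pos),
                     as.numeric(sim$left$positions[k, ]))
  }
})

test_that("k_inter = 0 output is invariant to the human input", {
  cfg <- model_config(k_inter = 0, duration = 10)
  hands <- default_hands(cfg)
  a <- simulate_virtual(hands, cfg, phase_source = function(t) c(0, 0),
                        seed = 3)
  b <- simulate_virtual(hands, cfg,
                        phase_source = function(t) c(100 * sin(t), -50 * t),
                        seed = 3)
  expect_identical(a$right$positions, b$right$positions)
  expect_identical(a$left$positions, b$left$positions)
  # and a phase source is mandatory once coupling is on
  cfg2 <- model_config(k_inter = 0.0075)
  expect_error(simulate_virtual(hands, cfg2, seed = 3), "phase source")
})

test_that("repeated simulation under one seed is bit-identical", {
  cfg <- model_config(k_inter = 0.0075, duration = 8)
  hands <- default_hands(cfg)
  src <- function(t) c(2.7 * t, 2.7 * t)
  s1 <- simulate_virtual(hands, cfg, src, seed = 21)
  s2 <- simulate_virtual(hands, cfg, src, seed = 21)
  expect_identical(s1$right$positions, s2$right$positions)
  expect_identical(s1$left$positions, s2$left$positions)
})

test_that("identical parameters give mirror-image hands through z = c_z", {
  cfg <- model_config(noise_amplitude = 0, k_inter = 0, k_intra = 0.005,
                      duration = 10)
  c0 <- c(0.343, 1.2, 0)
  hands <- list(right = hand_params(c0, 0.16, 2.7, "right"),
                left = hand_params(c0, 0.16, 2.7, "left"))
  sim <- simulate_virtual(hands, cfg, seed = 6)
  expect_equal(sim$left$positions[, "y"], sim$right$positions[, "y"])
  expect_equal(sim$left$positions[, "z"] - c0[3],
               -(sim$right$positions[, "z"] - c0[3]))
})

test_that("parameter estimation is exact on noiseless circles", {
  # whole cycles sampled without endpoint duplication: period 2 s at 50 Hz
  times <- (0:499) / 50
  omega <- pi # 2 s period
  for (side in c("right", "left")) {
    center <- c(0.343, 1.2, ifelse(side == "right", 0.25, -0.25))
    hp <- hand_params(center, 0.163, omega, side)
    traj <- hand_trajectory(side, times, position_of(hp, omega * times, 0.163))
    est <- estimate_params(traj, traj)[[side]]
    expect_equal(est$center, center, tolerance = 1e-9)
    expect_equal(est$radius0, 0.163, tolerance = 1e-9)
    expect_equal(est$omega0, omega, tolerance = 1e-9)
  }
})

test_that("estimation tolerates measurement noise and flags degeneracy", {
  # 5 mm Gaussian position noise, 60 s: radius within 2 mm, omega within
  # 0.02 rad/s (20 seeded replicates here; the wider sweep runs in the
  # acceptance suite)
  for (rep in 1:20) {
    traj <- make_circle(duration = 60)
    set.seed(rep)
    traj$positions <- traj$positions +
      matrix(rnorm(length(traj$positions), sd = 0.005),
             ncol = 3)
    est <- estimate_params(traj, traj)$right
    expect_lt(abs(est$radius0 - 0.163), 0.002)
    expect_lt(abs(est$omega0 - 2.695), 0.02)
  }
  # near-stationary trajectory errors out
  times <- (0:199) / 50
  still <- hand_trajectory("right", times,
                           cbind(0.343, 1.2 + 0.001 * sin(times),
                                 0.25 + 0.001 * cos(times)))
  expect_error(estimate_params(still, still), "near-stationary")
})

test_that("estimates from a realistic simulated partner match the population magnitudes", {
  cfg <- model_config()
  hum <- simulate_human(human_profile("drifting", seed = 8), cfg)
  est <- estimate_params(hum$right, hum$left)
  for (s in c("right", "left")) {
    expect_gt(est[[s]]$radius0, 0.08); expect_lt(est[[s]]$radius0, 0.25)
    expect_gt(est[[s]]$omega0, 1.5); expect_lt(est[[s]]$omega0, 4.0)
  }
})
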