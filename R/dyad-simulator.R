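#' Synthetic human partner profile
#'
#' Parameterises the synthetic humans used to close the loop around the
#' virtual player. The profile is package scaffolding: the underlying study
#' recorded real participants, so every structural choice here (kinds,
#' drift model, noise) is a modelling convention, with magnitudes chosen to
#' match the training-trial population estimates (radius about 0.16 m,
#' angular velocity about 2.7 rad/s).
#'
#' Three kinds are supported:
#' * `constant` — fixed angular velocity `base_omega`;
#' * `drifting` — angular velocity follows an Ornstein-Uhlenbeck process
#'   around `base_omega` with stationary sd `drift_sd` and time constant
#'   `drift_tau`;
#' * `coupled` — a second-order phase-coupled follower: each hand's angular
#'   velocity accelerates by `k_human * sin(theta_virtual_opposite - theta)`
#'   (mirror pairing), optionally on top of the drift process.
#'
#' @param kind `"constant"`, `"drifting"` or `"coupled"`.
#' @param base_omega Baseline angular velocity, rad/s (> 0).
#' @param base_radius Circle radius, metres (> 0).
#' @param center_right,center_left Circle centres, metres.
#' @param drift_sd Stationary sd of the angular-velocity drift, rad/s.
#' @param drift_tau Drift time constant, seconds.
#' @param position_noise_sd Isotropic Gaussian jitter added to emitted
#'   positions (tracking noise), metres.
#' @param k_human Coupling gain of the synthetic human towards the virtual
#'   player, rad/s^2 (used by the `coupled` kind).
#' @param seed Integer seed for the profile's own randomness.
#'
#' @return An object of class `human_profile`.
#' @export
human_profile <- function(kind = c("constant", "drifting", "coupled"),
                          base_omega = 2.7,
                          base_radius = 0.16,
                          center_right = c(0.903, 1.20, 0.25),
                          center_left = c(0.903, 1.20, -0.25),
                          drift_sd = 0.15,
                          drift_tau = 5,
                          position_noise_sd = 0.005,
                          k_human = 0.15,
                          seed = 0L) {
  kind <- match.arg(kind)
  stopifnot(base_omega > 0, base_radius > 0,
            drift_sd >= 0, drift_tau > 0, position_noise_sd >= 0,
            k_human >= 0)
  structure(
    list(kind = kind, base_omega = base_omega, base_radius = base_radius,
         center_right = as.numeric(center_right),
         center_left = as.numeric(center_left),
         drift_sd = drift_sd, drift_tau = drift_tau,
         position_noise_sd = position_noise_sd,
         k_human = k_human, seed = as.integer(seed)),
    class = "human_profile"
  )
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# per-tick Ornstein-Uhlenbeck innovations for the angular-velocity drift;
# the reversion (dt / tau) applies to the full velocity in the update loops,
# so the human always relaxes towards their preferred tempo
human_drift_noise <- function(profile, n, dt) {
  if (profile$kind == "constant" || profile$drift_sd == 0)
    return(numeric(n - 1L))
  eps <- with_seed(derive_seed(profile$seed, 21), stats::rnorm(n - 1L))
  profile$drift_sd * sqrt(2 * dt / profile$drift_tau) * eps
}

# shared assembly of the two hand trajectories from phase series
human_trajectories <- function(profile, times, th_r, th_l) {
  hr <- hand_params(profile$center_right, profile$base_radius,
                    profile$base_omega, "right")
  hl <- hand_params(profile$center_left, profile$base_radius,
                    profile$base_omega, "left")
  pos_r <- position_of(hr, th_r, profile$base_radius)
  pos_l <- position_of(hl, th_l, profile$base_radius)
  if (profile$position_noise_sd > 0) {
    n <- length(times)
    # drawn row-wise so a longer trial extends a shorter one sample-for-sample
    jit <- with_seed(derive_seed(profile$seed, 22),
                     matrix(stats::rnorm(2L * 3L * n, sd = profile$position_noise_sd),
                            ncol = 6L, byrow = TRUE))
    pos_r <- pos_r + jit[, 1:3]
    pos_l <- pos_l + jit[, 4:6]
  }
  list(right = hand_trajectory("right", times, pos_r),
       left = hand_trajectory("left", times, pos_l),
       phases = list(right = th_r, left = th_l))
}

#' Simulate a synthetic human partner
#'
#' Generates the two hand trajectories of one synthetic human over a trial.
#' The `coupled` kind requires a `virtual_phase_source`, a `function(t)`
#' returning the virtual player's `c(theta_right, theta_left)`; it is called
#' with the previous tick's time (one-tick delay). Output is deterministic
#' given the profile's seed.
#'
#' @param profile A [human_profile()].
#' @param config A [model_config()] (grid and duration).
#' @param virtual_phase_source `NULL`, or `function(t)` with the virtual
#'   player's phases (required for the `coupled` kind).
#' @return An object of class `human_simulation`: list with
#'   [hand_trajectory()] elements `right`/`left`, internal `phases` and
#'   `omegas` series, and `times`.
#' @export
simulate_human <- function(profile, config, virtual_phase_source = NULL) {
  n <- n_samples(config)
  times <- (0:(n - 1L)) / config$sample_rate
  dt <- config$dt
  noise <- human_drift_noise(profile, n, dt)
  a <- if (profile$kind == "constant") 0 else dt / profile$drift_tau
  if (profile$kind == "coupled") {
    if (is.null(virtual_phase_source))
      stop("coupled human kind requires a virtual phase source", call. = FALSE)
    th_r <- th_l <- om_r <- om_l <- numeric(n)
    om_r[1] <- om_l[1] <- profile$base_omega
    for (k in 2:n) {
      i <- k - 1L
      v <- virtual_phase_source(times[i])
      acc_r <- profile$k_human * sin(wrap_phase(v[2] - th_r[i]))
      acc_l <- profile$k_human * sin(wrap_phase(v[1] - th_l[i]))
      om_r[k] <- om_r[i] + (profile$base_omega - om_r[i]) * a +
        noise[i] + acc_r * dt
      om_l[k] <- om_l[i] + (profile$base_omega - om_l[i]) * a +
        noise[i] + acc_l * dt
      th_r[k] <- wrap_phase(th_r[i] + om_r[k] * dt)
      th_l[k] <- wrap_phase(th_l[i] + om_l[k] * dt)
    }
    out <- human_trajectories(profile, times, th_r, th_l)
    out$omegas <- list(right = om_r, left = om_l)
  } else {
    om <- numeric(n)
    om[1] <- profile$base_omega
    for (k in 2:n)
      om[k] <- om[k - 1L] + (profile$base_omega - om[k - 1L]) * a +
        noise[k - 1L]
    th <- wrap_phase(cumsum(c(0, om[-1] * dt)))
    out <- human_trajectories(profile, times, th, th)
    out$omegas <- list(right = om, left = om)
  }
  out$times <- times
  class(out) <- "human_simulation"
  out
}

#' Run one 60-second mirror-game trial
#'
#' Produces a complete trial record in one of the three experimental
#' conditions:
#' * `human` — the "virtual" character replays a second simulated human
#'   verbatim (pass-through; the oscillator model is not used);
#' * `no_coupling` — the virtual player runs open loop with `k_inter = 0`;
#' * `coupling` — human and virtual player are co-simulated in closed loop
#'   at the sample rate, each side seeing the other's phase from the
#'   previous tick (gain `k_inter`, default 0.0075 if the config carries 0).
#'
#' The button stream reports felt synchrony between the facing pair of hands
#' (human right vs virtual left) via [generate_button_stream()].
#'
#' @param condition `"human"`, `"no_coupling"` or `"coupling"`.
#' @param profile A [human_profile()] for the participant.
#' @param hands List of [hand_params()] (`right`, `left`) for the virtual
#'   player.
#' @param config A [model_config()].
#' @param seed Integer trial seed; all constituent seeds derive from it
#'   (virtual radius noise uses `seed` itself, so a `no_coupling` trial is
#'   bit-identical to `simulate_virtual()` with the same seed).
#' @param button_threshold,button_dwell Button model parameters, see
#'   [generate_button_stream()].
#' @return An object of class `trial_record`: condition, the four
#'   [hand_trajectory()]s (`human_right`, `human_left`, `virtual_right`,
#'   `virtual_left`), the logical `button` series, internal `phases`
#'   (`human`, `virtual` with `right`/`left` vectors), `times`, `seed`,
#'   `config` and `model_used`.
#' @export
run_trial <- function(condition = c("human", "no_coupling", "coupling"),
                      profile = human_profile("coupled"),
                      hands = default_hands(config),
                      config = model_config(),
                      seed = 0L,
                      button_threshold = pi / 4,
                      button_dwell = 0.5) {
  condition <- match.arg(condition)
  n <- n_samples(config)
  times <- (0:(n - 1L)) / config$sample_rate
  participant_profile <- profile
  participant_profile$seed <- derive_seed(seed, 10)

  if (condition == "human") {
    # the partner is a second, independently seeded human running open loop;
    # the participant may still track the partner (coupled kind)
    partner_profile <- profile
    partner_profile$seed <- derive_seed(seed, 11)
    if (partner_profile$kind == "coupled") partner_profile$kind <- "drifting"
    partner <- simulate_human(partner_profile, config)
    human <- simulate_human(participant_profile, config,
                            virtual_phase_source =
                              phase_lookup(partner$phases, config$sample_rate))
    virtual_right <- partner$right
    virtual_left <- partner$left
    virtual_phases <- partner$phases
    model_used <- FALSE
    cfg_used <- config
  } else if (condition == "no_coupling") {
    cfg_used <- config
    cfg_used$k_inter <- 0
    sim <- simulate_virtual(hands, cfg_used, phase_source = NULL, seed = seed)
    human <- simulate_human(participant_profile, config,
                            virtual_phase_source =
                              phase_lookup(sim$phases, config$sample_rate))
    virtual_right <- sim$right
    virtual_left <- sim$left
    virtual_phases <- sim$phases
    model_used <- TRUE
  } else {
    cfg_used <- config
    if (cfg_used$k_inter <= 0) cfg_used$k_inter <- 0.0075
    loop <- run_coupled_loop(participant_profile, hands, cfg_used, seed)
    human <- loop$human
    virtual_right <- loop$virtual_right
    virtual_left <- loop$virtual_left
    virtual_phases <- loop$virtual_phases
    model_used <- TRUE
  }

  rel <- wrap_phase(human$phases$right - virtual_phases$left)
  button <- generate_button_stream(rel, config$sample_rate,
                                   threshold = button_threshold,
                                   dwell = button_dwell)
  structure(
    list(condition = condition,
         human_right = human$right, human_left = human$left,
         virtual_right = virtual_right, virtual_left = virtual_left,
         button = button,
         phases = list(human = human$phases, virtual = virtual_phases),
         times = times, seed = as.integer(seed), config = cfg_used,
         model_used = model_used),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record %s> %d samples, seed = %d, model %s\n",
              x$condition, length(x$times), x$seed,
              if (x$model_used) sprintf("used (k_inter = %g)", x$config$k_inter)
              else "not used"))
  invisible(x)
}

# turn recorded phase series into a function(t) for one-tick-delayed lookup
phase_lookup <- function(phases, sample_rate) {
  function(t) {
    i <- as.integer(round(t * sample_rate)) + 1L
    c(phases$right[i], phases$left[i])
  }
}

# closed-loop co-simulation: virtual player and (possibly coupled) human step
# together; each consumes the other's phases from the previous tick only
run_coupled_loop <- function(profile, hands, config, seed) {
  n <- n_samples(config)
  times <- (0:(n - 1L)) / config$sample_rate
  dt <- config$dt
  k_inter <- config$k_inter
  k_intra <- config$k_intra
  coupled_human <- profile$kind == "coupled"
  noise <- human_drift_noise(profile, n, dt)
  a <- if (profile$kind == "constant") 0 else dt / profile$drift_tau

  th_vr <- th_vl <- om_vr <- om_vl <- numeric(n)
  th_hr <- th_hl <- om_hr <- om_hl <- numeric(n)
  om_vr[1] <- hands$right$omega0
  om_vl[1] <- hands$left$omega0
  om_hr[1] <- om_hl[1] <- profile$base_omega
  for (k in 2:n) {
    i <- k - 1L
    # virtual update from human phases at tick k-1 (mirror pairing)
    acc_vr <- k_inter * sin(wrap_phase(th_hl[i] - th_vr[i])) +
      k_intra * sin(wrap_phase(th_vl[i] - th_vr[i]))
    acc_vl <- k_inter * sin(wrap_phase(th_hr[i] - th_vl[i])) +
      k_intra * sin(wrap_phase(th_vr[i] - th_vl[i]))
    om_vr[k] <- om_vr[i] + acc_vr * dt
    om_vl[k] <- om_vl[i] + acc_vl * dt
    th_vr[k] <- wrap_phase(th_vr[i] + om_vr[k] * dt)
    th_vl[k] <- wrap_phase(th_vl[i] + om_vl[k] * dt)
    # human update from virtual phases at tick k-1
    eta <- if (length(noise)) noise[i] else 0
    acc_hr <- if (coupled_human)
      profile$k_human * sin(wrap_phase(th_vl[i] - th_hr[i])) else 0
    acc_hl <- if (coupled_human)
      profile$k_human * sin(wrap_phase(th_vr[i] - th_hl[i])) else 0
    om_hr[k] <- om_hr[i] + (profile$base_omega - om_hr[i]) * a +
      eta + acc_hr * dt
    om_hl[k] <- om_hl[i] + (profile$base_omega - om_hl[i]) * a +
      eta + acc_hl * dt
    th_hr[k] <- wrap_phase(th_hr[i] + om_hr[k] * dt)
    th_hl[k] <- wrap_phase(th_hl[i] + om_hl[k] * dt)
  }
  r_r <- radius_at(hands$right, times, config, seed)
  r_l <- radius_at(hands$left, times, config, seed)
  human <- human_trajectories(profile, times, th_hr, th_hl)
  human$omegas <- list(right = om_hr, left = om_hl)
  human$times <- times
  class(human) <- "human_simulation"
  list(
    human = human,
    virtual_right = hand_trajectory("right", times,
                                    position_of(hands$right, th_vr, r_r)),
    virtual_left = hand_trajectory("left", times,
                                   position_of(hands$left, th_vl, r_l)),
    virtual_phases = list(right = th_vr, left = th_vl)
  )
}

#' Synthetic button-press stream from relative phase
#'
#' Emulates a participant holding a controller button while feeling in
#' synchrony: the button is pressed at a sample iff the wrapped relative
#' phase has stayed within `threshold` continuously for the preceding
#' `dwell` seconds (inclusive of the current sample).
#'
#' @param relative_phase Numeric series of relative phase in rad.
#' @param sample_rate Hz.
#' @param threshold Absolute phase threshold in rad, in (0, pi] (default
#'   pi/4).
#' @param dwell Required dwell time in seconds, `>= 0` (default 0.5).
#' @return Logical vector, same length as `relative_phase`.
#' @export
generate_button_stream <- function(relative_phase, sample_rate,
                                   threshold = pi / 4, dwell = 0.5) {
  stopifnot(threshold > 0, threshold <= pi, dwell >= 0, sample_rate > 0)
  below <- abs(wrap_phase(relative_phase)) < threshold
  need <- as.integer(floor(dwell * sample_rate)) + 1L
  run <- integer(length(below))
  cur <- 0L
  for (i in seq_along(below)) {
    cur <- if (below[i]) cur + 1L else 0L
    run[i] <- cur
  }
  run >= need
}

#' Synthetic per-participant synchrony-report times
#'
#' Generates the amount of time (seconds within a 60-s trial) each
#' participant reports feeling in synchrony, per condition, with the
#' structural features of real button data: a strong idiosyncratic
#' per-participant bias (including a minority of near-constant pressers,
#' which makes the raw samples non-normal), plus a condition effect that
#' only becomes visible after removing the `human`-condition baseline.
#'
#' @param n_participants Number of participants (default 34).
#' @param effect_coupling,effect_no_coupling Mean shift of the `coupling`
#'   and `no_coupling` conditions relative to `human`, seconds (defaults
#'   `2.2` and `-3.1`, the magnitudes of the study's baseline-corrected
#'   samples).
#' @param bias_sd Sd of the per-participant baseline bias, seconds.
#' @param noise_sd Sd of the per-trial residual, seconds.
#' @param presser_prob Probability that a participant is a near-constant
#'   presser (default 0.2).
#' @param duration Trial duration in seconds (values are clipped to
#'   `[0, duration]`).
#' @param seed Integer seed.
#' @return Data frame with columns `participant`, `condition`,
#'   `time_pressed_s`.
#' @export
generate_sync_times <- function(n_participants = 34,
                                effect_coupling = 2.2,
                                effect_no_coupling = -3.1,
                                bias_sd = 12,
                                noise_sd = 12,
                                presser_prob = 0.2,
                                duration = 60,
                                seed = 0L) {
  stopifnot(n_participants >= 2, duration > 0, bias_sd >= 0, noise_sd >= 0,
            presser_prob >= 0, presser_prob <= 1)
  conds <- c("human", "no_coupling", "coupling")
  shift <- c(human = 0, no_coupling = effect_no_coupling,
             coupling = effect_coupling)
  with_seed(derive_seed(seed, 41), {
    presser <- stats::runif(n_participants) < presser_prob
    base <- ifelse(presser,
                   duration - abs(stats::rnorm(n_participants, sd = 2)),
                   pmin(duration, pmax(0,
                     stats::rnorm(n_participants, mean = duration / 3,
                                  sd = bias_sd))))
    grid <- expand.grid(participant = seq_len(n_participants),
                        condition = conds,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    raw <- base[grid$participant] + shift[grid$condition] +
      stats::rnorm(nrow(grid), sd = noise_sd)
    grid$time_pressed_s <- pmin(duration, pmax(0, raw))
  })
  grid[order(grid$participant), c("participant", "condition",
                                  "time_pressed_s")]
}

#' Synthetic questionnaire responses
#'
#' Generates a per-trial questionnaire table (10 graded items on a -3..+3
#' scale, one response per participant, condition and question) as
#' `round(clip(base + condition effect + participant intercept + noise))`,
#' for power and recovery testing of the statistical pipeline.
#'
#' @param n_participants Number of participants, `>= 2` (default 34, the
#'   analysed study sample).
#' @param effects Numeric `n_questions x n_conditions` matrix of mean shifts
#'   (columns `human`, `no_coupling`, `coupling`); default all zero.
#' @param sd Residual noise sd in scale units (default 1).
#' @param intercept_sd Sd of the per-participant random intercept (default
#'   0.5).
#' @param base Grand mean in scale units (default 0).
#' @param n_questions Number of graded items (default 10).
#' @param seed Integer seed.
#' @return Data frame with columns `participant`, `condition`, `question`,
#'   `response` (integers in `[-3, 3]`).
#' @export
generate_questionnaire <- function(n_participants = 34,
                                   effects = NULL,
                                   sd = 1,
                                   intercept_sd = 0.5,
                                   base = 0,
                                   n_questions = 10,
                                   seed = 0L) {
  stopifnot(n_participants >= 2, sd >= 0, intercept_sd >= 0, n_questions >= 1)
  conditions <- c("human", "no_coupling", "coupling")
  if (is.null(effects))
    effects <- matrix(0, n_questions, length(conditions),
                      dimnames = list(NULL, conditions))
  stopifnot(nrow(effects) == n_questions, ncol(effects) == length(conditions))
  if (is.null(colnames(effects))) colnames(effects) <- conditions
  grid <- expand.grid(question = seq_len(n_questions),
                      condition = conditions,
                      participant = seq_len(n_participants),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(derive_seed(seed, 31), {
    intercept <- stats::rnorm(n_participants, sd = intercept_sd)
    noise <- stats::rnorm(nrow(grid), sd = sd)
    raw <- base + effects[cbind(grid$question,
                                match(grid$condition, colnames(effects)))] +
      intercept[grid$participant] + noise
    grid$response <- as.integer(round(pmin(3, pmax(-3, raw))))
  })
  grid[, c("participant", "condition", "question", "response")]
}
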