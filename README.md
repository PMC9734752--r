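# mirrorplayer

Simulation and analysis toolkit for a **virtual mirror-game player**: a
virtual character whose two hands are driven by a pair of second-order
Kuramoto phase oscillators and that can imitate a human partner in real
time. The package is aimed at researchers in joint action and interpersonal
sensorimotor synchronisation who want to study such a character — its
locking behaviour, its responsiveness, and the statistics of the resulting
dyadic interaction — entirely in silico.

## The model

Each hand traces a circle in the frontal (y–z) plane,

```
p_R(t) = c_R + r_R(t) cos(θ_R) ẑ + r_R(t) sin(θ_R) ŷ
p_L(t) = c_L − r_L(t) cos(θ_L) ẑ + r_L(t) sin(θ_L) ŷ
```

with the radius jittered by smooth Perlin gradient noise,
`r(t) = r(0) + n(t)`, `n ∈ [−0.085, 0.085] m`. The phases follow an
inertial Kuramoto law with **crossed pairing** (each virtual hand tracks
the human's opposite hand, i.e. the hand it faces in the mirror):

```
ω̇_R = K_inter sin(θ_L^H − θ_R^V) + K_intra sin(θ_L^V − θ_R^V)
ω̇_L = K_inter sin(θ_R^H − θ_L^V) + K_intra sin(θ_R^V − θ_L^V)
```

integrated by explicit Euler at 50 Hz (`ω` first, then
`θ(t_k) = θ(t_{k−1}) + ω(t_k)Δt`). `K_intra = 0.005 rad/s²` binds the two
virtual hands; `K_inter` defines the experimental conditions: `human`
(model off — the character replays a partner verbatim), `no_coupling`
(`K_inter = 0`, open loop) and `coupling` (`K_inter = 0.0075`). Against a
constant-tempo partner the relative phase obeys a pendulum equation, so
phase lock onsets at the separatrix `|Δω| = 2√K_inter ≈ 0.173 rad/s` — a
law the test suite verifies against independent numerical integration.

On top of the core model the package provides:

* `simulate_human()` / `run_trial()` — synthetic partners (constant,
  tempo-drifting, or phase-coupled followers) and closed-loop 60-s trials
  in all three conditions, with a one-tick (20 ms) phase-exchange delay as
  in the original networked setup, plus synthetic felt-synchrony button
  streams, questionnaires and per-participant sync-time tables;
* `estimate_params()` — recovers each hand's centre, radius and angular
  velocity from a training trajectory;
* `extract_phase()`, `relative_phase()`, `order_parameter()`,
  `detect_lock()`, `sync_time()` — synchrony analytics;
* `analyze_questionnaire()`, `analyze_sync_times()`, `compare_paired()`,
  `cliffs_delta()` — the statistical pipeline (Shapiro–Wilk gating,
  Wilcoxon signed-rank / paired t, human-baseline correction, Cliff's
  delta with categorical labels);
* a CLI (`inst/cli/mirrorplayer`): `simulate`, `estimate`, `analyze`,
  `stats`, `make-fixtures`, each run emitting a reproducibility manifest.

## Worked example

```r
library(mirrorplayer)

cfg <- model_config()                     # 50 Hz, 60 s, K_intra 0.005
trial <- run_trial("coupling", config = cfg, seed = 42)
trial
#> <trial_record coupling> 3001 samples, seed = 42, model used (k_inter = 0.0075)

trial_metrics(trial)
#>   condition    mean_R lock_fraction time_pressed_s     ratio
#> 1  coupling 0.9831956             0           56.1 0.9346884
```

`mean_R` is the time-averaged Kuramoto order parameter of the facing hand
pair (0.98: the synthetic participant and the character are tightly
synchronised), and `time_pressed_s` says the simulated participant's button
model reported felt synchrony for 56.1 s of the minute. Estimating the
partner's parameters back from the trial recovers the generating profile:

```r
estimate_params(trial$human_right, trial$human_left)$right
#> <hand_params right> center = (0.903, 1.201, 0.249) m, r0 = 0.160 m, omega0 = 2.691 rad/s
```

A full synthetic study (34 participants) through the two-stage statistics:

```r
analyze_sync_times(generate_sync_times(seed = 42))
#> <stat_result shapiro_human> stat = 0.9033, p = 0.005613, ...
#> <stat_result wilcoxon_raw> stat = 151, p = 0.05732, delta = 0.121 (negligible), n = 34
#> <stat_result shapiro_coupling_minus_human> stat = 0.9675, p = 0.3973, ...
#> <stat_result paired_t_baseline> stat = 2.29, p = 0.02854, delta = 0.216 (small), n = 34
```

showing the pattern the pipeline is built to expose: raw button times are
non-normal and the rank test on them is inconclusive, while the
human-baseline-corrected times are normal and the paired t-test resolves
the coupling effect.

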