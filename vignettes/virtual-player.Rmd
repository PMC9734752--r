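---
title: "The coupled-oscillator virtual player: model, simulator and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled-oscillator virtual player: model, simulator and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorplayer)
```

## The problem

In the mirror game two players face each other and imitate each other's hand
movements. A virtual character can stand in for one of the players if its
hands move plausibly *and* respond to the partner. `mirrorplayer` implements
such a virtual player — two circular hand movements driven by a pair of
second-order Kuramoto phase oscillators — together with everything needed to
study it end to end without human participants: a closed-loop dyad simulator
with synthetic partners, phase and synchrony analytics, and the statistical
pipeline used to compare experimental conditions.

## The model

Each virtual hand traces a circle in the frontal (y–z) movement plane. For
the right hand at phase $\theta_R$ and radius $r_R(t)$,

$$p_R(t) = c_R + r_R(t)\cos\theta_R\,\hat z + r_R(t)\sin\theta_R\,\hat y,$$

and the left hand counter-rotates laterally (its $\cos$ term carries a minus
sign), so that equal phases put the two hands at mirror-image positions. The
frame is right-handed with $\hat y$ vertical, $\hat z$ lateral and $\hat x$
the facing axis; the movement plane sits at $x = 0.343$ m from the character
origin and the character stands 1.246 m from the participant.

The radius is not constant: it is modulated by smooth gradient (Perlin)
noise, $r(t) = r(0) + n(t)$ with $n(t)\in[-0.085, 0.085]$ m. Gradient noise
rather than white noise keeps the hand motion continuous at the 50 Hz sample
rate.

The phases obey a second-order (inertial) Kuramoto law. With $H$ and $V$
denoting the human and the virtual player,

$$\dot\omega_R = K_{inter}\sin(\theta^H_L - \theta^V_R)
             + K_{intra}\sin(\theta^V_L - \theta^V_R),$$

and symmetrically for the left hand. Note the *crossed* pairing: each
virtual hand is attracted to the phase of the human's opposite hand, which
is the hand it faces in a mirror arrangement. $K_{intra} = 0.005$ rad/s²
binds the virtual player's own hands together; $K_{inter}$ sets the
responsiveness to the partner and defines the experimental conditions:

| condition     | $K_{inter}$ | virtual hands driven by              |
|---------------|-------------|--------------------------------------|
| `human`       | (model off) | a recorded/simulated partner, verbatim |
| `no_coupling` | 0           | the oscillators, open loop           |
| `coupling`    | 0.0075      | the oscillators, tracking the human  |

The integration is explicit Euler at $\Delta t = 0.02$ s, exactly as the
update rule is stated: the velocity is updated first,
$\omega(t_k) = \omega(t_{k-1}) + \dot\omega\,\Delta t$, and the phase then
advances with the *new* velocity. This phase-increment reading,
$\theta(t_k) = \theta(t_{k-1}) + \omega(t_k)\Delta t$, is the only
continuous interpretation when $\omega$ varies; it coincides with the
literal $\cos(\omega t)$ form for constant $\omega$, which is retained in
tests as a verification mode. Phases are wrapped to $(-\pi, \pi]$ after
every step, and phase differences are wrapped before the sine (numerically
harmless, required for diagnostics).

### Why these dynamics lock

Against a partner oscillating at a constant detuning $\Delta\omega$ and with
$K_{intra} = 0$, the relative phase $\varphi$ obeys the pendulum equation
$\ddot\varphi = -K_{inter}\sin\varphi$ with $\dot\varphi(0) = \Delta\omega$.
Energy conservation puts the separatrix between bounded (locked) and
rotating (drifting) solutions at $|\Delta\omega| = 2\sqrt{K_{inter}}$, i.e.
0.173 rad/s at the operating gain. The acceptance suite verifies that the
simulated player reproduces this threshold within 5% of an independent
Runge–Kutta integration of the pendulum equation (`deSolve`).

### Parameters

| parameter          | default | units  | meaning                                |
|--------------------|---------|--------|----------------------------------------|
| `k_inter`          | 0/0.0075| rad/s² | coupling towards the human partner     |
| `k_intra`          | 0.005   | rad/s² | coupling between the virtual hands     |
| `noise_amplitude`  | 0.085   | m      | half-range of the radius noise         |
| `sample_rate`      | 50      | Hz     | simulation and recording rate          |
| `plane_offset`     | 0.343   | m      | movement plane along the facing axis   |
| `partner_distance` | 1.246   | m      | character-to-participant distance      |
| `duration`         | 60      | s      | trial length                           |
| `radius0`, `omega0`| 0.16 m, 2.7 rad/s | | population-mean hand parameters |

The hand parameters (`center`, `radius0`, `omega0`) are estimated per
partner from a training trial by `estimate_params()`: the centre is the mean
position, the radius the mean distance from it, and the angular velocity the
mean derivative of the unwrapped extracted phase, taken as a positive
magnitude (rotation direction is absorbed by the per-side phase convention).
Estimation refuses near-stationary input (mean radial spread below
$r_{\min} = 0.03$ m).

## Perlin noise conventions

The published description fixes only the range, the continuity requirement
and the sample rate, so the lattice conventions are ours: classic 1-D
gradient noise with one node per second, a single octave, ±1 gradients
assigned by a deterministic integer hash of `(node, seed)`, quintic fade,
and a final rescaling by $2\times$ amplitude so the theoretical extremes
(±1/2 at mid-lattice with opposing gradients) map exactly onto
±`noise_amplitude`. Right and left hands draw from independent streams
derived from the trial seed. The hash arithmetic stays below $2^{53}$, so
noise values are bit-identical across platforms and never touch R's global
RNG.

## Phase extraction

The original real-time system never documented how it computed the human's
phase; we use the centred arctangent,
$\theta = \operatorname{atan2}(y - c_y,\; \pm(z - c_z))$ (sign by side),
because it inverts the generative circle model exactly and works causally,
which is what a real-time implementation must have done. A Hilbert-transform
estimator would require the whole trial and offers no benefit on
quasi-circular motion. The centre defaults to the trajectory's mean
position; samples within $r_{\min}$ of the centre carry no usable angle and
repeat the last valid phase (freeze rule), mirroring the fact that the
autonomous character keeps moving when the player stops. Derivatives of
phase are always taken on the nearest-branch unwrapped series.

## The synthetic dyad

The study this package models recorded real participants, so the synthetic
human (`human_profile()`) is explicitly scaffolding. It reuses the circular
kinematics with its own centre/radius/tempo and comes in three kinds:
`constant`, `drifting` (angular velocity follows an Ornstein–Uhlenbeck
process around the preferred tempo, stationary sd `drift_sd`, time constant
`drift_tau`), and `coupled` (adds a sinusoidal phase attraction of gain
`k_human` towards the virtual player's opposite hand). The OU relaxation
acts on the *full* velocity, so the human is a damped follower with a
preferred tempo — without that damping a second-order follower librates
forever and closed-loop comparisons become unstable.

Defaults are chosen once to match the training-trial population estimates
and plausible human variability: `base_radius` 0.16 m and `base_omega`
2.7 rad/s (the estimated population means), `drift_sd` 0.15 rad/s (≈5%
tempo variability), `drift_tau` 5 s, 5 mm tracking jitter, and `k_human`
0.15 rad/s² — strong enough that a participant instructed to mirror
actually locks to the character (lock range $2\sqrt{0.15}\approx0.77$
rad/s).

`run_trial()` assembles the three conditions. In `human`, a second,
independently seeded human is simulated and copied verbatim into the
virtual-player slot (the model is not used). In `no_coupling`, the virtual
player runs open loop; the participant may still track it one-way. In
`coupling`, human and virtual player are co-simulated with each side seeing
the other's phase from the previous tick — a deliberate one-tick (20 ms)
delay that mimics the networked two-machine setup and avoids algebraic
loops. Because of it, a 60-s simulation extends a 10-s simulation
sample-for-sample, which is how the causality tests check the scheduling.

The felt-synchrony button is modelled as a threshold-dwell rule on the
relative phase of the facing hand pair: pressed once $|\varphi| < \pi/4$
has held for 0.5 s. Both numbers are conventions (the real button reflects
subjective feeling) and are configurable.

The questionnaire generator produces 10 graded items on the −3..+3 scale
for 34 participants (the analysed sample size) as rounded, clipped
Gaussians: grand mean + per-question condition effect + participant
intercept (sd 0.5) + residual (sd 1). The sync-times generator reproduces
the *structure* of the button data: a large idiosyncratic baseline
(bias sd 12 s, with a 20% minority of near-ceiling "always pressers" that
makes the raw samples non-normal) plus condition shifts of +2.2 s
(`coupling`) and −3.1 s (`no_coupling`) relative to `human` and a 12-s
trial residual — magnitudes taken from the published baseline-corrected
sample means and dispersions.

What the synthetic dyad does *not* emulate: individual motor signatures,
fatigue, gesture variety beyond circles, reaction latencies beyond one
tick, or any cognitive model of when people *feel* in synchrony. Passing
tests therefore validate the machinery — the oscillators, the loop, the
estimators and the statistics — not claims about human behaviour.

## The statistical pipeline

The pipeline mirrors the published analysis. Questionnaire items are
compared per question with the Wilcoxon signed-rank test; reported synchrony
times go through two stages: Shapiro–Wilk per condition and a signed-rank
test on the raw `coupling` vs `no_coupling` times, then a human-baseline
correction (subtracting each participant's `human`-condition time) followed
by Shapiro–Wilk on the difference samples and a paired t-test. Shapiro–Wilk
gates at $\alpha = 0.05$. Effect sizes are Cliff's delta,
$\delta = (\#\{a_i > b_j\} - \#\{a_i < b_j\})/(|a||b|)$, computed by
exhaustive pair counting.

Implementation choices worth knowing:

* **Signed-rank convention.** The statistic is $\min(W^+, W^-)$ with zero
  differences dropped and a tie-corrected normal approximation without
  continuity correction — the convention of the mainstream scientific-Python
  toolkits, so the statistic is directly comparable to published W values.
  `stats::wilcox.test` (which reports $V = W^+$) serves as the independent
  cross-check in the tests.
* **Effect labels.** $|\delta|$ cuts at 0.15 / 0.33 / 0.66 for
  negligible / small / medium / large. The conventional 0.474 medium/large
  cut would contradict the published labelling (0.5 labelled medium); the
  cuts are configurable.
* **No multiple-testing correction** across the 10 questions by default,
  matching the practice of reporting raw per-question p-values; Holm and
  friends are available via `p_adjust`.
* **Degenerate inputs.** All-zero paired differences raise an explicit
  degenerate-test error in `compare_paired()`; inside
  `analyze_sync_times()` the same situation is propagated as a flagged
  null result so a batch analysis never aborts.
* An open ambiguity in the source tables — medians printed as
  non-half-integers — is left alone: we report true sample medians.

## Numerical choices and test scale

Tolerances: on-circle identity to 1e-9 (it holds to machine precision),
parameter recovery to 1e-9 noiseless and (2 mm, 0.02 rad/s) at 5 mm noise,
locking threshold within 5% of the independent pendulum integration. The
locking analyses simulate 600 s at 50 Hz and classify lock as a bounded
(range < $2\pi$) post-transient relative phase; 600 s is long relative to
the slow libration near the separatrix (period $2\pi/\sqrt K \approx 73$ s).
Monte-Carlo sizes — 100 trials for the invariant sweeps, 100 replicates
for recovery, 200 for the power study, 20 paired seeds for the closed-loop
comparison — keep the whole suite under a minute while leaving Monte-Carlo
error well below the asserted margins.

The closed-loop order-parameter comparison uses a marginal-tracking human
(`k_human = 0.03`, `drift_sd = 0.3`): with the default strong tracker the
human locks with or without the virtual player's help and the coupling gain
of 0.0075 rad/s² changes nothing measurable. In the marginal regime the
mutual adaptation contributes a reliably positive mean gain, which is the
claim the test asserts (per-seed strict ordering does not hold in a
stochastic dyad).

## Known limitations

* The virtual player's phase dynamics are undamped; only the synthetic
  human carries relaxation. This is faithful to the published model but
  means open-loop frequency errors persist for the whole trial.
* Explicit Euler at 20 ms is part of the model definition, not a numerical
  convenience; do not raise `sample_rate` expecting convergence to an
  underlying ODE with the same constants.
* The published behavioural statistics can only be recomputed from the
  study's per-participant supplementary data, which are not redistributable
  with this package; the corresponding check in the test suite documents
  the expected values and fails until that table is supplied.

```{r example, eval = FALSE}
cfg <- model_config()
trial <- run_trial("coupling", config = cfg, seed = 42)
trial_metrics(trial)
analyze_sync_times(generate_sync_times(seed = 42))
```
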