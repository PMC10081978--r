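---
title: "Modeling and measuring bimanual coordination under force fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring bimanual coordination under force fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordphase)
```

# The scientific problem

When people oscillate both hands rhythmically, only two coordination
patterns are stable without training: in-phase (relative phase
$\phi = 0$, homologous muscle groups contracting together) and
anti-phase ($\phi = \pi$, alternating contraction). Anti-phase is the
weaker attractor: it is more variable, and at high movement frequencies
it collapses into in-phase, never the reverse. `coordphase` provides a
complete, simulation-backed pipeline for studying how *mechanical
asymmetries between the arms* — such as a robot applying a viscous
(velocity-dependent) or elastic (position-dependent) force field to one
or both hands — perturb these patterns: a coupled-oscillator model, a
synthetic experiment generator styled on a robotic exoskeleton paradigm,
a Hilbert-transform continuous-relative-phase (CRP) measurement
pipeline, and a mixed-effects statistical layer.

# The model

## Potential dynamics of relative phase

The relative phase between the hands is modeled by the standard
potential-function account of rhythmic interlimb coordination, extended
with a symmetry-breaking detuning term:

$$V(\phi) = -\Delta\omega\,\phi - a\cos\phi - b\cos 2\phi$$

yielding the Langevin dynamics

$$\dot\phi = -\,V'(\phi) + \sqrt{Q}\,\xi_t
          = \Delta\omega - a\sin\phi - 2b\sin 2\phi + \sqrt{Q}\,\xi_t$$

with $\xi_t$ unit white noise. The parameters, their units, defaults and
rationale:

| parameter | units | default | role |
|---|---|---|---|
| $a$ | rad/s | 1 | depth of the in-phase well (coupling at the movement frequency) |
| $b$ | rad/s | 1 | depth of the anti-phase well (coupling at twice the frequency); $b/a < 1/4$ destabilizes anti-phase |
| $\Delta\omega$ | rad/s | 0 | detuning: eigenfrequency difference between the arms; tilts the potential and shifts the attractors |
| $Q$ | rad²/s | — | noise strength; sets phase variability |

With $a = b = 1$ the stable fixed points sit at $0$ and $\pi$ with
curvatures $V''(0) = a + 4b = 5$ and $V''(\pi) = -a + 4b = 3$; in-phase
is always the stiffer well. Near a stable point the dynamics linearize
to an Ornstein–Uhlenbeck process, so the stationary phase SD is
$\sqrt{Q / 2V''(\phi^*)}$ (`hkb_predicted_sd()`), and the predicted
anti-phase/in-phase SD ratio at $a = b = 1$ is $\sqrt{5/3}$.

`hkb_fixed_points()` locates all stationary phases on $(-\pi, \pi]$ by a
dense sign-change scan of the drift followed by bisection; exact grid
hits (such as $\phi = \pi$ at zero detuning, where the drift underflows
without a sign change) are caught by a relative near-zero test. When the
detuning exceeds the maximal restoring drift there is no stationary
phase and an empty table is returned — phase wrapping, not a solver
failure.

## Numerical integration

`simulate_phase()` integrates the Langevin equation by Euler–Maruyama at
the sampling rate of the rendered kinematics (default 1000 Hz, so
$\Delta t = 1$ ms). At these step sizes the deterministic step error is
negligible against every tolerance used downstream; the function warns
if the largest deterministic step exceeds 0.1 rad so that stiff
parameter choices are not integrated silently at too coarse a step.
Noise is pre-drawn under an isolated RNG scope (`withr::with_seed`) so
simulations are reproducible without disturbing the caller's RNG state.

# The synthetic experiment generator

## What it emulates

`experiment_design()` / `run_experiment()` reproduce the structure of a
Kinarm-style bimanual paradigm: 9 load conditions (each arm under
`none`, `viscous`, or `elastic` field) × 2 paced cycle periods (750 and
1200 ms) × 5 repetitions = 90 trials per coordination mode per
participant; 45 s trials sampled at 1000 Hz; 10 cm peak-to-peak
hand excursions along the y axis. Each trial's relative phase is
simulated from the potential model and rendered into two-hand
kinematics, $y_L = \tfrac{A}{2}\sin\theta(t)$,
$y_R = \tfrac{A}{2}\sin(\theta(t) - \phi(t))$, plus Gaussian measurement
noise (0.5 mm SD, the scale of optical/robotic position noise).
`force_field()` annotates traces with the commanded robot force,
$F = k \begin{pmatrix} 0 & -1 \\ 1 & 0 \end{pmatrix} u$ with $k = -15$
acting on velocity (viscous) or $k = +15$ acting on displacement
(elastic) — a rotational field orthogonal to its driving vector, which
is why it perturbs rather than assists the movement.

## Load-to-dynamics calibration

The bridge from load condition to model parameters is
`condition_dynamics()`, driven by `default_dynamics_mapping()`:

- each load pulls its arm's eigenfrequency (`none` 0, `viscous` −0.35,
  `elastic` −0.15 rad/s); the detuning of a condition is
  $\Delta\omega = \text{pull}(L) - \text{pull}(R)$, so matched loads
  cancel and mismatched loads tilt the potential;
- each load adds phase noise (`viscous` +0.01, `elastic` +0.02 rad²/s
  per arm on a 0.02 rad²/s base), doubled in anti-phase where the
  shallower well amplifies perturbations.

These values are the package's fixed study conditions, not free dials:
viscous fields damp velocity and slow the limb cycle more than elastic
fields do, elastic fields inject more state-dependent disturbance, and
anti-phase coordination is uniformly noisier. A consequence worth
stating explicitly: because matched loads cancel in $\Delta\omega$ but
*add* in $Q$, a matched elastic/elastic condition carries the largest
noise of any condition, and the mean *absolute* deviation of folded
phase grows with noise even at zero detuning (the folded mean of a
zero-mean fluctuation is $\sigma\sqrt{2/\pi}$). So under this
calibration the matched elastic/elastic condition can deviate more than
a weakly-detuned mismatched pair — mismatch is not a perfect separator
of deviation, and the end-to-end suite documents exactly that behavior.

Participant heterogeneity: one random intended-phase offset per
participant (SD 2°) and one positive noise multiplier (SD 0.2 around 1),
drawn once per participant; per-trial seeds are derived from the master
seed so any single trial can be regenerated in isolation.

## What it does not emulate

The generator produces stationary-phase rhythmic movement with additive
white measurement noise. It does not emulate movement onset/offset
transients beyond the model's own relaxation, pacing-metronome
entrainment error, amplitude drift or fatigue, within-trial learning,
broken or missing channels, or soft-tissue/robot-dynamics artifacts.
Green tests therefore certify the pipeline's correctness on data whose
generating process is known — they bound algorithmic error, not the
biological validity of the model.

# The measurement pipeline

Each hand's displacement is midrange-centered,
$x \mapsto x - \min x - \tfrac{1}{2}(\max x - \min x)$, which removes
offset without assuming amplitude symmetry. The analytic signal is
formed by the FFT method (zero the negative frequencies, double the
positive ones), the instantaneous phase is the four-quadrant
`atan2(H(x), x)` unwrapped by `signal::unwrap`, and the CRP is

$$\phi(t) = \arctan\!\frac{H_1(t)\,x_2(t) - H_2(t)\,x_1(t)}
                          {x_1(t)\,x_2(t) + H_1(t)\,H_2(t)}$$

folded into $[0°, 180°]$, with hand 1 the right hand. Per-trial
summaries use the 12–42 s window (half-open, exactly 30 000 samples at
1000 Hz), skipping the settling-in period and any end-of-trial slowing.

Numerical choices: signals shorter than 4 samples or constant are
rejected rather than silently processed; zero-amplitude samples (both
the signal and its quadrature zero) have no defined phase and propagate
the previous sample's angle with a message; the window extractor treats
a trial's final sample as covering one sampling step so a 45 s record
contains the full 12–42 s window.

## Phase-transition exclusion

Anti-phase trials that collapse into in-phase must be excluded from
condition averages, or they drag the anti-phase mean toward 0°.
`detect_phase_transition()` flags a trial when a 3 s moving average of
its folded CRP crosses more than 90° away from the intended phase —
a sustained basin change — while brief excursions and measurement
spikes do not trigger it. The 3 s window, 0.5 s step and 90° threshold
are the package's own operational definition (the underlying phenomenon
is usually reported only qualitatively); they are deliberately coarse so
that the flag identifies basin changes, not variability.

## Measured SD versus the model's SD

The Ornstein–Uhlenbeck prediction $\sqrt{Q/2V''}$ applies to the *phase
trajectory*. The Hilbert measurement estimates instantaneous phase from
a carrier of finite frequency (≈ 1.3 Hz at the 750 ms period), so phase
fluctuations faster than the carrier are smoothed: the pipeline-measured
SD is attenuated relative to the generating process (at $Q = 0.005$,
to roughly half). This is a property of analytic-signal phase
estimation, not an implementation defect — the simulated trajectory
itself matches the OU prediction, and the test suite asserts both facts
separately. Consequences: comparisons of measured SD across conditions
remain valid (the attenuation is common-mode), but measured SDs should
not be read as direct estimates of $\sqrt{Q/2V''}$.

# The statistical layer

`build_condition_table()` pools retained trials into the 4 analysis
strata (mode × cycle period) with a 9-level load-condition factor
(reference `none/none`). Per stratum and response (mean CRP or SD of
CRP), `fit_lme()` fits

```
response ~ load_condition + (1 | trial) + (1 | participant)
```

by REML through `lmerTest`, reporting per-coefficient Wald $\chi^2$
p-values. A singular fit (trial variance estimated at the boundary) is
refit with the participant intercept only, with a logged downgrade;
non-convergence is an error, never silent. `pairwise_emm()` produces the
9 estimated marginal means and all 36 Tukey-adjusted pairwise contrasts
(`emmeans`, Satterthwaite df), and `learning_effect_check()` adds a
trial-index slope to test for practice effects. `classify_handedness()`
implements the standard laterality-quotient cutoffs (≤ −61 left,
≥ +61 right, mixed between).

`simulate_condition_table()` generates summary-level data with known
offsets, participant/trial variance components and trends; it backs the
recovery and error-control simulations: a +5° injected condition offset
is recovered with small bias over 50 replicates of 20 participants, and
the null family-wise error of the Tukey contrasts is checked over 200
replicates at 8 participants × 2 repetitions (family-wise error control
does not depend on sample size, so the smaller design tests the same
property at lower cost).

# Problem sizes used in verification

The test and verification suites run at desk scale: single 45 s trials
at 1000 Hz for measurement checks; one 2000 s simulation at 250 Hz for
the stationary-density (Boltzmann) check at $Q = 0.1$; 10–20 repeated
45 s simulations for SD checks at $Q = 0.005$; 50 and 200 replicates for
the statistical simulations; and one 4-participant full-design synthetic
study (720 trials) for the end-to-end direction-of-effect check. Larger
designs run through the same code paths via the streaming
`run_experiment()`, which never holds more than one trial's kinematics
in memory.

# Known limitations

- The load-to-dynamics calibration is a stylized stand-in for real
  robot–limb interaction; only its qualitative structure (mismatch ⇒
  detuning, loads ⇒ extra noise, anti-phase noisier) is asserted.
- The transition detector is an operational rule; it is validated on
  constructed cases, not against human-rater exclusions.
- Measured SD is attenuated relative to the generating phase SD (see
  above); absolute SD comparisons against the OU formula must be made on
  phase trajectories.
- The mixed model uses random intercepts only; random slopes by
  condition are out of scope.
- CSV is the interchange format; native robot binary formats are a
  documented extension point, not implemented.
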