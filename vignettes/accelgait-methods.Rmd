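---
title: "Belt-acceleration propulsion training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belt-acceleration propulsion training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelgait)
```

## The problem

Propulsion — the forward push generated in late stance — has a kinematic
component (the posture of the trailing limb, quantified by the trailing
limb angle, TLA) and a kinetic component (the anterior ground reaction
force, AGRF, generated chiefly by the ankle plantarflexors). After a
stroke, propulsion of the paretic leg is weak and asymmetric. One implicit
training strategy accelerates the treadmill belt under the trailing limb
during push-off, challenging force generation precisely when the
plantarflexors are active. Running such a protocol requires (i) a
real-time controller that times short belt accelerations to the gait
cycle, and (ii) an offline pipeline that turns force-plate, marker and
EMG recordings into per-stride propulsion outcomes.

`accelgait` implements both, plus a synthetic gait generator with exact
ground-truth labels, so the whole chain is testable without any recorded
data.

## The belt-acceleration controller

The controller runs per belt at a fixed 1 ms tick. Its goal: the belt
under the trailing limb should accelerate for a desired duration
$T_{des}$ ending at toe off (TO), preferably inside double support. Since
the treadmill actuates with delay $T_{del}$, commands must lead the
predicted toe off $T_{TO,pred}$ by

$$T_{TOT} = T_{des} + T_{del},$$

220 ms with the defaults ($T_{des}=180$, $T_{del}=40$ ms).

Decision logic per tick, inside the lead window
$t > T_{TO,pred} - T_{TOT}$:

* **Low speed** ($v \le 0.5$ m/s): double support is long, so the
  controller waits until the contralateral heel strike (HS) has actually
  been detected, then accelerates; the acceleration ends when TO is
  detected.
* **High speed** ($0.5 < v < 1$ m/s): double support is comparable to
  $T_{des}$, so the belt is accelerated in *anticipation* of the
  contralateral HS, starting $T_{ant}$ before its prediction
  $T_{HS,pred}$ and holding through $T_{HS,pred} + T_{HSdelay}$
  ($T_{HSdelay} = 70$ ms). The anticipation scales with speed,
  $T_{ant} = T_{antBase}\,(2v-1)$ ($T_{antBase} = 175$ ms), saturating at
  $v \ge 1$ m/s.
* **Safety**: if the contralateral HS has not arrived when the window
  closes, or if TO does not occur within $T_{maxDur} = 250$ ms of the
  acceleration onset $t_{accel}$, the acceleration stops and the
  controller pauses for three steps while the event predictions are
  rebuilt.

Event predictions use the previous gait cycles: next event = last event
plus the median of up to the last three inter-event intervals
(`predict_events()`). Predictions are refreshed when the controlled leg's
toe off is ingested, so during a double support the controller reasons
about the *current* awaited events; a pause clears the histories and the
three pause steps supply fresh ones.

Design choices where the logic itself left room:

* **Control tick** 1 ms: resolves every constant exactly; the force loop
  runs at 500 Hz, so sensing is the limiting granularity.
* **"Step"** = heel strike of the controlled leg. With that reading, a
  missed-HS pause yields exactly the documented behavior: the stride with
  the miss has its acceleration aborted, the next two strides are fully
  acceleration-free, and the third step after the pause is accelerated
  again.
* **$t_{accel}$** is recorded at the first accelerating tick of an
  episode — the discrete-time realization of "window entry" (the outer
  gate is a strict inequality, so the first eligible tick is one tick
  past the nominal window edge).
* **Regime speed** is the commanded base speed, not the instantaneous
  belt speed, avoiding regime chatter during the accelerations
  themselves.
* **In-loop sensing** is a causal 50 N crossing with a 20 ms debounce
  (the offline 200 ms persistence rule is non-causal); events keep their
  crossing timestamp and become visible at confirmation. Ground-truth
  sensing is available behind a flag for timing studies.
* **Plant model**: belt accelerates at 5 m/s² beginning $T_{del}$ after
  the command, stops rising $T_{del}$ after the command ends, and returns
  to base speed at the same magnitude (the return profile is a modeling
  choice); speed never falls below base. A session ramps the magnitude
  linearly over the ramp phase before full exposure.

An independently written tick-by-tick evaluator of the same decision
table (`reference_command_log()`, no incremental state) must produce
bit-identical command logs; this is asserted over 50 seeded sessions in
the test suite.

### Timing across speeds

The anticipation scaling encodes an assumed relation between speed and
double-support (DS) duration: the onset precedes TO by
$DS + T_{ant} - T_{del}$ at high speed, which equals $T_{des}$ exactly
when $DS = T_{TOT} - T_{ant}(v)$. `gait_config_for_speed()` constructs
synthetic gait obeying that inverse relation (any $DS > T_{TOT}$ at low
speed), with the cycle duration snapped to the 2 ms force grid so that
threshold-crossing events are exactly periodic and predictions exact.
Under those conditions the realized onset precedes the true toe off by
$T_{des}$ within 2 ms at every tested speed (0.3–1.1 m/s), which the
acceptance tests assert.

## Offline pipeline

**Filtering.** Force traces are low-pass filtered at 25 Hz, EMG band-pass
filtered at 20–500 Hz, rectified, and low-pass filtered at 10 Hz — all
with 4th-order zero-shift Butterworth filters (forward–backward
application; the effective order doubles). Because `signal::filtfilt`
applies no padding and rings at the edges, the package odd-reflects the
signal at both ends before the forward/backward pass and strips the
padding afterwards. Forces are filtered once, upstream of both event
detection and metrics.

**Events.** A heel strike is the first sample at which the vertical GRF
exceeds 50 N (strictly) and stays above for at least 200 ms; a toe off is
the mirrored downward crossing. Timestamps are kept at the 500 Hz sample
granularity (no sub-sample interpolation). `pair_events()` enforces
HS/TO alternation per leg, dropping and counting violators. Marker gaps
strictly shorter than 25 samples (50 ms) are linearly interpolated;
longer or boundary gaps stay missing.

**Per-stride metrics.** Over each gait cycle (HS to next ipsilateral HS):
peak AGRF is the maximum positive antero-posterior force / bodyweight;
the propulsive impulse (PI) is the trapezoidal integral of the positive
portion / bodyweight (stored in BW·s; report-scale conversions such as
$\times 10^{-3}$ are left to presentation). TLA is the sagittal angle
between vertical and the hip→ankle marker line at TO, positive when the
ankle trails the hip. Stride length on a treadmill is
$SL = \Delta P_{HS} + \int_{t_{HS,prev}}^{t_{HS,curr}} v\,dt$ — ankle
displacement between heel strikes plus integrated belt travel. Velocity
is the mean belt speed over the cycle; stance duration is HS→TO of the
same leg.

**EMG activations.** Each envelope stride is resampled onto a fixed phase
grid: 0–100% of stance and swing (200 points) for the plantarflexors and
for the tibialis anterior co-contraction index (TACC); 0–100% of double
support, of the inter-toe-off interval, and of swing (300 points) for the
tibialis anterior (TA). Activation is the ROI mean: second half of stance
(grid points 51–100) for SOL/LGAS/MGAS/TACC; for TA, the signal
surrounding heel strike — this stride's swing plus the *following*
stride's double support (the last stride of a trial therefore has no TA
activation). Activations are normalized by the mean, over
outlier-cleaned baseline strides, of the per-stride ROI peak envelope;
normalization is invariant to channel gain, and a zero divisor flags the
channel unusable.

**Automatic stride-outlier removal.** Three screens per muscle, each:
trim the top and bottom 5% (⌈0.05 n⌉ per tail) of the statistic, compute
mean and SD of the remainder, flag strides whose untrimmed statistic is
beyond 10 SD (two-sided). Statistics: ROI maximum, ROI mean, and the
value at every point of the stride (one 1-D screen per point; any flagged
point flags the stride). The three screens are evaluated on the original
stride set and their flags combined, making the result independent of
evaluation order and equivariant under stride permutation. Dispersion at
numerical precision (≤ $10^{-8}$ relative) counts as zero, so identical
strides are never removed.

**Protocol binning.** Strides are binned into BL (heel strikes in the
last 60 s of baseline), EE / LE (first / last 20 exposure strides), EPE /
LPE (first / last ⌊25%⌋, minimum 1, of post-exposure strides). Exposure
is counted from full acceleration magnitude (after the ramp; the ramp
minute belongs to neither bin — configurable). Bins under 40 exposure
strides overlap and are flagged. Post-exposure series can be resampled
onto a 0–100% axis for cross-session comparison. Helpers provide the
age-predicted maximum heart rate ($220 - \text{age}$, with the 85%
safety threshold) and the Bonferroni threshold ($\alpha/k$; 0.0125 for
four contrasts). Change-from-baseline summaries are descriptive (means
with stride-count-weighted standard errors); fitting mixed models to the
emitted tables is deliberately left to dedicated statistics tools.

## The synthetic gait generator

The generator emulates the statistical structure the pipeline assumes,
with exact labels:

* **Vertical GRF**: raised-cosine loading/unloading ramps (120 ms) around
  a bodyweight plateau per stance. Ground-truth events are the analytic
  50 N crossings snapped to the sample grid, so the offline detector must
  recover them exactly on noiseless data.
* **AP GRF**: a braking then propulsive pair of squared-sine lobes. The
  smooth ($C^1$) lobes pass the 25 Hz filter essentially unchanged, which
  gives closed-form ground truth: peak = configured amplitude, impulse =
  amplitude × stance/4.
* **Kinematics**: the ankle marker rides the belt backwards during stance
  (AP velocity = −belt speed) and swings forward to the next landing
  position; landing positions are anchored so that the TLA at the true
  toe off equals the configured angle under the generation-time belt.
  When a different belt profile is imposed (`apply_belt_profile()`), the
  anchors stay fixed: extra late-stance belt travel then increases the
  TLA and changes exactly the perturbed cycle's stride length by the
  pulse's integral — the same mechanism the training exploits.
* **EMG**: a deterministic per-muscle carrier (95–155 Hz) amplitude
  modulated by phase-locked Gaussian bursts plus additive Gaussian noise.
  With a deterministic carrier the rectified mean is analytic
  ($2/\pi \times$ modulation), giving exact ground-truth activations on
  the same phase grids the pipeline uses.
* **Cadence**: a common cycle duration for both legs (two legs of one
  walker cannot sustain different cadences), per-stride Gaussian
  variability truncated at 3 SD; per-leg asymmetry enters through stance
  fraction, phase offset, force amplitudes and TLA. Double support
  emerges from stance fractions and the phase offset and spans the
  100–400 ms range the controller's two regimes need.
* **Artifacts**: labeled spikes (tone bursts), dropouts and flatlines per
  channel and stride, for scoring the outlier remover's recall and false
  positives.

What the generator does **not** emulate: physiological inter-limb
coupling of force shapes, reactive cadence changes under perturbation
(coupling is one-way — belt speed shapes kinematics, never event
timing), soft-tissue marker artifacts, or EMG crosstalk. Passing tests
therefore validate the *pipeline's* correctness and the controller's
timing logic, not claims about real post-stroke walkers.

## Numerical choices and degenerate inputs

* Event timestamps and the trailing stride are dropped rather than
  guessed when a stance is cut by the trial boundary (persistence cannot
  be established); pairing logs every dropped event.
* The belt-displacement integral extrapolates linearly (last speed)
  beyond the recorded trace so that landing anchors of the final strides
  are well defined.
* All-missing marker channels warn and pass through; gaps of exactly the
  maximum length are left missing ("less than" is strict).
* `remove_outlier_strides()` requires ≥ 5 strides; `resample_stride()`
  refuses out-of-order events; negative belt speeds are rejected.
* Prediction quality: with the median-of-3 predictor the median absolute
  prediction error sits near 0.8 × the stride-duration SD (Monte-Carlo
  derived, asserted as a band in the tests) — adequate because the
  controller tolerates ±70 ms and pauses when it is wrong.

## Problem sizes in the test-suite

The suite exercises: 100 noiseless seeded trials (16 s each) for
ground-truth recovery; 50 seeded closed-loop sessions (12 s) for
controller/oracle equivalence; 50 + 50 seeded trials (30 s) for outlier
recall and false positives; 5-speed closed-loop timing sessions of ~20 s.
These sizes keep the full suite within a few minutes while leaving every
property's Monte-Carlo error far below its asserted margin; the same
computations at larger sizes are available by changing the loop bounds.

## Known limitations

* The closed loop is kinematic, not dynamic: belt perturbations do not
  feed back into gait timing or force generation, so training *effects*
  (adaptation) are outside the generator's scope — programmed effects
  can be injected per phase instead.
* The adaptive self-selected-speed treadmill controller used around the
  exposure phase in the original protocol is out of scope; sessions here
  run at a commanded base speed.
* Statistical inference (mixed models, Dunnett contrasts) is not
  reimplemented; the package emits tidy per-stride and per-bin tables
  for any external tool.
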