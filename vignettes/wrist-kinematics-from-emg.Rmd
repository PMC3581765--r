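---
title: "Methods: estimating wrist kinematics from forearm surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating wrist kinematics from forearm surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristemg)
```

## The problem

Simultaneous and proportional myoelectric control of a wrist prosthesis
requires estimating continuous joint angles — not discrete motion classes —
from the surface EMG of the forearm. A practical obstacle is that the EMG
pattern produced by the *same* wrist movement changes when the arm is held
in a different posture: muscles shift under the electrodes, loading
changes, and a regressor trained in one arm position degrades when the arm
moves. `wristemg` implements the complete analysis pipeline for
quantifying this effect and for the standard mitigation (pooling training
data across positions), together with a synthetic-session generator so the
entire chain is testable end to end without human recordings.

The three wrist degrees of freedom (DoFs) are flexion/extension (DoF1),
radial/ulnar deviation (DoF2) and pronation/supination (DoF3).

## Pipeline stages and the choices inside them

### Signal conditioning

Raw EMG (7 bipolar channels per forearm, 2048 Hz) is band-pass filtered
10–450 Hz with a second-order Butterworth filter and decimated 2:1 to the
1024 Hz analysis rate (anti-alias low-pass before decimation, via
`signal::decimate`). Filtering is causal by default because the method
targets online prosthesis control; `zero_phase = TRUE` switches to
forward–backward filtering for offline work. One consequence worth
knowing: the causal filter's group delay depends on the sampling rate it
is designed at, so "filter then decimate" and "decimate then filter" agree
only up to a small time shift in causal mode; in zero-phase mode the two
orders agree to well under 1% RMS, which is how the package tests the
equivalence.

The EMG and motion-capture streams are recorded on separate clocks and
carry a shared 20 Hz square-wave synchronization signal. Alignment detects
the first common rising edge by hysteresis thresholding at one/two thirds
of the signal range (robust to amplitude scaling) and trims an integer
number of leading samples from each stream on its own time base; no
floating-point time axis is ever constructed, so there is nothing to
drift. The residual misalignment is below half a kinematic sample period
(≈2 ms).

### Features

Per channel, on sliding analysis windows of 100 ms with 60 ms overlap
(102 samples, step 41 at 1024 Hz — the durations are not integral sample
counts at this rate, so the length is truncated and the step rounded,
fixed once for reproducibility), the pipeline computes the classic
time-domain set plus autoregressive coefficients ("TDAR", 10 features per
channel, 70 in total):

* **MAV** — mean absolute value;
* **MAVS** — MAV slope, taken as the difference of MAV between
  consecutive analysis windows (the per-window feature-vector layout
  leaves no natural intra-window segmentation; an across-window
  difference is the corresponding discrete slope);
* **ZC / SSC** — zero crossings and slope sign changes, both with an
  amplitude dead zone defaulting to 1% of the channel RMS, so that
  baseline noise does not saturate the counts;
* **AR1–AR6** — coefficients of a 6th-order linear predictor adapted by
  least mean squares over the (unit-variance normalized) window: zero
  initialization, step size 0.01, three sweeps. The reported coefficients
  are the *average of the weight trajectory over the final sweep* rather
  than the final weights: plain LMS leaves steady-state gradient noise of
  the same order as the smaller coefficients, and tail averaging removes
  most of it at no cost to the adapted solution. With these defaults the
  predictor recovers the coefficients of a known AR(2) process embedded
  in the 6-coefficient model to better than 0.1 per coefficient on a
  2048-sample realization.

### Joint angles from markers

Seven reflective markers per arm (shoulder; medial/lateral humeral
epicondyles MEP/LEP; ulnar/radial styloids STU/STR; second/fifth
metacarpal heads RMC/UMC) are captured at 256 Hz. The wrist frame has its
origin `O` midway between the styloids, its z-axis toward the midpoint of
the epicondyles (the forearm axis, positive proximal), its x-axis the
inter-styloid direction orthogonalized against z (the mediolateral axis —
the styloid markers make it point laterally on both arms without any
side-specific sign), and y = z × x. With `H` the metacarpal midpoint and
`(Hx, Hy, Hz)` its components on (x, palmar axis, distal axis):

* α₁ = atan(Hy / Hz) — flexion positive,
* α₂ = atan(Hx / Hz) — radial deviation positive,
* α₃ = ∠(STR−STU, LEP−MEP) ∈ [0°, 180°] — 90° is the prono-supination
  neutral, larger is pronation.

A right-handed frame cannot be mirrored, so on the left arm the palmar
direction is −y; the flexion sign is applied per side in the angle step.
This keeps the frame's right-handedness (det = +1) *and* makes mirrored
bilateral movements produce identical angle traces on both arms — which
is exactly what contralateral training requires. `atan` (not a
quadrant-aware variant) matches the stated ±90° ranges, with the distal
component kept positive by construction.

Angles are computed per frame from the raw markers and then filtered in
the angle domain (6 Hz second-order Butterworth low-pass, zero-phase so
the regression targets stay time-aligned with the features), then
upsampled to 1024 Hz by linear interpolation. Marker gaps up to 0.25 s
are linearly interpolated; frames in longer gaps are flagged and every
analysis window touching them is dropped from features and targets
jointly. Per-window regression targets are the mean of each angle over
the window's sample span.

### Regression

Three multilayer perceptrons — one per DoF — map the 70-dimensional
feature vector to the contralateral measured angle. The hidden layer has
three units, the output is linear; inputs are z-scored with training-set
statistics (a zero-variance feature falls back to unit scale), targets
stay in degrees. Fitting uses `nnet` with a small weight decay (1e-4).

Two training details are package design choices, since the underlying
optimizer and initialization are not fixed by the method itself:

* **Warm start.** With only three hidden units, randomly initialized
  training lands in poor local minima on a large fraction of starts (R²
  below 0.8 even on noiseless synthetic data). `train_mlp()` therefore
  initializes the network *at the ridge-regression solution*: small input
  weights place the sigmoid hidden units in their linear range so the
  initial network output equals the regularized linear predictor, plus a
  small seeded jitter to break hidden-unit symmetry. The optimizer then
  only ever improves on the linear fit. Training is deterministic given
  the seed.
* **Cross-validation without leakage.** "4/5 of each run for training"
  is implemented as contiguous fifths with a seeded block-to-fold
  permutation per run, because 60%-overlapping windows make window-wise
  random splits leak heavily. Held-out windows within two window indices
  of any training window (the overlap radius of the default window
  geometry) are additionally excluded from the test blocks, so no test
  window shares a single sample with the training data.

### Evaluation

Performance is the multivariate R²: one minus the ratio of the
error sum of squares to the target variance sum, *pooled over the
scenario's DoFs before the ratio is formed* (a single fraction — not the
mean of per-DoF R² values, which differs whenever DoF variances differ).
The analysis grid crosses four scenarios (DoF12 = runs 1–2, DoF13 = runs
3–4, DoF23 = runs 5–6, DoF123 = all seven runs) with training
configurations (each single position, plus the pooled set) and five
folds. Intra-position cells test on the fold's held-out blocks;
inter-position cells on *all* rows of the other positions; pooled cells
on the held-out blocks of each position (which pooled training never
saw). Inter-position scores are normalized by the fold-matched
intra-position baseline — fold-level pairing is the strictest
reproducible granularity for an intra-relative score — and the pooling
effect is assessed with a one-tailed paired t test across matched
(scenario, test position, fold) cells. The two-way ANOVA over subject
groups is out of the package's scope; the grid and normalized tables it
would consume are exactly what `run_pipeline()` writes.

## The synthetic-session generator

`simulate_session()` / `generate_session()` emulate one recording session
of the protocol: 3 arm positions × 7 runs, bilateral mirrored movement,
~65 s per run by default.

* **Movement scripts** follow the run table: one DoF articulated in
  alternating-direction neutral–extreme–neutral cycles whose half-period
  is drawn uniformly from 1–2 s per cycle (a smooth sin² bump, C¹ at the
  neutral joins), a second DoF held at 90% of its range, run 7
  articulating all three DoFs. Default amplitudes are 60° per DoF
  (α₃ ∈ [30°, 150°]), inside the stated conventions; the protocol left
  the range of motion to the subject, so a comfortable sub-maximal
  excursion is the realistic default.
* **Markers** come from a rigid-segment forward model (adult-scale
  segment lengths; 55 mm styloid spacing, 70 mm epicondyle spacing,
  80 mm metacarpal spacing) constructed so that `compute_angles()`
  recovers the scripted angles *exactly* (≈1e-13°) in the noiseless
  case — the geometric identity is the oracle for the kinematics module.
  Arm positions apply global rigid poses (angles are provably invariant
  to them); 0.5 mm isotropic marker noise, the capture system's stated
  calibration error, propagates to under 1° RMS of angle error.
* **EMG** is amplitude-modulated band-limited noise: per channel, an
  envelope `noise floor + Σ gain[c, d] · excursion_d(t)` over the six DoF
  directions, multiplied by a unit-variance 20–350 Hz Gaussian carrier at
  2048 Hz. The default gain matrix is a smooth circular tuning of the
  seven channels around the forearm (von-Mises-like, rank 6), so the
  direction excursions are linearly recoverable from the envelopes. A
  `"deterministic"` carrier (fixed multi-sine in the same band) removes
  carrier stochasticity for noise-free end-to-end checks. Motor-unit
  physiology, fatigue and soft-tissue artifacts are deliberately not
  modelled: the pipeline only consumes windowed envelope/spectrum
  statistics, so envelope realism is what matters for exercising it.
* **The arm-position effect** is a per-position multiplicative channel
  gain vector (log-normal, σ_g on the log scale) plus a small additive
  baseline shift — a parametric stand-in for electrode–muscle geometry
  changes. σ_g = 0 is the null (positions statistically identical);
  σ_g = 0.3 is the package's "moderate effect" reference condition. The
  true magnitude of the effect in human data is not identifiable from
  published summaries, so the synthetic defaults are calibrated only to
  reproduce the qualitative orderings (intra > inter; pooling helps),
  never any particular published percentage.
* Both sides share one angle trace (the mirrored-movement idealization);
  an "amputee" session flag blends each channel's direction tuning
  toward the across-channel mean on the control side, emulating the
  reduced channel specificity of a residual limb.

What passing tests on this generator do show: the pipeline's geometry,
features, alignment, training and scoring are correct, leak-free and
seed-deterministic, and the evaluation grid responds to a
position-dependent EMG change in the direction the method predicts. What
they cannot show: performance levels on real muscle activity, real
electrode placement variability, or real marker artifacts.

## Problem sizes used by the packaged checks

The protocol's session (3 × 7 runs, 5 folds, all scenarios, pooled
training) is simulated with 30 s runs for the packaged end-to-end checks
and the acceptance script — about 750 analysis windows per run, ≈180
MLP fits for the full grid — which keeps a complete run at desk scale
while leaving every structural parameter (rates, window geometry, folds,
hidden units) at its study value. The geometry round-trip checks use the
full 65 s traces. `duration_s = 65` remains the generator default.

## Worked example

```{r example, eval = FALSE}
library(wristemg)

cfg <- with_position_effect(emg_synth_config(), sigma_g = 0.3, seed = 101)
ses <- simulate_session(master_seed = 7, duration_s = 30, config = cfg)
res <- run_pipeline(ses, seed = 5, out_dir = "results")

res$summary          # intra vs inter R^2 per scenario (percent)
res$position_matrix  # normalized 3x3 generalization matrix
res$pooling          # pooled vs single-position training, paired t test
autoplot(res)
```

## Known limitations

* The EMG model is phenomenological; none of its parameters are fitted
  to human recordings, and absolute R² levels on synthetic sessions are
  not comparable to levels on human data.
* Only integer resampling ratios are supported (2048 → 1024 → from
  256 Hz covers the protocol).
* The per-subject statistical layer (two-way ANOVA over subject groups,
  post-hoc comparisons) is outside the package; it consumes the tables
  the pipeline emits.
* `atan`-based angles saturate at ±90°; poses outside the stated DoF
  ranges are clipped, not unwrapped.
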