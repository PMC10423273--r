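---
title: "Decoding reaching goals from hand kinematics in the double-step paradigm"
author: "doublestep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding reaching goals from hand kinematics in the double-step paradigm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a double-step reaching task a participant reaches for a target that may
jump to a nearby location during the movement, either sideways (a *direction*
or horizontal shift) or nearer/farther along the line of sight (a *depth* or
sagittal shift). The hand then has to be corrected online. Two questions
drive the analyses in this package:

1. **When** during the movement does the hand's past kinematics contain
   enough information to predict the *final* reaching goal, and how is that
   timing affected by a mid-movement target shift, by the shift's dimension
   (direction vs. depth), and by the shift's latency (at movement onset vs.
   100 ms later)?
2. How far into the future can the *intermediate trajectory itself* be
   predicted from a short window of past kinematics?

Both questions are answered with sliding-window decoding: a recurrent neural
network reads a short chunk of fingertip and wrist positions and outputs
either a goal classification or the kinematic state a fixed fraction of the
movement ahead.

Because the motion-capture recordings that motivated this design are not
publicly deposited, the package ships a first-class synthetic-data module
that reproduces the task's geometry, timing and correction dynamics. Every
analysis stage is exercised and tested against that simulator.

## The task and its simulator

### Geometry

`target_layout()` builds the 12-target workspace: a central fixation point,
four static targets 8 cm away on the cardinal axes (left/right along x,
near/far along y), and eight shifted targets, two per static parent,
displaced 2.4 cm along the parent's dimension. Coordinates are centimetres
on the touchscreen plane; x is rightward, y is away from the body, z is up.

### Trial generation

`simulate_trial()` composes each reach from interpretable pieces:

* **Primary movement.** A minimum-jerk reach (fifth-order polynomial with
  zero endpoint velocity and acceleration — the standard smoothest-path
  model of point-to-point reaching) from a jittered start position in front
  of the body to the initially cued target, plus a sinusoidal vertical lift
  arc.
* **Online correction.** In shifted trials the target jumps
  `shift_latency_ms` after movement onset (0 ms for Experiment 1, 100 ms
  for Experiment 2). After a dimension-specific correction latency a
  *second* minimum-jerk submovement covering the 2.4 cm displacement is
  superposed on the primary one, completing at touch. Superposition rather
  than re-planning is the standard model of double-step corrections and
  produces the smooth lateral-velocity divergence seen empirically.
* **Failures to correct.** Sagittal shifts in Experiment 2 are never
  corrected (`p_no_correction_sagittal = 1` in that preset), emulating the
  empirical absence of detectable depth corrections at the later shift
  latency; a drawn latency that leaves no movement time also aborts the
  correction. Uncorrected reaches land on the *initial* target, so their
  endpoint error is approximately the 2.4 cm shift distance.
* **Measurement model.** I.i.d. Gaussian noise per sample on every marker
  coordinate; the wrist is the fingertip plus a rigid offset plus
  independent noise; the recorded touch point is the planned endpoint plus
  endpoint scatter.

`simulate_session()` draws 120 trials by default — 60 static, 60 shifted,
balanced over the four static parents, in seeded random order. Shifted
trials within a parent split as evenly as possible between its two children
(8/7 when the share is odd, with the extra child alternating across
parents).

### Parameters, units, defaults

| parameter | default | why |
|---|---|---|
| `shift_latency_ms` | 0 / 100 | the two experimental conditions |
| movement duration | 630 ± 60 ms, min 400 | back-computed from the reported 63% ≈ 396 ms time point (396.18/0.63 ≈ 629 ms); durations themselves are not published |
| reaction time | 350 ± 50 ms, min 150 | typical visually guided reach RT; free parameter of the simulator |
| correction latency, horizontal | 195 ± 25 ms (Exp 1), 140 ± 25 (Exp 2) | matches the reported lateral-velocity deviation times (~196/193 and ~144/133 ms) |
| correction latency, sagittal | 290 ± 25 ms | between the reported ~357 and ~229 ms depth deviation times |
| `p_no_correction_sagittal` | 0 (Exp 1), 1 (Exp 2) | no depth corrections detectable at the 100 ms shift latency |
| `position_noise_sd_cm` | 0.05 | motion-capture marker noise scale |
| `endpoint_sd_cm` | 0.4 | touch scatter producing realistic endpoint errors |
| `start_jitter_sd_cm` | 0.3 | trial-to-trial posture variability; guarantees pre-movement kinematics carry no goal information |
| `lift_height_cm` | 3 | vertical reach arc |

The latency spread (25 ms), noise scales, start position and lift height are
the simulator's own choices of realistic magnitudes: the underlying study
reports none of them. They were fixed once from motor-control common sense
and are exposed as `sim_params()` fields, not tuned to any analysis outcome.

### What the simulator does and does not emulate

It reproduces the geometry, the trial mix, event timing, dimension-specific
correction dynamics, correction failures, and a plausible measurement model.
It does **not** model biomechanics (muscle dynamics, joint constraints),
curved or obstacle-avoiding paths, movement segmentation pauses, eye
movements, or touchscreen digitization beyond endpoint scatter. Kinematic
classes in the simulator are cleaner than in real data, so decoding
accuracies on synthetic sessions are upper bounds: passing tests show the
*pipeline* is correct and calibrated, not that real hands are equally
decodable.

## Kinematic analyses

* **Deviation (correction) time.** `lateral_velocity()` differentiates the
  fingertip's x coordinate by central differences;
  `detect_deviation_time()` compares two groups of traces (e.g. reaches
  corrected leftward vs. rightward) sample-by-sample with a two-tailed
  Welch t-test and reports the first sample at or after the target shift
  that begins a run of at least `run_length = 10` consecutive significant
  samples (100 ms of sustained separation; `run_length = 1` reproduces the
  bare first-significant-sample criterion, since it is not documented
  whether sustained significance was required). Differentiation amplifies
  marker noise by √2/Δt (≈ 3.5 cm/s here), which systematically delays the
  first significant sample while the corrective velocity is still growing
  from zero; the deviation analyses therefore smooth the velocity with a
  50 ms centred moving average first (`velocity_smooth_window = 5` in
  `run_config()`). Fifty milliseconds is far below the 100–300 ms latency
  scales being estimated; with it, injected mean latencies of 150/200/300 ms
  are recovered within ±30 ms. The raw `lateral_velocity()` accessor leaves
  smoothing off by default.
* **Endpoint accuracy.** `endpoint_error()` is the planar Euclidean
  distance √((x_M−x_loc)² + (y_M−y_loc)²) between touch point and target.
* **Reaction time** is cue-to-onset; **trajectory variability**
  (`peak_velocity_variability()`) is the across-trial SD of the x or y
  coordinate at each trial's moment of peak 3D speed.
* Group comparisons use Welch t-tests with explicit Bonferroni thresholds
  (`corrected_two_sample_test()`; α/2 = 0.025, α/4 = 0.0125 for the 2- and
  4-comparison families).

Trials of unequal length are aligned on the shift (shifted trials) or onset
(static trials) and truncated to the common time range — no imputation.

## Goal and trajectory decoding

### Data representation

Each trial's movement segment (onset to touch) is resampled by linear
interpolation to 100 time steps of normalized movement time
(`normalize_trial()`), giving a 100 × 6 matrix of features
(fingertip x, y, z; wrist x, y, z). Sliding windows of T = 8 consecutive
steps form the decoder's input chunks: stride 4 during training (24 chunks
per trial, cheaper), stride 1 during inference (93 chunks, full time
resolution). A chunk is plotted at its *last* sample, so "% of movement" =
end_index/99.

### The network

`gru_fit()` implements the decoder from scratch (RcppArmadillo backend): a
single hidden layer of gated recurrent units (100 by default) reading the
chunk step by step, then a dense head — softmax over classes for
classification (categorical cross-entropy), linear with 6 units for
trajectory regression (mean squared error). Training uses Adam (learning
rate 0.001, batch size 32), full backpropagation through time, Glorot/
orthogonal initialization, and early stopping on a held-out 20% validation
split (stratified for classifiers) with best-weight restoration. All
randomness flows through R's RNG, so any seed reproduces a fit bit for bit.
Per-feature z-scoring is fitted on training data only (default on; exposed
as `standardize`).

The default epoch cap is 500 with patience 50 — a desk-scale setting under
which the synthetic problems are near-converged; a full-scale run would use
up to 10000 epochs with patience 500. One network is trained per fold on
chunks pooled across all window positions (default); a per-window mode
(`mode = "per_window"`) that fits a separate network at each training
window position is available but much more expensive and not the default,
since a single reported architecture evaluated along time matches the
pooled reading.

### Cross-validation and problems

`decode_goals()` runs stratified five-fold cross-validation *at the trial
level*: all chunks of a trial stay on one side of every fold, so chunk-level
leakage is structurally impossible (and tested). On a 60-trial two-class
problem each fold trains on 48 trials and tests on 12, balanced across
classes. Problems per dimension: the static pair, each static target's pair
of shifted children, and the 6-way problem over all endpoints of the
dimension (chance 1/2 and 1/6 ≈ 0.16). The composition of the shifted-pair
problems (the two children of one static target) is the reading most
consistent with the task geometry.

`permute_labels = TRUE` turns a run into a permutation null: the *training*
labels are permuted within each fold while test labels stay intact, which
makes the expected accuracy exactly the chance level. Permuting all labels
before the fold split is deliberately not offered as a null — a classifier
can then learn each kinematic cluster's plurality permuted label and score
well above 1/n (about 0.24 on a six-way problem here), which mimics decoding
where there is none.

`decode_trajectory()` trains regressors mapping a chunk to the 6 feature
values `offset` ∈ {4, 6, 8, 10, 12, 20, 30} normalized steps ahead, per
target cluster (a static target and its two shifted children); chunks whose
future sample falls beyond the trial are dropped. R² is computed per
component, pooled over all held-out chunks, and averaged across folds;
fingertip x, y, z are the headline components, wrist components are in the
full output.

## Time-resolved statistics

* **Curve comparisons.** `hotelling_curve_test()` computes a per-node
  two-sample Hotelling T² (for these univariate accuracy curves, the squared
  pooled-variance t) and controls the family-wise error over all nodes with
  the permutation distribution of the maximum statistic (seeded label
  permutations). Max-statistic permutation was chosen over random-field
  theory because it is assumption-light and its calibration is directly
  testable: under a simulated null its family-wise error sits near the
  nominal 5%. Supra-threshold runs are reported as intervals in % of
  movement at node resolution.
* **Chance crossings.** `chance_crossing_time()` reports the first node
  starting a run of ≥ 3 nodes strictly above the chance level (the run
  requirement suppresses single-node flickers; 1 restores the bare
  definition).
* **Confidence ellipses.** `confidence_ellipse()` eigendecomposes the
  sample covariance of per-participant crossing-time pairs; semi-axes are
  scaled by √χ²₂(0.95) so the ellipse covers 95% of a bivariate normal
  population. Because the source description of the ellipse *area* is
  ambiguous ("standard deviations σx and σy"), both the χ²-scaled area
  (`area`, default) and the one-sigma area (`area_sigma`) are returned.
* **Distribution comparisons.** `compare_r2_distributions()` is the
  two-sample Kolmogorov–Smirnov test on pooled R² values.

## Numerical choices and degenerate inputs

* Velocity at segment edges uses one-sided differences; interior samples
  central differences.
* Deviation search only considers samples at or after the alignment zero;
  groups on different sampling rates are rejected, unequal durations are
  truncated to the common range.
* Collinear point clouds yield a flagged degenerate ellipse (λ₂ = 0, zero
  area) rather than an error; constant features get unit scale in the
  z-scorer; constant regression targets give R² = 1 only for exact
  prediction.
* Classification ties in `predict()` resolve to the first class
  (deterministic).
* Session files round-trip positions to 6 decimals (CSV); events and labels
  exactly (JSON sidecar).

## Problem sizes used by the tests and the acceptance script

The shipped test-suite and `scripts/acceptance.R` run everything at desk
scale, chosen so a single CPU completes the whole suite in minutes while
every check remains statistically meaningful: networks of 16–24 units,
epoch caps of 60–400 with early stopping (the synthetic problems are either
easy or at chance, so convergence is quick), 10 seeded sessions for
chance-level checks, 12 simulated participants for the static-goal
reproduction, 500 null replicates for the family-wise-error calibration,
and 10⁴-point Monte Carlo for ellipse coverage. The near-converged settings
(units 24, epochs 400) are used where the *trend* across offsets matters,
because an underfit network's R² profile reflects optimization noise rather
than the task.

## Known limitations

* Simulated kinematic classes are cleaner than real data; absolute
  accuracies are optimistic upper bounds, and published significant-interval
  endpoints (which depend on the real recordings) are only qualitatively
  reproducible.
* The GRU is intentionally small and single-architecture; no hyperparameter
  search is provided.
* The deviation-time estimator inherits the bias/variance trade-off of its
  smoothing window; window widths approaching the latency differences of
  interest would blur them.
* Sessions are modeled as exchangeable trials: no fatigue, learning, or
  sequential effects.
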