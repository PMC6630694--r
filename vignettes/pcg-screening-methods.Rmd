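---
title: "Methods: heart-sound screening with pcgscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-sound screening with pcgscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgscreen)
```

## The problem

Auscultation screens for structural heart disease by listening for the two
normal heart sounds — S1 (mitral/tricuspid closure, 50–60 Hz) and S2
(aortic/pulmonic closure, 80–90 Hz) — and for abnormal additions: the
low-pitched S3/S4 gallops (20–30 Hz) and turbulent-flow murmurs whose
energy reaches well above the normal sounds, notably into 300–600 Hz.
`pcgscreen` implements the decision-making half of a digital-stethoscope
system: given a mono phonocardiogram at 2000 Hz it segments heart cycles,
extracts a 27-value feature vector per cycle, and classifies each cycle
(and, by majority vote, each record or 10 s stream buffer) as normal or
abnormal. Because this is a screening task with asymmetric consequences —
a missed abnormality is far worse than a false alarm — misclassification
costs are asymmetric by default (10:1).

## The synthetic phantom

Every stage is testable without external data through a seeded generator
(`generate_pcg`). Design choices, fixed once:

* **Heart sounds** are Gaussian-windowed sinusoids. S1: centre frequency
  55 Hz (configurable in 50–60), σ = 12.5 ms (≈ 50 ms burst), amplitude
  1.0. S2: 85 Hz (80–90), σ = 10 ms, amplitude 0.6. The amplitude ordering
  makes S1 the dominant peak, which the segmenter relies on.
* **Timing.** S1 period is 60/HR seconds with a small uniform jitter
  (default ±10 ms). Systole (S1→S2 spacing) is 0.3 s at 60 bpm and scales
  linearly with the cycle length. Optional S3 follows S2 by 0.1–0.2 s and
  S4 leads the next S1 by 0.07–0.1 s, both at 25 Hz.
* **Murmur** (abnormal records only): white noise band-passed to
  300–600 Hz, windowed over each systole with a raised-cosine, scaled so
  heart-sound power exceeds murmur power by `murmur_snr_db` (default 5 dB).
  This reproduces the key discriminative fact — normal records have
  essentially no spectral peaks above 300 Hz, abnormal ones do — without
  claiming any specific pathology.
* **Noise and drift.** White Gaussian noise at `noise_snr_db` (default
  25 dB; the segmentation stress tests run at 10 dB) and baseline drift
  modelled as a 0.4 Hz sinusoid plus a slow random walk.
* **Sensor chain** (`apply_sensor_chain`): pre-amplifier gain 11 v/v, a
  zero-phase Butterworth stand-in for the 20–600 Hz analog band-limit, and
  10-bit ADC quantization over a 3.0 V reference — a 2.93 mV step
  (`3.0 / 2^10`). Signal amplitude is interpreted relative to converter
  full scale, so the normalized step is `2 / 2^10`; overdriven samples
  saturate with a warning.

What the phantom does **not** emulate: real murmur taxonomy (systolic vs
diastolic grading, shapes), inter-patient variability of S1/S2 morphology,
sensor placement effects, friction/ambient artefacts, arrhythmic beat-to-
beat variability beyond the small timing jitter. Passing tests on the
phantom therefore demonstrate the pipeline's mechanics and its stated
invariants, not clinical performance on real recordings.

The power-budget helper follows the battery-life formula
`capacity / current × 0.70` literally; a 300 mAh cell at the measured
1.48 mA average current gives ≈ 142 h. At the 7.18 mA worst case the same
formula evaluates to 29.25 h (41.8 h without the derating factor); the
estimator reports the derated value.

## Pre-processing

Fixed composition: spike removal → baseline correction → band-pass.

* **Band-pass:** sixth-order Butterworth, 20–600 Hz at 2000 Hz. "Sixth
  order" is read as the total band-pass order (order-3 low/high
  prototypes); the constructor exposes `order` so the alternative reading
  is one argument away. Filtering is zero-phase (forward–backward), since
  a causal IIR pass would delay S1 peaks by several milliseconds and bias
  segmentation.
* **Spike removal:** samples deviating from the median by more than 8
  median absolute deviations are replaced by linear interpolation of the
  flanking clean samples. A constant record (MAD = 0) passes through.
* **Baseline correction:** 2 Hz second-order zero-phase high-pass, below
  the 20 Hz band edge. The mean is removed before filtering so constant
  offsets vanish exactly instead of leaving edge transients.

All operators are length-preserving and deterministic; swapping the last
two stages changes outputs by under 5% RMS on synthetic fixtures.

## Segmentation

The envelope is the normalized average Shannon energy: per 20 ms frame
(5 ms hop), `-1/N Σ x² log x²`, smoothed with a short moving average and
scaled to maximum 1. One numerical subtlety: `-x² log x²` is increasing
only for |x| < 1/√e ≈ 0.61, so a full-scale S1 would be *compressed below*
a 0.6-amplitude S2. The signal is therefore mapped to half range (peak at
0.5) before the transform, keeping the envelope monotone in burst
amplitude and preserving S1 dominance.

S1 candidates are local envelope maxima above 0.2 of the global maximum.
Candidates closer together than the refractory spacing `60 / hr_max`
(default hr bounds 40–180 bpm) are resolved greedily in favour of the
larger envelope value — the S1-dominance assumption. Cycles span
`[s1_i − offset, s1_{i+1} − offset)` with a 50 ms pre-offset so each cycle
contains the start of its S1 and the end of its S2; the offset and the
physiological duration bounds (0.3–2.0 s, outside which cycles are
dropped) are configurable, and starts are clamped at the record edge.
Indices are 0-based with half-open intervals throughout.

On the phantom, across seeds 1–20 and heart rates {50, 60, 90, 120} bpm at
10 dB noise SNR, every annotated S1 is recovered within ±20 ms (the test
requires ≥ 95%).

## Features

27 values per cycle in a fixed canonical order; all choices below are
config-exposed (`feature_config`):

* **Percentiles** use linear interpolation between order statistics
  (R type 7) — the index-formula definition of quartiles is ambiguous for
  non-integer positions, so the rule is declared once.
* **Shannon entropy** needs a probability model for continuous amplitudes:
  a 32-bin histogram over the cycle's min–max range, log base 2.
* **Moments.** The standard deviation uses the n−1 denominator; skewness
  and kurtosis divide by N·s³ and N·s⁴ with that s, and kurtosis is excess
  (−3). For a constant cycle they are defined as 0, so classifiers never
  see non-finite values.
* **Spectral features** come from the one-sided periodogram of the whole
  cycle with DC excluded (band-passed cycles are zero-mean; excluding DC
  makes `f_max` meaningful regardless). The energy-ratio half-window Δf
  defaults to 10 Hz.
* **MFCCs:** pre-emphasis `x[n] − 0.95 x[n−1]`, 25 ms Hamming frames at
  10 ms hop (a whole-cycle single-frame mode is a switch), power FFT,
  26 triangular mel filters over 20–600 Hz, log energies floored at
  machine epsilon, orthonormal DCT-II, coefficients 1–13 (the 0th, a pure
  loudness term, is excluded — hence the retained coefficients are
  amplitude-scale invariant), averaged across frames.

Each statistic is verified against a straight-line reimplementation
(explicit loops) to 1e-8 in the test suite.

## Feature selection

NCA learns one non-negative weight per feature by maximizing a softmax
leave-one-out objective: point *i* picks neighbour *j* with probability
`p_ij ∝ exp(−d_ij)`, `d_ij = Σ_r w_r (x_ir − x_jr)²`, and the objective is
the mean probability of picking a same-class neighbour minus `λ Σ w_r`.
Weights are parameterized as the square of a free vector (non-negativity
by construction); optimization is gradient ascent with an adaptive step
that only accepts improving moves, so the recorded loss trace is monotone.
λ defaults to 1/n. The analytic gradient is checked against central
differences to 1e-5.

Independently of NCA, the package ships the fixed 15-feature reduced
preset — kurtosis, f_max, and all 13 MFCCs — as
`reduced_feature_preset()`; it is the reproducible anchor for reduced-
feature experiments, while NCA itself is validated by recovery and
equivariance properties (an informative feature's weight exceeds a noise
feature's by >10× across seeds).

## Classification and costs

* **Presets.** "Fine" KNN is k = 1, euclidean, unweighted; "weighted" KNN
  is k = 10, euclidean, inverse-squared-distance votes. Features are
  z-scored with parameters learned from the training data only (a declared
  convention — distance methods require one).
* **Costs enter at decision time**, not through resampling: the label is
  the argmin of expected cost over the posterior estimate, which for costs
  (cost_fn, cost_fp) = (10, 1) means predicting abnormal whenever
  p(abnormal) > 1/11. This leaves KNN training untouched and makes the
  sensitivity/specificity trade-off a pure threshold movement — raising
  cost_fn can never lower sensitivity on a fixed model. Exact ties go to
  normal.
* **Subspace ensemble:** n base learners (default 30) on seeded random
  feature subsets (default half the features), mean posterior. The
  discriminant base is a pooled-covariance linear discriminant,
  ridge-regularized when the within-class covariance is singular; a KNN
  base is available because metric/k tuning only makes sense for that
  variant.
* **Validation:** stratified 5-fold CV; standardization and any in-fold
  NCA selection are fitted inside each training fold (no leakage; the test
  suite re-derives fold models independently). Per-fold confusion matrices
  are summed and metrics are computed on the pooled matrix and per fold.
  Hyper-parameter search is an exhaustive grid over
  {euclidean, cityblock, chebyshev, cosine} × k ∈ 1..30 minimizing pooled
  expected cost, ties to smaller k then metric order.
* **Granularity:** metrics are per cycle; a record (or stream buffer)
  label is the majority vote over its cycles, with ties resolved
  alphabetically (abnormal first) and bufferless spans reported as
  indeterminate.

## Metrics

All eight statistics come from the pooled confusion matrix with abnormal
as the positive class: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
FPR = 1 − specificity, precision TP/(TP+FP), F-score (harmonic mean),
accuracy (TP+TN)/(P+N), error = 1 − accuracy, and
MCC = (TP·TN − FP·FN)/√((TP+FP)·P·N·(TN+FN)). Undefined ratios are
reported as NaN with a warning, never silently 0.

## Problem sizes

The shipped tests and examples run at desk scale by design: records of
5–10 s, datasets of 12–80 records (roughly 100–700 cycles), NCA fixtures
of n = 200, and 20-seed × 4-rate segmentation sweeps. These sizes are
large enough to exercise every invariant while keeping the whole suite in
well under a minute of compute per module.

## Known limitations

* The phantom's separability (5 dB murmur SNR) makes end-to-end accuracy
  near-perfect; real-corpus performance is a different question the
  package does not claim to answer.
* Segmentation assumes S1 dominance; recordings where S2 exceeds S1 (some
  pulmonary hypertension presentations) or with severe arrhythmia would
  need the four-state segmentation approaches deliberately left out.
* The streaming mode processes disjoint 10 s buffers with no cross-buffer
  state; cycles straddling a buffer boundary are lost.
* KNN stores its training set; for corpus-scale data a tree or
  approximate-neighbour backend would be needed.
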