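---
title: "Methods: signal model, pipeline design and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal model, pipeline design and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`threadmotion` implements a processing chain that turns two raw impedance
time series — from a pair of strain-sensing threads crossed on the back of
the neck — into a stream of head-orientation labels. This vignette
documents the signal model the package assumes, the reasoning behind each
tunable parameter, what the synthetic-data generator does and does not
emulate, and the numerical conventions adopted where the design was
genuinely open.

## Signal model

The wearer's head pose at any instant maps to a *normalized level*
per channel in [−1, 1]: 0 is the settled front-facing value, +1 the
impedance at the stretch limit of the range of motion, −1 at the
relaxation limit. Raw impedance is an asymmetric piecewise-linear function
of level,

$$x = b + \ell\,s_+ \ (\ell \ge 0), \qquad x = b + \ell\,s_- \ (\ell < 0),$$

with baseline $b$ and positive/negative spans $s_+ > s_-$: a thread's
impedance changes more under stretch than under relaxation, which is why
the pipeline normalizes the two sides separately. Horizontal motion drives
the two channels in opposite directions (anti-correlated); vertical motion
drives them together (correlated). The two settled-level orderings are
encoded in `default_orientation_profiles()`; the horizontal levels sit
inside the per-orientation segment-mean bands observed for this sensor
layout, while the vertical levels are a design choice constrained only by
monotonicity from `down` to `up` (no published bands exist for that axis),
with a small channel asymmetry to mimic imperfect thread matching.

## What the generator emulates

`generate_recording()` executes a motion script (targets, dwell times,
transition times) against the level profiles:

* **Transitions** follow a raised-cosine path (smooth, zero end
  velocity). A front-to-extreme traversal is routed *through* the
  intermediate orientation's level at its midpoint, so the intermediate
  band of the path matches the intermediate profile rather than a straight
  interpolation.
* **Intermediate labels.** Samples in the central 60 % of a
  front-to-extreme traversal are labeled with the intermediate
  orientation (band width exposed as `intermediate_band`); the outer 20 %
  tails keep the endpoint labels. Intermediate-labeled spans therefore
  carry steep slopes and large within-window ranges — the defining
  property of those classes. Directly adjacent pairs switch labels at the
  midpoint.
* **Stochastic components**, all drawn from one seeded generator per
  call: white read-out noise (`noise_sd`, default 5 a.u. ≈ 2.5 % of the
  stretch span); a slow linear drift (`drift_rate`, default 0.02 a.u./s —
  visible over minutes, consistent with the need for periodic
  recalibration of resistive threads); Poisson-timed persistent step
  offsets emulating spontaneous motion of the unsecured thread middles
  (`jump_prob` 0.02/s, `jump_sd` 1.5 a.u.); per-dwell level jitter, since
  a person never repeats a pose exactly (`level_jitter_sd` 0.04); and a
  slow *common-mode* micromotion shared by both channels
  (`micro_sd` 0.01, smoothed over 250 samples) representing involuntary
  posture sway. Common-mode sway is what makes settled dwells on *both*
  axes positively correlated while horizontal transitions stay strongly
  anti-correlated, matching the observed correlation structure.
  Instantaneous levels are clamped to [−1, 1]: the calibrated extremes
  are by definition the physical stops of the range of motion, and sway
  cannot push the head past them.

The generator does **not** model the electromechanics of a carbon-coated
thread (resistance hysteresis, cyclic fatigue, temperature or humidity
effects), inter-subject anatomical variation, sensor placement error, or
off-axis/diagonal head poses. Passing tests therefore demonstrate that the
pipeline is correct and that the *claimed signal structure* is sufficient
for accurate classification — not that a particular human recording would
reach the same accuracy.

`generate_calibration_recording()` emulates the calibration protocol:
starting front-facing, excursions to each of the four extremes (at full
range, levels ±1) with settled front dwells between them, repeated three
times. Excursions carry no per-dwell jitter — the range-of-motion stop is
a repeatable physical limit. The generating parameters are attached as
`ground_truth` for recovery experiments.

## Calibration

Per channel, after the same moving-average filter used downstream:

* **Plateaus** are maximal runs (≥ `min_dwell_s`, default 1 s) where a
  centred rolling standard deviation (window 0.25 s) stays below 1 % of
  the filtered signal's observed range. Relative thresholds make
  calibration commute with shifting or rescaling the raw units, so the
  estimators are unit-agnostic. Plateau means are computed after trimming
  one flatness window from each edge, excluding the filter's settling
  transient (this is what makes noiseless recovery exact rather than
  approximate).
* **Baseline**: plateau means are clustered in one dimension by splitting
  at gaps larger than 25 % of their spread; the cluster with the most
  plateaus is the front level (the protocol returns to front after every
  excursion, so front dwells are the most frequent), and the baseline is
  the median of its plateau means — robust to the occasional jump-shifted
  dwell.
* **Extremes** are the global min/max of the *filtered* signal. Filtering
  first protects against single-sample spikes; the alternative (raw
  extremes) would be biased upward by noise peaks.

Recovery performance under the default noise model (20 seeds): baseline
within 2 % of the stretch span, extremes within 5 %; exact in the
noiseless limit. Residual error is dominated by drift and by spontaneous
jumps, which genuinely move the settled value — an irreducible ambiguity
that periodic recalibration addresses in practice.

## Filtering, normalization, segmentation

* The moving average is **causal** (trailing) with a growing window
  during warm-up: output length equals input length without inventing
  padding values, and no future samples are needed — the pipeline targets
  near-real-time use. The default length is 120 samples at 1 kHz.
* Normalization maps {min, baseline, max} to {−1, 0, +1} exactly, is
  strictly increasing and continuous, and does **not** clip outside
  [−1, 1]: the calibration extremes are empirical and can be exceeded
  (drift, jumps), and clipping would destroy information used by the
  range feature. Out-of-range samples are counted and reported.
* Windows are 550 samples (0.55 s) with 250 samples of overlap
  (hop 300), indexed 0-based and half-open. The window must be long
  enough to capture a transition's ramp, to cover the settled spans of
  extreme poses, and to average over the threads' fast internal dynamics;
  a trailing partial window is discarded. Segment labels are the majority
  of the per-sample labels, with ties going to the window's centre
  sample — a surrogate for manual video-based labeling, which provides no
  rule of its own.

## Features and classifiers

Each segment yields six predictors, in fixed order:
(μ_/, μ_\\, Δμ = μ_/ − μ_\\, ρ, δ_/, δ_\\). Fixing the order makes model
files and reports reproducible; the Gaussian-kernel SVM's kernel scale is
√p = √6 ≈ 2.4 by construction. A zero-variance window has undefined
Pearson correlation; the package returns 0, the neutral
"no linear relationship" value.

The nine configurations mirror a standard desktop toolkit's presets, and
the quantities that toolkit leaves implicit are resolved here as follows
(all exposed as arguments):

* SVMs: box constraint C = 1, polynomial kernels of degree 2 and 3 with
  unit scale and offset, one-vs-one multiclass reduction.
* KNN: k = 10 for all three variants; cosine distance
  (1 − cosine similarity), cubic Minkowski distance (exponent 3), and
  Euclidean distance with 1/d² vote weights.
* Kernel naive Bayes: per-class, per-feature Gaussian kernel densities
  with normal-reference (Silverman) bandwidths; a degenerate bandwidth
  falls back to 10⁻³ of the feature's global standard deviation.
* Features are standardized with training-split statistics (stored in the
  model, re-applied at prediction) before every SVM and KNN fit: the
  predictors mix [−1, 1] means with [0, ~2] ranges, and distance-based
  methods need comparable scales. Predictions are consequently invariant
  to affine rescaling of any feature column.

Numerical conventions for KNN, shared by the production path and the
brute-force reference oracle used to verify it: neighbours are ranked by
(distance, training index); vote ties go to the nearest neighbour holding
a tied label; a query coinciding with training points under 1/d²
weighting takes the majority label among the coincident points (avoiding
division by zero); zero-norm vectors under the cosine metric are assigned
distance 1 to everything.

## Evaluation protocol

`repeated_holdout()` runs 100 rounds; each round draws one simple random
split (train size = round(0.75·N)) **shared by all nine classifiers**, so
between-classifier comparisons are paired and lower-variance. Splits are
not stratified — matching plain random selection — but a split missing a
class is redrawn (and counted). Accuracies are reported both as the mean
of per-round accuracies (the headline number) and pooled over the
accumulated confusion matrix; with a fixed seed the entire evaluation is
bit-reproducible. `adjacency_error_fraction()` summarises error
structure: among misclassified segments, the fraction whose (true,
predicted) pair is adjacent along an axis; an error-free matrix returns 1
by convention, since it contains no non-adjacent errors either.

## Problem sizes

The replication experiment used throughout the tests and the acceptance
script runs the standard protocol — five repeats per axis with 2 s
extreme dwells, 1.8 s front dwells and 1.1 s transitions, 120.25 s at
1 kHz → exactly 400 segments — with a 3-round calibration session
(~52 s), followed by the full 100 × 9 evaluation; the whole chain takes
well under a minute on one core. Parameter-recovery experiments use 20
seeds; oracle-equivalence checks use 50 training points and 200 queries
per metric.

## Known limitations

* Orientation is quantised to nine positions on two axes; diagonal poses
  (e.g. up-left) are outside the model.
* Streaming classification treats each window independently; no temporal
  smoothing or tracking is applied, so isolated segment errors pass
  through unfiltered.
* Calibration is a one-shot procedure; long-session drift beyond the
  linear/jump model requires recalibration rather than online
  compensation.
* The windowing is fixed-scale; motions much faster or slower than the
  default protocol would warrant a different window length.
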