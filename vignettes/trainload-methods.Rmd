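---
title: "Methods: activity recognition, training efficiency and fatigue modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity recognition, training efficiency and fatigue modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trainload)
```

## Overview

`trainload` assesses a weightlifting training session from two data
sources: inertial streams logged by wrist-worn units on both wrists
(tri-axial acceleration, angular velocity and fused attitude angles at a
nominal 50 Hz) and a per-minute heart-rate series with a seated resting
baseline. The external-load side recognises which of four lift phases —
grip, lift-off, clean-and-jerk, set-down — the athlete is in at every
moment and converts phase durations into a training-efficiency score. The
internal-load side converts heart rate into a relative measure, maps it to
a perceived-exertion (Borg RPE 6–20) prediction through a linear fatigue
model, and rates the training load. The two three-level ratings cross into
a nine-state verdict with a management recommendation per state.

## Activity recognition

### Windowing

Both wrist streams are segmented jointly into fixed-length sliding windows
of 5 s advancing by half a window (50% overlap). Fixed-size overlapping
windows keep every feature vector comparable and give each lift phase —
phases last a few seconds — a good chance of dominating at least one
window; much longer windows would routinely mix phases. Windows are
half-open `[start, start + len)` on an elapsed-seconds clock, and the
window grid is computed on sample indices, so the window count equals the
closed form `floor((n - len·fs) / step) + 1` exactly and trailing samples
shorter than one window are dropped. When ground-truth labels are
available each window takes the activity code occupying the majority of
its span; exact ties go to the earlier-starting interval, a deterministic
rule chosen because no occupancy tie-break is canonical.

### Features

Each window is summarised per channel by six time-domain statistics —
mean, sample standard deviation (n−1), interquartile range (type-7
linear-interpolation quantiles), excess kurtosis, adjusted Fisher–Pearson
skewness, and a covariance feature — over a 12-channel subset, giving the
72-dimensional feature vector C = (c1, …, c72). Two interpretation choices
deserve explanation:

* **The covariance feature.** A per-channel "covariance" is ambiguous:
  cross-channel covariance would not preserve a 6-statistics × 12-channels
  layout. We define it as the lag-1 autocovariance of the channel within
  the window (about the window mean, denominator n−1), which measures
  short-range temporal smoothness and preserves the 72-dimensional count.
  A second reading, covariance of the sample with elapsed time (a trend
  measure), is selectable via `extract_features(covariance =
  "cov_with_time")`.
* **The 12-channel subset.** Each wrist logs nine channels but twelve feed
  the features. The default subset is both wrists × (acceleration +
  attitude angles), since phase differences express themselves mainly as
  acceleration and angle variation; an acceleration + gyroscope subset is
  equally defensible and can be passed explicitly.

Zero-variance windows would make skewness and kurtosis 0/0; they are
defined as 0 instead so feature vectors are always finite — classifiers
require finite inputs, and "no asymmetry measurable" is a reasonable
reading of a constant signal. Time-domain statistics only: spectral
features cost more to compute and the four phases already separate in the
time domain.

### Classifier and evaluation

A random forest maps feature vectors to phase codes: 500 trees, unlimited
depth, √p candidate features per split — standard forest defaults, all
exposed as arguments. Vote ties break to the lowest class code so
predictions are reproducible. Two evaluation protocols are provided:
repeated stratified hold-out (7:3 split, ten repeats, per-class metrics
from the confusion counts pooled across repeats — pooling is the stabler
convention when a single number per cell is wanted) and the
growing-database protocol (train on subjects 1..k pooled, predict the
rest, for k = 1..n−1), which probes how accuracy on unseen subjects
responds to a growing training base. Splits are stratified by class to
avoid degenerate splits on small sets; a split that still misses a class
is resampled a bounded number of times.

## Training efficiency

Lift-off and clean-and-jerk count as effective training, grip as
auxiliary, set-down as non-training. The effective training rate is

θ = Te / T,

effective time over total time. With 50% overlapping windows a naive
per-window sum would count most of the session twice, so each window
contributes the step duration (len × (1 − overlap)) to its predicted
phase and the final window contributes the full window length; the
per-phase times then sum exactly to the span the windows cover. A
consequence worth noting: because the final window alone carries the extra
(len − step) seconds, reordering window labels can move that small amount
between phases — total time is conserved under any reordering, and θ is
exactly reorder-invariant only for non-overlapping windows.

Efficiency is rated low below 35%, high above 55%, and medium on the
closed band [35%, 55%] — the boundary values belong to the middle band,
following the printed interval convention.

The four-phase scheme has no idle class, so inter-set rest in real
recordings is absorbed into the nearest phase unless a label track marks
gaps; this is a documented limitation of the 4-class decomposition.

## Fatigue model

Relative heart rate Hr = Hw / Hc (per-minute mean over resting baseline)
normalises out individual resting-rate differences. The fatigue model is
an ordinary-least-squares line from Hr to the Borg RPE score; the fitted
reference coefficients are slope 16.12343 and intercept −10.36787
(adjusted R² 0.973, F 219.73 in the original fit). Predictions are *not*
clipped to the Borg range: a predicted RPE above 20 flags significantly
intense training rather than being hidden, and the flag threshold is
crossed at Hr ≈ 1.8835. Load is rated low below Hr 1.33, high above 1.57,
medium on the closed band [1.33, 1.57]. The session-level rating is taken
at the mean exercise Hr by default — the model was built on averaged
indicators — with `max` and `final` aggregation available.

The underlying averaged (Hr, RPE) points are not public, so the printed
diagnostics cannot be recomputed from data; the fitting code is instead
verified against a direct-summation normal-equations oracle to ten
significant figures and by parameter recovery on simulated sessions.

## Nine-state assessment

The 3×3 cross of load level × efficiency level indexes a fixed
recommendation catalogue shipped as an editable CSV
(`inst/extdata/recommendations.csv`) so coaches can localise or extend the
texts; the shipped entries are the canonical ones. Note two states
deliberately share the text "The more ideal training state" — the
catalogue is keyed by state, not by text. Reports carry a
`report_version` field so downstream consumers can detect schema changes.

## Synthetic data generator

No public recording of the original sessions exists, so the package ships
a generator that emulates the statistical structure the pipeline assumes:

* **IMU signatures.** Per phase and channel group, a sinusoid plus offset
  (plus an intra-segment linear angle trend): grip near-static, lift-off
  and clean-and-jerk dynamic at different dominant frequencies (1.2 vs
  2.2 Hz), set-down mirroring lift-off with the angle trend inverted.
  Amplitudes are plausibility-driven — no quantitative per-phase
  kinematics are published — which is why classifier acceptance is
  property-based (separation ≫ noise ⇒ accuracy near 1; zero separation ⇒
  chance) rather than a reproduction of any printed accuracy table.
* **Schedule.** Default five sets of grip 8 s / lift-off 5 s /
  clean-and-jerk 7 s / set-down 5 s, back to back (no idle class exists,
  so no rest gaps by default); the fatigue-side experiments use more sets
  to reach a 30-minute session.
* **Heart rate.** Exponential approach from rest toward a plateau multiple
  of resting HR (default plateau 1.55, time constant 8 min) plus AR(1)
  noise. The defaults put the early-exercise (minute 4) relative HR at
  ≈1.22 and the 30-minute value at ≈1.54, inside the observed ranges
  1.21–1.42 and 1.46–1.64.
* **RPE.** The latent line is continuous; integer rounding and clipping to
  6–20 happen only at report time, at 5-minute marks, matching how the
  scale is administered.

What passing tests on this generator do **not** show: robustness to real
sensor artefacts (drop-outs, re-strapping, soft-tissue motion), to
between-day variability, or to lift techniques whose signatures differ
from the sinusoid family. The generator's job is to make the pipeline's
logic testable, not to certify field accuracy.

## Numerical and design choices

* Logs are plain CSV with an explicit declared sampling rate and an
  explicit rest/exercise segment column (explicit beats inferring rest
  from the first minutes); values are written with 17 significant digits
  so write→read round trips are bit-identical.
* A denoising stage exists but is the identity (`strategy = "none"`): the
  fixed-mount collection strategy makes additional filtering unnecessary,
  and keeping the stage explicit preserves the pipeline graph for future
  strategies.
* The classifier backend is intentionally behind a small surface
  (`train_activity_model` / `predict_activity`), so other learners could
  be swapped in; the random forest is the default and the only backend
  under test.
* Problem sizes in the test suite: single sessions of 2–16 sets
  (50 s–30 min), cohorts of up to 6 subjects, forests of 50–100 trees —
  sizes at which every property under test is already stable.

## Limitations

* Four-phase weightlifting only; no rep counting, no per-set efficiency.
* No idle/rest class (see above).
* The fatigue line is fit on session-averaged indicators; per-minute
  predictions inherit the averaged model.
* TRIMP- or HRV-style load indices are out of scope by design.
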