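---
title: "FrontalGait: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FrontalGait: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FrontalGait)
```

## The measurement model

A subject walks toward a fixed front-facing camera, turns, and walks
back. The silhouette bounding-box height `Sh_i` is then an indirect
but information-rich gait probe: it grows monotonically with the
approach (perspective), but in *spurts* — while the legs pass each
other the apparent height is constant, and at terminal stance / swing,
when the legs are maximally apart, the body advances and the height
steps up. One stride therefore contributes two rises, and the
staircase structure of `Sh_i` carries stride timing without any joint
tracking.

Three nuisance factors are removed before feature extraction:

* **stature** — `Sh_i` is divided by the face height `fh`, which is
  approximately a fixed fraction of body height;
* **camera placement** — min-max normalization to [0, 1];
* **detection jitter** — a centered 5-frame moving average followed by
  quantization into consecutive 5-frame partitions, each replaced by
  the mean of its points. At the standard 25 fps both spans are 0.2 s,
  which is comfortably below a stride (0.8–2 s) and above single-frame
  noise; the two defaults are kept equal on purpose so smoothing never
  blurs across more than one partition boundary.

The forward and backward walks are split at the first frame attaining
the global maximum (closest approach). Ties take the first occurrence
to keep the split deterministic.

## Gait events on the quantized staircase

Events are rises of the quantized signal. Two practical complications
arise, both from the same cause: a physical rise almost never lands
exactly on a partition boundary.

1. The partition containing the rise settles at an intermediate level,
   so one event is smeared over a short monotone chain of rising
   plateaus (sliver, partial, settled level).
2. Residual detection noise makes neighbouring partition means differ
   slightly, so a strict "any increase" rule would fire between true
   events.

`detectEvents` addresses the first by placing events at the
(non-strict) local maxima of the plateau-increment sequence within
each monotone rising chain: the partitions carrying the bulk of a rise
count, their leakage neighbours do not, and a regular staircase —
whose increments are all equal — keeps one event per rise. It
addresses the second with a minimum-rise threshold. The default
threshold is estimated per recording: the lower quartile of the
absolute increments is almost always noise (true steps are sparse
outliers there), `|N(0, s)|` has lower quartile `0.3186 s`, and the
threshold is three estimated standard deviations, bounded below by
0.01 of the normalized range and above by a quarter of the largest
increment so that clean signals are never thresholded away. A fixed
numeric threshold (including 0, the strict rule) can be supplied
instead.

Stance, swing and stride then follow from the event timestamps `Ts`:
consecutive intervals alternate stance / swing, strides are
non-overlapping stance+swing pairs (the odd-index stepping of the
stride recursion), and a trailing unpaired interval is dropped. Since
non-overlapping strides telescope, the mean stride time is robust to
the ±1 partition timing error of individual events.

## The five features

* **`S_avg`** (s) — mean stride time on the quantized *forward* walk;
  events are only meaningful on the approach, where height steps up.
* **`alpha`** — detrended fluctuation exponent of the normalized walk.
  The series is integrated about its mean, cut into non-overlapping
  boxes of size `l, 2l, …` up to a quarter of the series length (at
  least four box sizes are required; `l = 5`), each box detrended by
  its least-squares line, and the pooled RMS fluctuation regressed on
  box size in log–log coordinates. White noise gives about 0.5, 1/f
  structure about 1, Brownian-like signals about 1.5. With ordinary
  least squares over all scales the estimator carries the usual mild
  finite-size downward bias at the Brownian end; the validation
  bounds account for it.
* **`E`** — the amplitude sum `-Σ x log2 x` with `0·log 0 := 0`,
  applied to the normalized amplitudes exactly as defined — it is not
  a probability-distribution entropy, and it scales with recording
  length, which is itself severity-information (impaired walks are
  longer).
* **`A_delta_C`** (Hz) — mean *signed* difference of consecutive
  5-sample spectral centroids. As printed the sum telescopes to
  `(C_N - C_1)/N`, so the default feature is small for every signal
  and mostly reflects end effects; we keep it as defined for
  fidelity, and provide a mean absolute-difference variant behind
  `absCentroidDiff` for users who want the "variability" reading.
  Spectral magnitudes use the DFT of each box over the non-negative
  frequencies `i·fps/n` Hz; an all-zero box yields 0 Hz.
* **`T`** (s) — first-occurrence valley-to-peak time of the
  normalized walk, reported as an absolute value; effectively the
  forward-walk duration, the single strongest severity correlate.

`alpha`, `E`, `A_delta_C` and `T` are computed on the full normalized
walk by default (`featureSegment = "full"`); the forward-only variant
is available because the forward walk is where events live, but the
full walk retains the turn dwell, which is itself discriminative.

## Severity classification

The five features mix seconds, hertz and dimensionless quantities, so
they are standardized (per-feature center/scale, fitted on the
training split only — refitted inside every cross-validation fold) in
front of a distance-based kernel. The Pearson VII universal kernel

$$k(V_i, V_j) = \left[1 + \left(\frac{2\,\lVert V_i - V_j\rVert\,
\sqrt{2^{1/\omega}-1}}{\sigma}\right)^{2}\right]^{-\omega}$$

with tailing factor ω = 0.2 and half-width σ = 1.0 interpolates
between Gaussian-like and heavy-tailed shapes. Three binary
soft-margin SVMs (C = 1 by default; the quadratic program is solved by
kernlab on the precomputed gram matrix) discriminate each level
against the other two; prediction takes the class with the maximal
decision value, ties toward the lower level. Each machine's decision
sign is oriented on its own training fit, because the solver's sign
convention with respect to factor levels is not contractual.

Evaluation uses seeded stratified 10-fold cross-validation: every
sample is tested exactly once, per-fold accuracies are averaged, the
out-of-fold predictions pool into one confusion matrix, and per-class
ROC curves over the pooled decision scores give per-class AUCs whose
macro average is the headline number. The fold assignment and seed
are stored in the report so any run is reproducible from its outputs.
The Kruskal–Wallis screen (`rankFeatures`) reports the tie-corrected
H, chi-square p-value (df = levels − 1) and per-level mean ranks per
feature.

## The simulator: what it emulates, and what it does not

`simulateWalk` generates the staircase a front camera sees: rises at
half-stride intervals `1/(2·cadence)`, per-rise amplitude
`stepAmplitude`, both perturbed by multiplicative Gaussian jitter; a
festinating stride is replaced by three quick rises at 45% of the
normal interval and amplitude; a dwell at maximum height models the
turn; the descent mirrors the approach; Gaussian pixel noise is added
to the height; and the face height is `faceRatio ×` subject height
with proportionally scaled noise. Everything is deterministic given
(profile, fps, seed), and per-walk seeds in `simulateGaitDataset` are
drawn from the master seed and logged.

The class defaults encode the clinically reported contrasts — healthy
walks are fastest (cadence 1.1 strides/s, 8 px steps, 7 s forward,
0.8 s turn), level 1 slower and smaller with more jitter (0.8, 5 px,
10 s, 1.5 s), level 2 smallest and festinating (0.65, 3 px, 13 s,
2.5 s, festination probability 0.35, noise sd 2 px at a 250 px
subject). No quantitative clinical values are published for these
signals; the numbers are chosen once as plausible magnitudes and the
within-class ranges (±8% draws around the defaults) keep samples
distinct. Consequently the simulated classes are *cleaner* than
clinical ones: passing the end-to-end classification checks
demonstrates that the pipeline recovers the structure it is designed
for, not that clinical accuracy would reach the same level. Real
recordings add detector failures, occlusions, perspective distortion
of the face, clothing-dependent silhouettes and label noise that the
simulator deliberately leaves out.

The silhouette renderer draws a blocky human shape (narrow head,
full-width torso, two legs) on a light background, which the default
threshold-and-connected-components person detector and the head-block
face detector recover essentially exactly; both detectors sit behind a
plain `function(img)` interface so a pretrained pedestrian or face
detector can be substituted for real footage. Frame stacks are
multi-frame TIFFs or directories of image frames; containers carry no
frame-rate metadata, so fps is a configuration value (default 25).

## Numerical and degenerate-input conventions

* Stages are enforced (`raw → face_scaled → normalized → smoothed →
  quantized`); each operation rejects input at the wrong stage.
* Constant signals are degenerate for normalization, event detection,
  DFA and valley-to-peak time and raise errors; in batch mode a
  failing recording yields a flagged incomplete feature row that is
  excluded from training with a warning count, never an abort.
* Normalization pins its output to [0, 1] exactly (clamping the last
  bit of rounding); segments sliced from a normalized walk stay within
  [0, 1] but need not attain the extremes.
* Interior detection gaps are linearly interpolated, edge gaps held;
  missing faces fall back to the recording median face height
  (`fhPolicy = "frame"`), or the median can be used throughout
  (`"median"`, recommended when per-frame face size tracks camera
  distance, as with the renderer's sprites), or a constant supplied.
* Ties: the walk split and valley/peak use first occurrences;
  prediction ties go to the lower severity level; equal plateau
  increments each count as events.
* All randomness flows through explicit integer seeds, and the
  global RNG state is saved and restored around every seeded step.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen to exercise every code
path: DFA validation on series of length 600–2000 (10 seeds for the
1/f target), cadence recovery over 10 seeds across 0.5–1.2 strides/s,
end-to-end classification on 50 recordings per class with 10-fold
cross-validation plus a 10-seed label-permutation null, and rendered
round-trips on a few hundred 260×240 frames.
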