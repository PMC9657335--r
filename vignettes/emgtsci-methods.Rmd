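---
title: "Methods: simulation, conditioning and classification of pre/post-lesion EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, conditioning and classification of pre/post-lesion EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emgtsci)
```

This vignette documents the scientific and numerical choices behind
`emgtsci`: what the synthetic EMG generator emulates, how the
conditioning and classification stages are defined, which parameters
matter, and what the package's passing tests do and do not demonstrate
about real recordings.

## The signal model

An intramuscular EMG signal is modelled as the linear superposition of
motor unit potential trains (MUPTs) plus additive noise:

$$x(t) \;=\; \sum_{m=1}^{M} \sum_{j} w_m(t - t_{mj}) \;+\; \varepsilon(t),
  \qquad \varepsilon(t) \sim \mathcal{N}(0, \sigma^2)$$

where $w_m$ is the potential waveform of motor unit $m$ and $t_{mj}$
its discharge times. The three modelling components are deliberately
minimal:

* **Waveform** $w_m$: the first derivative of a Gaussian — smooth,
  biphasic and band-limited, the standard minimal surrogate for a motor
  unit potential. It is mean-subtracted and peak-normalized, so
  `template_amplitude` is exactly the peak absolute value and the
  waveform contributes no DC component.
* **Firing** $t_{mj}$: Gaussian-perturbed regular inter-pulse
  intervals with mean $1/\text{rate}$ and standard deviation
  $\text{CV}/\text{rate}$, truncated below at 1 ms. This captures
  "repetitive firing with physiological variability" without importing
  a full stochastic point-process model. The train phase is randomized
  uniformly within one mean interval.
* **Noise** $\varepsilon$: white Gaussian. Real instrumentation and
  movement artifacts are *not* modelled (see Limitations).

A **lesion regime** `(recruitment_fraction, rate_scale,
amplitude_scale)` transforms a pre-lesion configuration into a
post-lesion one: only `round(recruitment_fraction * M)` units stay
active, with rates and amplitudes scaled down. The identity regime
`(1, 1, 1)` reproduces pre-lesion statistics exactly, which the test
suite asserts sample-for-sample. The default `(0.5, 0.8, 0.6)`
produces a clearly separable contrast whose difficulty can be tuned
continuously toward `(1, 1, 1)`.

The direction of the post-lesion change (reduced recruitment, rate and
amplitude) is an assumption: published descriptions say the lesion
perturbs muscle electrical activity but do not quantify the direction
of power change in these recordings. The regime is therefore fully
configurable rather than hard-coded.

### Default study conditions

The generator's defaults define the conditions under which the
package's end-to-end claims are tested:

| Parameter | Default | Why |
|---|---|---|
| sampling rate | 1000 Hz | one sample/ms, so a 1000 ms window is 1000 samples; 450 Hz cutoff realizable. The source experiments never state their telemetry rate — **1000 Hz is inferred**, not quoted. |
| recording duration | 2 s | two disjoint windows per recording; keeps the 400-per-class dataset tractable on one CPU |
| motor units per recording | 20 | small pool, amplitudes 0.5–1.5, durations 4–12 ms, rates 8–20 Hz (broad physiological ranges) |
| noise sigma | 0.05 | ~1/20 of a typical single-unit peak: visible noise floor without burying the signal |
| lesion regime | (0.5, 0.8, 0.6) | clearly separable classes; tunable difficulty |
| recordings per class | 400 | ~1280 training windows after balancing and splitting: enough for the CNN to converge in 30 epochs |

Every randomized quantity derives from one master seed through
`derive_seed(master_seed, stage_tag)`, a 31-bit multiplicative hash.
Stage streams are therefore isolated: changing the CNN seed cannot
perturb the simulated recordings. The hash multiplier (48271) keeps
all intermediates below $2^{53}$ so the modular arithmetic is exact in
doubles.

## Signal conditioning

* **Bandpass**: Butterworth, overall order 4 (an order-2 lowpass
  prototype mapped to a bandpass), cutoffs 10 and 450 Hz. The filter
  is designed by `signal::butter`; the zero-phase application is the
  package's own: odd (point-reflected) padding of $3\times$ the
  coefficient length on each end, forward pass, backward pass, trim.
  Reflect padding suppresses the edge transient that plain
  zero-padding leaves behind; the effective magnitude response is the
  square of the single-pass response, and the net phase is zero (the
  suite checks the cross-correlation of input and output peaks at lag
  0).
* **Notch**: an RBJ-cookbook biquad centred at 60 Hz. No installed R
  package provides this design, so the two coefficient lines live in
  the package. Quality factor **Q = 30** (a ~2 Hz stopband): only the
  centre frequency is prescribed by the source description, and a
  narrow notch preserves the neighbouring EMG band — the suite checks
  gain ≈ 1 at 30 Hz and ≈ 0 at 60 Hz against the analytic magnitude
  response.
* Sampling rates at or below 900 Hz are rejected (Nyquist violation
  for the 450 Hz cutoff); mismatched sampling rates across recordings
  are an error, never silently resampled.

## Windowing, balancing, normalization, split

The stage order is fixed: **filter → segment → balance → normalize →
split**, which is the narrative order of the reference procedure.
Windows are disjoint 1000-sample blocks; a trailing remainder is
discarded (floor rule). Balancing duplicates minority-class windows
uniformly at random with replacement until the counts match, keeping
every original row.

Two decisions here were genuinely open:

* **Normalization scope.** "Normalized between 0 and 1" could be
  per-window or global. The package normalizes **per window**: it
  matches the CNN's fixed [0, 1] input contract exactly, removes
  slow day-scale amplitude drift, and — because each window is scaled
  independently of any other — sidesteps the train/test information
  leakage that a globally fitted min/max would introduce.
  `preprocess_recordings(normalize = FALSE)` disables it for users who
  want a global scheme.
* **Split unit.** The 80:20 split is stratified at the *window* level,
  which mirrors the reference procedure but allows windows of one
  recording to appear in both sets. This inflates held-out estimates
  relative to a recording-level split; `kfold_cv` and
  `split_train_test` operate on any `segment_dataset`, so a user can
  group by recording before splitting for leakage-free evaluation.

## The feature-based arm

Four amplitude features per window, in fixed column order: area
($\sum_i |x_i|$, the integrated rectified value — no formula is
prescribed, this is the standard "area" EMG feature), RMS, turns, zero
crossings. Features are computed on the normalized windows (the
narrative order of the stages); `build_feature_matrix` accepts any
`segment_dataset`, so computing them on unnormalized windows is a
one-line change.

Thresholds: after min–max normalization physical units are gone, so
the classical 100 µV Willison turns threshold is inapplicable; the
default is instead `0.1 * (max - min)` of the training windows' pooled
amplitude range. The zero-crossing threshold defaults to 0 — and on
[0, 1]-normalized windows the zero-crossing count is identically zero
(no sign changes exist). That column then has zero training variance
and is mapped to 0 with a warning, which is the package's general
policy for degenerate feature columns. The kNN arm works from the
remaining three informative features; on raw (unnormalized) windows
all four are informative.

Scaling is "standardize then min–max", in that printed order: z-score
with training-column mean/SD, then rescale to [0, 1] with
training-column extremes. Test rows use the training parameters and
may legitimately fall outside [0, 1].

The classifier is exact brute-force kNN with Euclidean distance and
k = 9. The distance metric and tie policy are not prescribed
anywhere, so the package fixes them: Euclidean; exact distance ties
break toward the lower training-row index (a stable `order`); k odd
makes binary vote ties impossible. Equivalence with an independent
exhaustive-distance oracle is asserted for k ∈ {1, 3, 9}.

## The convolutional arm

The network is specified exactly: four blocks of
conv1d(+ReLU)+maxpool(2, stride 2) — 32×5/s2, 32×5/s2, 64×3/s1,
128×3/s1, dropout 0.1 after blocks 3 and 4 — then global average
pooling, dense(100)+ReLU and a single sigmoid unit. The package
derives every output shape and parameter count from the spec and the
suite pins them: temporal lengths 1000 → 500 → 250 → 125 → 63 → 63 →
32 → 32 → 16, GAP width 128, parameter counts 192 / 5152 / 6208 /
24,704 / 12,900 / 101, total **49,257**.

**Padding is the critical unstated detail.** "Same" zero padding with
ceil-mode lengths, $L_\text{out} = \lceil L_\text{in}/s \rceil$ for
both convolutions and poolings, is the only convention that reproduces
that shape sequence (witness 125 → 63); the package supports exactly
this mode and names it `same_ceil`.

Because no deep-learning framework is part of the package's
dependency set, the forward pass, backpropagation and Adam are
implemented in vectorized base R: convolutions are evaluated as one
channel-mixing BLAS product per kernel tap against gathered input
slices, max-pooling records its argmax for the backward pass (ties to
the first element), and the final sigmoid is fused with the
binary cross-entropy loss so the output-layer gradient is the
numerically stable $(p - x)/n$. Backpropagation is verified against
central-difference numerical gradients to ~1e-7 relative error.

Numerical/training choices:

* **Loss**: $\mathrm{BC} = -\frac{1}{n}\sum_i [x_i \log y_i +
  (1 - x_i)\log(1 - y_i)]$, natural log, predictions clipped to
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-7}$.
* **Optimizer**: Adam, learning rate 0.001, batch 128. The moment
  decay rates are not prescribed, so the framework defaults are
  assumed and pinned: $\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-7}$.
* **Initialization**: seeded Glorot-uniform (fan-based) — the
  initializer is not prescribed; this is the common framework default.
* **Epochs**: the reference budget is 500; the package default is
  **30**, which suffices for convergence on the default synthetic
  study conditions (final losses ≈ 0.01–0.1). The 500-epoch setting
  ships as `training_config(paper_preset = TRUE)` and
  `inst/config/paper-defaults.yaml`.
* **Decision rule**: probability > 0.5 ⇒ post-lesion, < 0.5 ⇒
  pre-lesion; exactly 0.5 (a measure-zero event) falls to class 0 by
  the package's strict-inequality convention.
* **Dropout** is active only during training; evaluation and
  prediction run deterministically. Training is reproducible on one
  machine from the seed (initialization, shuffling and dropout masks
  all derive from it).
* The kernel notation "(5, 1)" in 2-D-style layer tables is read as a
  1-D kernel of length 5 (the trailing 1 is the singleton spatial
  dimension), and each window is a single-channel input — left- and
  right-side muscles are separate experiments tagged in metadata, not
  a two-channel model.

## Evaluation

Five metrics from the confusion matrix, reported in percent:
accuracy, sensitivity, specificity, precision, and F-measure (harmonic
mean of precision and sensitivity). The **positive class is
post-lesion** — detecting the lesion effect is the clinical question;
the reference description never names its positive class, so this is
documented here. Zero-denominator ratios are reported as 0 with a
warning rather than NaN.

Both evaluation modes are implemented explicitly, because how the
reference reconciles an 80:20 split with five-fold cross-validation is
unclear: `run_pipeline` reports the held-out 20% split by default, and
`kfold_cv` runs stratified, disjoint, exhaustive k-fold CV
(`cv_knn = TRUE` in the run configuration; CNN cross-validation is
available the same way but costs k training runs).

## Problem sizes and runtime

The default end-to-end run — 400 recordings per class × 2 s,
conditioning, 1600 windows, kNN, and 30 CNN epochs on ~1280 training
windows — completes in about 5–6 minutes on a single CPU core; the
package's test suite, which includes one such full run, takes about
6 minutes. The tiny configurations used in unit tests (tens of
recordings, 2–8 epochs, 500-sample windows) run in seconds.

## What passing tests do and do not show

The synthetic generator provides ground truth and unlimited replicates,
so the suite can assert sharp, reproducible claims: filter gains match
analytic responses, the architecture arithmetic is exact, kNN equals
brute force, gradients are correct, and both classifiers exceed 95%
F-measure on held-out windows of the default lesion contrast with
train/test loss curves that decrease together.

None of that certifies performance on real intramuscular recordings.
The simulator omits, among other things: volume-conductor shaping and
electrode-position effects, motor-unit recruitment thresholds and
force-dependent rate coding, waveform variability within a train,
fatigue, movement and stimulus artifacts, non-Gaussian and
non-stationary noise, and cross-talk between channels. The published
headline figures for the real non-human-primate dataset (F-measures
near 90–97%) are therefore *not* reproduction targets of this package
— that dataset is not publicly available — and the package makes no
claim of matching them; the end-to-end criteria here are properties of
the synthetic study conditions stated above.
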