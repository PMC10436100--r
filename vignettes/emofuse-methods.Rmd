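---
title: "Multimodal emotion recognition with attentive feature fusion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal emotion recognition with attentive feature fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emofuse)
```

This vignette is the package's account of the science it implements:
the signal model behind the synthetic data, the preprocessing
assumptions, the network and fusion mathematics, the numerical choices,
and the limits of what the shipped tests demonstrate.

## The problem

Emotion recognition from physiological signals typically pairs EEG
(objective, hard to mask, 62 scalp channels here) with eye-tracking
(pupil size and gaze, convenient but confounded by stimulus luminance).
The two modalities carry complementary information: neither alone
separates all four target states (happy, sad, fear, neutral) reliably.
The package implements a dual-branch convolutional feature extractor
with a multi-scale fusion stage that learns, per feature channel, how
much to trust each modality.

## Preprocessing model and assumptions

**Band-pass (1–75 Hz), zero phase.** The EEG band edges are part of the
method's recipe. Only the band is prescribed, so the filter is our
choice: a 4th-order Butterworth applied forward–backward
(`signal::filtfilt`). Zero phase matters because the two modalities must
stay temporally aligned through preprocessing.

**Baseline correction.** Interpreted as per-trial, per-channel mean
subtraction. It is idempotent and commutes with the linear filter;
nothing fancier (e.g. pre-stimulus-interval baselines) is assumed
because the raw container carries no pre-stimulus segment.

**Pupillary light-reflex removal.** Pupil size responds strongly to
luminance. Since every participant watches the same clip at the same
trial index, the luminance response is a *shared* component across
participants while the emotional response is idiosyncratic. For the
panel `M` (time × participants) of one pupil channel, each column is
z-scored and the projection onto the first principal component across
participants is removed:

```
M = A + B,   A = u1 u1' M   (light reflex),   B retained.
```

`A` and `B` are orthogonal by construction and `A + B` reconstructs the
normalized panel to machine precision; both facts are asserted in the
tests. Panels are built per (session, trial index, pupil channel)
across subjects — our reading of "responses to the same video"; gaze
channels are not PCA-corrected (the reflex argument applies to pupil
diameter only) and are z-scored per trial instead. The decomposition
needs at least two participants; with one it degrades to plain
z-scoring, with a warning-free explicit code path.

**Windowing and resampling.** Trials are cut into non-overlapping 4-s
windows (half-open, zero-based; an incomplete trailing window is
dropped, never padded — padding would fabricate signal at the window
edge) and the temporal dimension is brought to 60 Hz, giving
240 × 62 EEG and 240 × 4 eye windows. Because 60 Hz cannot represent
content up to 75 Hz, naive subsampling would alias: resampling is
anti-aliased (zero-phase low-pass at 27 Hz, i.e. 0.9 × the target
Nyquist, then local linear interpolation on the window grid). The
effective EEG content above ~30 Hz is therefore attenuated — an
unavoidable consequence of the prescribed rates that we make explicit
rather than hide. The anti-alias filter runs once over the whole trial,
and the interpolation is local to each window, so decimating then
windowing equals windowing then decimating exactly; the suite checks
this at 1e-9.

## The dual branches

The published recipe names the ingredients — four blocks, 3 × 1 and
1 × 5 kernels, ReLU, a normalization layer, max-pooling in the first
three EEG blocks, temporal-only adaptive pooling for the eye branch —
but not the widths, strides, padding, pooling sizes or layer order.
Those are design choices of this implementation:

* stride 1, "same" zero padding everywhere;
* block order: temporal conv → ReLU → spatial conv → ReLU → batch norm
  → 2 × 1 temporal max-pool (temporal-then-spatial matches the order in
  which the two kernels are introduced);
* channel widths default to 16, 32, 64, 64;
* the eye branch's "1 × 5" kernel is a 5-tap *temporal* kernel with the
  four eye series as input feature channels — four channels cannot span
  a 5-wide spatial kernel, and the eye branch pools only along time;
* both branches end in adaptive average pooling to a common (15, 1)
  grid. The fusion stage requires element-wise compatibility of the two
  feature maps; adaptive pooling is the minimal mechanism that
  guarantees it for any input geometry.

Batch normalization uses batch statistics during training and running
statistics (momentum 0.1) at inference, so single-window inference is
well defined.

## Multi-scale fusion

With `V = V_eeg + V_eye`, global average pooling gives the channel
summary `x` (length C). A bottleneck descriptor `y = ReLU(BN(W x))` of
dimension `d = max(ceil(C/r), L)` guides a two-way softmax per channel:

```
a_c = exp(A_c y) / (exp(A_c y) + exp(B_c y)),  b_c = 1 - a_c,
F_c  = a_c V_eeg,c + b_c V_eye,c.
```

`C/r` may be fractional, so the ceiling is taken before the floor `L`
(L = 32 by default; with the default C = 64 and r = 2 the bottleneck
sits exactly at the floor). The softmax is computed with logit
shifting, so exponential overflow cannot occur; `a_c + b_c = 1` holds
to 1e-6 over thousands of random draws in the tests, and the fused map
is elementwise bounded between the two branch maps (convexity), checked
property-style. The classifier head flattens `F`, applies a 256-unit
ReLU layer with dropout 0.2 and a 4-way softmax.

Training minimizes mean cross-entropy (probabilities clamped at 1e-12
inside the log) with Adam at learning rate 0.001; batch size 256 and
100 epochs are the reference settings, scaled down in the examples. All
gradients are hand-derived; the suite verifies every parameter tensor
against central finite differences at 1e-5 relative tolerance, in all
three modes (fused and the two single-modality ablations).

## Evaluation

Stratified k-fold cross-validation (k = 5) holds out 20% per fold,
reconciling the 80/20 split with the k-fold protocol. Folds are
stratified so every fold contains all four classes, and — by default —
grouped by trial: windows of one trial never appear on both sides of a
split, since adjacent windows of the same trial are highly dependent
and window-level splitting would leak. A flag restores window-level
splitting for comparison. Metrics: accuracy, one-vs-rest
precision/recall/F1 with macro averaging (the four classes are balanced
by design, so macro and weighted averaging coincide in expectation),
and Cohen's kappa from the confusion-matrix marginals. A class that
receives no predictions contributes precision 0 with a warning.

## The synthetic generator

The licensed dataset the method targets cannot be shipped, so the
generator emulates its structure — 15 subjects × 3 sessions × 24
two-minute trials at 200 Hz, 62 EEG + 4 eye channels, balanced classes,
the same clip order (hence label sequence and illumination) for every
subject within a session. The signal model is deliberately analytic:

* EEG: unit-variance Gaussian noise band-limited to 1–75 Hz (matching
  the filter passband, so filtering is near-identity and the windowing
  logic is isolated in tests), plus class-dependent sinusoidal
  signatures of amplitude `eeg_effect`: class 0 at 10 Hz on channels
  1–8, class 1 at 20 Hz on channels 9–16, classes 2 and 3 none.
* Gaze: a bounded random walk plus, for classes 2/3 only, slow drifts
  at 0.3/0.6 Hz of amplitude `eye_effect`.
* Pupil: baseline, unit measurement noise (without it the z-scoring in
  the light-reflex step would divide by zero for zero-effect configs),
  class-2/3 modulations at 0.5/1.0 Hz, and one smooth illumination
  waveform (sum of three slow sinusoids, unit sd) shared across all
  subjects per (session, trial), scaled by `illumination_amplitude`.
  The class frequencies are chosen slow relative to the EEG band yet
  fast enough that a single 4-s window sees a discriminable waveform.

This gives the complementarity contract the fusion claim is tested
against: classes {0, 1} differ only through EEG, {2, 3} only through
the eye series, and the two pairs differ in both. Default effect
amplitudes are 1.0 (equal to the noise scale) — "moderate" in the sense
that single windows are informative but far from saturated. All
randomness flows from one root seed through named substreams, so the
generator is bit-reproducible, components can be regenerated in
isolation (the illumination reference used as an oracle in the
light-removal tests), and the realization is invariant to the effect
amplitudes.

What the generator does *not* model: volume conduction or any
physiological EEG forward model, saccades, blinks, artifacts beyond
the shared illumination, non-stationarity across sessions, or
subject-specific response idiosyncrasies. Passing tests therefore
demonstrate that the pipeline's machinery is correct and that fusion
exploits complementary structure when it exists — not that the
architecture attains any particular accuracy on real recordings.

## Problem sizes in the examples and tests

The shipped experiments are desk-scale by design: the ablation study
uses 6 subjects × 4 two-minute trials (720 windows), narrow branch
widths (4, 8, 16, 16), 30 epochs at batch 64, and a single
trial-grouped 80/20 split; unit tests use smaller sets still. These
sizes were chosen so the full suite exercises every stage end-to-end —
generation, light removal, windowing, both branches, fusion, training,
paired ablation — while each training stays in the tens-of-seconds
range. At these sizes the qualitative claims are stable across seeds:
fused ≥ each single modality, and each single modality is at chance on
exactly the class pair it does not encode.

## Numerical and engineering notes

* The convolution, pooling and batch-norm kernels are compiled
  (Rcpp/BLAS) and hand-verified against plain-R reference
  implementations kept in the package for exactly that purpose; the
  finite-difference check then covers the full composed network.
* Convolutions exploit the tensor layout (time fastest) to express each
  kernel tap as one BLAS product on contiguous views, with explicit
  correction of segment-boundary rows; no im2col buffers are built.
* Ties in max-pooling resolve to the earlier time point,
  deterministically.
* BLAS/OpenMP threading is pinned to one thread at package load (unless
  the user has set the environment variables): the per-batch products
  are too small to gain from threading, and an oversubscribed pool is
  pathologically slow.
* Max-pooling requires an even temporal extent at every pooled block,
  which the default geometries satisfy (240 → 120 → 60 → 30 → 15).

## Known limitations

* The eye-channel semantics (pupil X/Y, gaze X/Y ordering) are a fixed
  convention of the containers, not a claim about any particular
  tracker export.
* Light-reflex removal assumes a dominant shared component; with very
  weak illumination the first principal component may capture emotional
  variance instead. The `pca_enabled` flag exists for that regime.
* The reference hyperparameters (100 epochs, batch 256) are impractical
  for the desk-scale examples and are scaled down there; the defaults
  in `train_config()` keep the reference values.
* Cross-validation is pooled across subjects (grouped by trial);
  subject-independent transfer is out of scope.
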