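---
title: "Methods: synthetic rhythms, wavelet denoising, and the 1D-CNN protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic rhythms, wavelet denoising, and the 1D-CNN protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures the package
implements, the assumptions behind them, the tunable parameters and
their defaults, and the design decisions taken where the design was
genuinely open. It states no empirical claim that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem and the modelling stance

Atrial fibrillation (AF) manifests on a single-lead ECG as an
irregularly irregular R–R interval sequence and the loss of the P-wave,
replaced by low-amplitude fibrillatory (f) oscillations around 4–9 Hz.
Short-term single-lead recorders differ widely in sampling frequency
(100–500 Hz) and record length, and a detector tied to one device's
frequency generalizes poorly. The stance taken here is the end-to-end
one: segment every recording *on its native grid* into fixed-length
episodes of L = 2700 samples and let a one-dimensional convolutional
network learn its own rhythm features from raw amplitudes. The package
never resamples a record, and applies no amplitude normalization by
default (an optional per-episode z-score flag exists on the episode
matrix path but is off: raw millivolt amplitudes are part of the
learned representation).

The choice L = 2700 ties episode duration to sampling frequency: 5.4 s
at 500 Hz, 27 s at 100 Hz. Even at the fastest supported rate an
episode spans at least two R–R intervals at physiological heart rates,
which is the minimum rhythm context for AF; `episode_qc()` checks
exactly this (≥ 3 detected R-peaks in the unpadded portion) and is used
for reporting only — segmentation is unconditional, and QC never drops
data silently.

## Synthetic rhythm generator

The generator exists so that every downstream stage — denoising,
segmentation, peak detection, training, evaluation — is exercisable and
testable without clinical data. It is first-class, seeded, and tested.

**Beat morphology** is a sum of Gaussians per beat (amplitudes in mV,
times in seconds relative to the R-peak): Q (−0.10 at −0.035, σ 0.010),
R (+1.00 at 0, σ 0.012), S (−0.15 at +0.035, σ 0.010), T (+0.30 at
+0.30·k, σ 0.05·k) and, for rhythms with organized atrial activity, P
(+0.15 default at −0.17·k, σ 0.022), where k clamps the local R–R
interval to [0.5, 1.2] so P and T compress at fast rates instead of
colliding with the next beat. This deliberately simple template family
is adequate for a *rhythm* classifier; it is not a dynamical ECG model
and makes no claim of morphological fidelity (see Limitations).

**R–R model**: intervals are i.i.d. log-normal with configured mean
(from `mean_hr`) and coefficient of variation `rr_cv`. Class
invariants are enforced at construction: N requires `rr_cv ≤ 0.05` and
a positive P-amplitude; AF requires `rr_cv ≥ 0.15` and a zero
P-amplitude. The i.i.d. log-normal choice reproduces "irregularly
irregular" without modelling atrioventricular-node dynamics. The
ectopic Non-AF variant shortens ~15% of intervals to 0.65× with a 1.3×
compensatory successor.

**f-wave**: AF replaces the P-wave with a sinusoid at a
uniformly-drawn 6–8 Hz frequency whose phase performs a small random
walk (σ 0.05 rad/sample), a standard coarse surrogate for fibrillatory
waves; default amplitude 0.08 mV against 0.15 mV P-waves, both at the
low end of clinical magnitudes.

**Artifacts**: baseline wander (0.05 mV sinusoid below 0.5 Hz),
powerline (0.02 mV at 50 Hz) and white noise (σ 0.02 mV) by default —
modest values chosen once as representative of a reasonable-quality
ambulatory recording; the sources give no noise model to copy.

**Seeding**: one root seed; every draw site (R–R stream, f-wave,
each artifact, each record of a dataset, each training epoch's shuffle)
uses a child seed derived by hashing a site tag into the root, so
adding a new draw site never shifts existing streams. R-times are drawn
in continuous time, which makes R-peak positions consistent across
sampling frequencies for the same seed — a tested invariant.

`generate_dataset()` assigns subjects round-robin within each class so
subject-disjoint splitting is meaningful, and jitters each record's
heart rate log-normally (5% CV) around the class default (N 70, AF 95,
bradycardia 45, tachycardia 130 bpm) so records are not clones of one
prototype.

## Wavelet denoising

`denoise_record()` performs a multilevel DWT with the Sym5 orthogonal
wavelet to 8 levels (reduced with a warning when the record is too
short, never silently cropped), using half-sample symmetric boundary
extension. The noise scale is estimated from the finest detail band as
σ = MAD/0.6745 and the universal threshold σ√(2 ln n) soft-thresholds
the configured detail levels — defaults to levels 1–2, the
high-frequency bands where broadband noise dominates; the deepest
approximation band (below fs/512, i.e. below 1 Hz at any supported fs)
is zeroed to remove baseline wander. All three switches are exposed in
`wavelet_plan()`. The transform convention is exchangeable with the
widespread open-source DWT implementations, and single-level
coefficients are pinned against independently computed values in the
tests; with no thresholding the transform reconstructs the input to
below 1e-8 relative error.

Denoising runs on whole records before segmentation, matching the
pipeline order in which episodes are the *model's* input unit, not the
filter's.

## Segmentation

Non-overlapping windows of L = 2700 samples (the stride is
configurable; overlap is off by default as the simplest policy
consistent with fixed-length episodes). A final remainder of at least
L/2 samples is zero-padded at the tail to L; a shorter remainder is
dropped; a record shorter than L yields exactly one padded episode. So
the episode count is `floor(n/L) + [n mod L ≥ L/2]`, with 1 when
n < L — asserted as a property over random lengths. Padded zeros are
fed to the network as-is; no masking, mirroring the zero-padding
design.

## The network

The canonical architecture is declarative (`model_config()`): five
convolution blocks of 64-64, 128-128, 256-256-256, 512-512-512,
512-512-512 filters — 13 convolutions, each kernel 3, stride 1, no
padding, ReLU — every block closed by a max-pool of size 2 stride 2;
then flatten (78 positions × 512 channels = 39,936), two dense-1000
layers, and the head: one sigmoid unit for two classes (AF the
positive class, ties at 0.5 broken toward AF) or a three-unit softmax.
`shape_trace()` reports each layer's output length, channels and
parameter count without running data, and `count_parameters()` totals
45,846,329 for the binary network, biases included in every trainable
layer. These numbers are pinned integer-exactly in the tests.

Weights initialize from a fan-in-scaled uniform,
U(±√(6/fan_in)), fully determined by one seed. Forward and backward
passes use im2col matrix products (BLAS); the Adam update is a single
fused in-place C++ kernel, because a chained elementwise update over
the multi-million-parameter dense block dominated training time in
pure R.

Numerical details: probabilities are clamped to [1e-12, 1−1e-12] inside
the cross-entropy; the softmax subtracts the row maximum; max-pool
breaks ties toward the earlier sample; odd trailing samples before a
pool are discarded (as the output-length table requires).

## Training protocol and evaluation

`make_folds()` builds a stratified k = 10 partition, by subject in
inter-patient mode (no subject may appear on both sides of a fold — a
leakage check asserts this on every plan) or by episode in
intra-patient mode, deterministic in the seed. Class weights are
inverse-frequency, n/(k_classes·n_c), computed on each fold's training
split — the sources describe weight tuning by resampling without
printing values, so the standard reproducible formula is used and
exposed in the config. Training is mini-batch Adam (β₁ 0.9, β₂ 0.999)
on class-weighted binary or categorical cross-entropy at the published
hyperparameters — learning rate 1e-4, batch 16, 100 epochs — with no
early stopping and no schedule, since none is described; the
final-epoch model is returned. Three-class mode uses intra-patient
episode-level stratification.

`metrics_report()` computes one-vs-rest confusion counts per class and
the five metrics: accuracy, sensitivity TP/(TP+FN), specificity
TN/(TN+FP), precision TP/(TP+FP), F1. Undefined ratios (zero
denominators) are reported as `NA`, never as 0. Fold averaging is the
unweighted arithmetic mean of per-fold metrics. Metrics are computed at
episode level; a record-level majority-vote summary can be formed from
the prediction table by the caller, since reporting level is a genuine
ambiguity in the source material. The tests verify every report against
brute-force recounts and the binary identity
`accuracy = (sens·P + spec·N)/(P+N)`.

## The synthetic recovery experiment

`synthetic_recovery_experiment()` is the package's end-to-end check:
under a clear class contrast (R–R CV 0.03 vs 0.25, the generator's
other defaults untouched), a scaled-down model trained under the
published optimizer settings must recover the classes across a
subject-disjoint split. Design choices, fixed after pilot runs and then
left alone:

- **Problem size**: 500 records per class, one episode each — roughly a
  50-fold scale-down of the source protocol's ~54,000 episodes. Much
  smaller sets (≤ 250/class) put any two-block model in a memorization
  regime at the fixed 5-epoch budget: training accuracy saturates while
  held-out accuracy stalls, and a 50-episode validation fold is at the
  binomial noise floor for a 0.95 requirement.
- **Sampling frequency 100 Hz, 27 s records**: a 2700-sample episode
  then spans ~30 beats, and the scaled model's receptive field (~14
  input samples ≈ 140 ms) covers the P-to-QRS distance and a full
  f-wave cycle. At 250 Hz the same episode holds ~13 beats and the
  receptive field (56 ms) sees neither morphological cue, leaving only
  position-specific features that do not transfer across subjects.
- **Scaled architecture** (`small_model_config()` defaults): two
  convolution blocks (8-8, 16-16) under the same kernel/stride/pool
  conventions as the full network, three additional pooling stages that
  coarsen the 672-position feature map to 84 before the head (curbing
  position memorization), and a dense-2000 layer (wide enough to learn
  at learning rate 1e-4 within 5 epochs).
- **Evaluation**: fold 1 of the inter-patient 10-fold plan (90:10, the
  protocol's split), AF positive.

The acceptance tests run this at seeds 1, 2 and 3 and require held-out
sensitivity and specificity ≥ 0.95. What passing shows: the
implementation's gradient flow, fold hygiene and metric pipeline are
sound, and the learned features transfer across subjects *on data whose
class signal is, by construction, clean and stationary*. What it does
not show: performance on clinical ECG, where morphology varies within
and across patients, noise is structured, and class boundaries are
soft. The printed full-corpus accuracies of the source study are not
reproducible without its nine external databases and full-scale
training, and the package makes no attempt to imitate them.

## Known limitations

- The beat template is fixed-shape; no intra-patient morphology
  drift, no ectopic morphology (ectopy is rhythm-only), no 12-lead
  simulation, and only three coarse Non-AF variants.
- The f-wave surrogate is narrowband; clinical fibrillatory activity is
  broader and less stationary.
- The R-peak detector (5–15 Hz Butterworth band-pass, squaring, 150 ms
  integration, adaptive threshold, 0.2 s refractory) is tuned for the
  generator's morphology and reasonable noise; it is a support tool for
  QC and rhythm statistics, not a validated clinical QRS detector.
- WFDB support covers format 16 with a common annotation subset —
  enough for round-trips and interoperability tests, not a complete
  reader for every variant in the wild.
- Training the full 45.8M-parameter network is computationally feasible
  here but slow in R; the package's own experiments use the scaled
  configuration, and the full configuration is exercised for
  architecture accounting and prediction contracts.
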