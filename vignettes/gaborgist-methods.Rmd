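---
title: "Classifying normal and abnormal patient movement from video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying normal and abnormal patient movement from video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaborgist)
```

## The problem

Epileptic seizures announce themselves in movement: abrupt changes of motion
direction interleaved with periods of no movement, against the smooth,
purposeful movement of an awake and comfortable patient. `gaborgist`
implements a holistic video-classification pipeline for this distinction:
grayscale intensity volumes are filtered with a small bank of spatiotemporal
3D Gabor filters, each filtered volume is average-pooled over a coarse
4 x 4 x 4 spatiotemporal grid into a *gist* descriptor, and a soft-margin
support vector machine (SVM) separates the two classes. Evaluation follows a
per-patient protocol: within each patient, half of the clips train the
classifier and the other half test it, repeated five times with fresh random
splits.

Clinical ward recordings are not distributable, so the package ships a
synthetic surrogate generator that reproduces the *motion statistics* of the
two classes — not seizure semiology — and the whole pipeline is exercised
and tested end to end on those surrogates.

## The model, stage by stage

### 3D Gabor filter bank

A 3D Gabor filter is a Gaussian envelope times two cosine carriers,

$$G(x,y,t) = \exp\!\Big(-\tfrac{X^2}{2\sigma_x^2} - \tfrac{Y^2}{2\sigma_y^2}
 - \tfrac{T^2}{2\sigma_t^2}\Big)\,
 \cos\!\big(\tfrac{2\pi}{\lambda_x}X\big)\cos\!\big(\tfrac{2\pi}{\lambda_y}Y\big),$$

where $(X,Y,T)$ are the volume coordinates rotated by a spatial orientation
$\theta$ and a temporal orientation $\omega$ (two elementary rotation
matrices applied in that order; see `rotate_coords()`). The default bank has
**one scale and four orientations**,
$(\theta,\omega) \in \{(0,0), (\pi/2,0), (0,\pi/2), (\pi/2,\pi/2)\}$ —
the two axis-aligned spatial orientations and their temporally tilted
variants.

Two parameterisation details deserve comment:

* **Gaussian denominators.** The filter family is sometimes written with
  denominators $2\sigma$ rather than $2\sigma^2$. The package defaults to
  the standard $2\sigma^2$ (so $\sigma$ is a length, in pixels/frames);
  `gabor_params(sigma_is_variance = TRUE)` gives the literal $2\sigma$ form
  for users who want the $\sigma$ values interpreted as variances.
* **Kernel normalization.** Sampled kernels are mean-subtracted and
  L2-normalized. Zero-mean taps respond exactly zero to constant volumes,
  which turns "robust to illumination changes" from a qualitative claim
  into a testable invariant; unit norm makes response magnitudes comparable
  across orientations.

**Border handling.** Same-size correlation needs a border rule. Zero padding
would make the response to a *constant* volume nonzero near borders
(partial kernel windows have nonzero tap sums), destroying the illumination
invariance that motivates the zero-mean kernels. The package therefore
extends volumes by **edge replication**: a constant volume then yields an
exactly constant window everywhere, and the response — and hence every gist
entry — is invariant to adding any constant offset, at every position
including borders. Correlation is computed by FFT on 2-3-5-smooth padded
grids; one forward transform per clip is shared across the bank, and pairs
of kernels share each inverse transform (two real responses packed into one
complex transform), so a four-kernel bank costs three large FFTs per clip.

**Filter scale.** The defaults are
$\sigma = (12, 8, 6)$ (pixels, pixels, frames),
$\lambda_x = \lambda_y = 96$ px, and support half-extents $(18, 18, 10)$,
at the working resolution of 160 x 128. The scale is deliberately matched
to the pooling grid (below), whose cells are 32 x 40 px x ~62 frames: the
descriptor keeps only the *mean* signed response per cell, so structure
much finer than a cell largely cancels inside the average. A carrier
wavelength well above the kernel support makes each kernel an anisotropic
center-surround (band-pass at low frequency) whose response field varies on
the cell scale, which is what mean pooling can actually transport to the
classifier. A fine carrier (e.g. $\lambda = 8$ px with $\sigma = 4$) is a
perfectly good Gabor filter, but its pooled means are near-zero for any
blob-like moving target — we verified this empirically during development:
class information then survives only in response *magnitudes*, which a
linear SVM on mean-pooled features cannot exploit. Every parameter is
configurable through `build_default_bank()` for users who want other
scales; the kernel order is fixed and documented because the feature layout
depends on it.

### Spatiotemporal gist pooling

Each filtered volume is divided into a 4 x 4 x 4 grid of near-equal blocks
(bin edges at `floor(i * d / 4)`, so every voxel belongs to exactly one
block even when a dimension is not divisible by 4), and each block is
replaced by the arithmetic mean of its responses. With four kernels this
yields the 4 x 64 = **256-dimensional** descriptor, laid out kernel-major
with the time-block index fastest. Pooling trades spatial precision for
tolerance to small shifts and noise; a one-pixel shift of a smooth clip
changes the descriptor by well under a tenth of its norm.

No per-feature standardization happens at extraction time: train-time
z-scoring lives in the classifier so that no test-set statistics can leak
into scaling.

### Soft-margin SVM

`svm_fit()` solves the Wolfe dual

$$\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j} \alpha_i \alpha_j
y_i y_j K(x_i, x_j), \qquad 0 \le \alpha_i \le C,\quad \textstyle\sum_i
\alpha_i y_i = 0,$$

by sequential minimal optimization with deterministic
maximal-violating-pair selection (ties break to the lowest index), stopping
when the KKT violation falls below `1e-6`. Linear, polynomial
$(x_i \cdot x_j + c)^d$ and Gaussian RBF
$\exp(-\lVert x_i - x_j\rVert^2 / 2\sigma^2)$ kernels are supported. The
bias $b$ is the mean over unbounded support vectors
($0 < \alpha_i < C$) of $y_i - \sum_j \alpha_j y_j K(x_j, x_i)$; when every
support vector sits at a bound, $b$ is the midpoint of the KKT-admissible
interval. The decision rule is $F(x) = \mathrm{sgn}(f(x))$ with the tie
$f(x) = 0$ mapped to $+1$ so predictions are deterministic. Features are
z-scored with training-set statistics inside `svm_fit()` (gist entries have
heterogeneous scales across orientations and cells).

$C$ is chosen by stratified $k$-fold cross-validation
(`select_C()`, default grid $\{0.01, 0.1, 1, 10, 100\}$, $k = 5$) with
exact ties broken toward the smaller — i.e. more regularized — value.

The solver was validated against a dense interior-point QP oracle
(`kernlab::ipop`) on randomized small problems across all three kernel
families, against the closed-form two-point problem, and against the KKT
conditions directly; the test suite keeps all three routes.

### Evaluation protocol

`run_experiment()` repeats, five times by default: split every patient's
clips randomly in half (ceiling to training for odd counts; seeded with
`base_seed + repeat`), choose $C$ on the training half only, fit on the
training half, predict the held-out half, record clip-level accuracy. The
report carries each repeat's accuracy and their mean, plus the seeds and a
configuration fingerprint; identical inputs and seeds reproduce the report
byte for byte. Clips segmented from one recording share a `patient_id`, so
the split is always per-patient; the literal protocol lets sibling clips of
one recording fall on both sides, and `group_ids` (CLI:
`--group-by-recording`) provides the strict variant that forbids it.

## The synthetic surrogate generator

`generate_normal_clip()` renders a Gaussian-profile blob (the patient)
moving over a uniform background with optional slow illumination drift,
pixel noise, and independently moving dimmer distractor blobs (other
persons). The trajectory starts near the frame center — the camera of the
emulated setup is mounted above the bed and centered on the patient — and
follows constant-speed motion whose heading performs a small-angle random
walk (per-frame increments capped at `heading_cap`), reflecting at the
borders. `generate_abnormal_clip()` uses the same engine plus the two
abnormal motion traits: **abrupt reversals** — instantaneous heading jumps
uniform in $[90^\circ, 180^\circ]$ at `jerk_rate` per 100 frames — and
**frozen periods** of `freeze_len` frames entered with per-frame
probability `freeze_prob`. With both rates zero the abnormal model
degenerates *exactly* to the normal model (same seed, identical output).
Every clip carries its trajectory log (positions, headings, jerk, freeze
and reflection flags) as an attribute, so motion statistics can be
recomputed independently in tests.

`generate_cohort()` draws per-patient appearance nuisances once per patient
(background level, blob intensity, blob size — different clothes and
lighting) and assigns labels at the requested abnormal fraction, spread
evenly over patients. `generate_cohort_features()` is the same cohort
streamed directly into descriptors, one clip in memory at a time, which is
how full-resolution cohorts are processed within a modest memory footprint.

### Default conditions and why

The defaults define the reference study conditions of the package's own
experiments (9 patients x 6 clips, 250 frames at 25 fps, 128 x 160 px):

* `speed = 16` px/frame with `heading_sd = 0.06` rad: normal clips sweep
  most of the frame within 10 s, so their time-averaged occupancy is
  spread, with modest clip-to-clip variation.
* `jerk_rate = 100` (a reversal nearly every moving frame): abnormal
  movement is a drift-free tremor around the resting position, matching
  the "continuously shaking" picture of seizure motion.
* `freeze_prob = 0.3`, `freeze_len = 80`: abnormal clips are frozen most
  of the time, with brief tremor bursts — "periods of no movement"
  dominate.
* `blob_radius = 5` px, `noise_sd = 0.005`, no illumination drift and no
  distractors by default: the clean, low-noise condition. Drift,
  distractors, and heavier noise are opt-in difficulty dials.
* Per-patient nuisances span moderate ranges (background 0.2-0.3, peak
  intensity 0.5-0.65, radius +-10%).

Under these conditions the two classes differ in their time-averaged
occupancy pattern (concentrated at the center versus spread across the
frame) and in their temporal dynamics, which the mean-pooled low-frequency
Gabor responses encode with consistent sign — this is what makes the
classes *linearly* separable downstream, and the end-to-end repeated
half-split experiment reaches mean accuracy above 0.9 (computed by
`scripts/acceptance.R` and asserted in the acceptance tests, alongside a
permuted-label null at chance level).

### What the surrogates do and do not show

The generator reproduces controllable motion statistics with loggable
ground truth; it does **not** attempt articulated human appearance,
clinically realistic seizure semiology, camera shake, occlusions, or
compression artifacts. A pipeline that separates the surrogate classes has
demonstrably sufficient machinery to encode "localized tremor plus
stillness versus smooth wandering", no more: results on surrogates say
nothing quantitative about clinical recordings, where reported accuracies
are far more modest.

## Numerical choices and edge cases

* FFT pad sizes are rounded up to 2-3-5-smooth integers; kernel spectra are
  cached per (kernel, pad shape), so cohorts of same-sized clips compute
  each spectrum once. Chunked temporal filtering (for clips longer than
  memory allows) overlaps chunks by the kernel's temporal half-extent and
  equals the single-pass result exactly.
* Pooling block edges at `floor(i d / 4)` make the partition deterministic
  and exhaustive for any dimension >= 4; dimensions below 4 are an error.
* The SMO quadratic term is floored at `1e-12` for numerically parallel
  pairs; `sd = 0` feature columns scale by 1 instead of dividing by zero.
* Degenerate kernels (taps vanishing after mean subtraction, e.g. an
  effectively constant envelope) raise a configuration error rather than
  returning a zero filter.
* Split seeds derive as `base_seed + repeat`, fold seeds as
  `base_seed + repeat + 1e5`; all generator randomness flows through one
  seeded stream per clip, and package functions restore the caller's RNG
  state.
* An exactly 60 s recording yields one segment ("no longer than" is
  inclusive); the trailing shorter segment of a longer recording is kept.

## Known limitations

* No AVI/container decoding in-package: clips enter as numbered PNG/TIFF
  frame directories (`ffmpeg -i clip.avi frames/%04d.png` upstream).
* The unit of classification is the clip; there is no per-frame onset
  detection or temporal localization.
* Binary classification only; no probability calibration.
* Mean pooling of signed responses discards response energy. With
  fine-scale carriers this loses most motion information (see "Filter
  scale"); the block-matched default scale is a design response to that
  constraint, not a removal of it.
* The per-patient half-split protocol measures within-patient
  generalization; it says nothing about transfer to unseen patients
  (leave-one-patient-out would, but is not part of the reference
  protocol).

## Problem sizes used by the test suite

Unit tests run on small volumes (tens of pixels, tens of frames) and small
banks; the end-to-end acceptance experiment uses the reference conditions —
9 patients x 6 clips x 250 full-resolution frames — streamed through
`generate_cohort_features()`, and the permuted-label null reuses the same
features. These sizes keep the full suite within a coffee break on one CPU
while exercising every stage at the reference resolution.
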