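---
title: "Methods: microstate-conditioned CSP and topographic CNN classification of EEG expertise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstate-conditioned CSP and topographic CNN classification of EEG expertise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eegskill` classifies expert versus novice performers of a bimanual
laparoscopic-style task from 32-channel scalp EEG recorded at 500 Hz around a
task-start trigger. Two branches share the preprocessing front end and the
evaluation back end:

1. **Microstate-conditioned regularized CSP + LDA.** Task-onset EEG is
   summarized by a small set of quasi-stable scalp topographies
   (microstates); common spatial patterns computed on microstate-conditioned
   samples feed a linear discriminant.
2. **Topography-preserving 3-D CNN.** EEG is rendered as a 16×16×360 tensor
   (scalp image × time) and classified by a small convolutional network whose
   temporal attentive pooling (TAP) layer learns which time segments matter;
   Grad-CAM exposes the spatial evidence.

This vignette records the modelling assumptions, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## Preprocessing chain

The cleaning chain, in fixed order: polyphase resampling to 250 Hz; zero-phase
FIR high-pass at 1 Hz; line-noise removal; bad-channel detection and
spherical-spline interpolation; common-average reference; task epoching; ASR;
common-average reference again; surface Laplacian. The executed order is
recorded in each epoch set's `manifest` attribute, and `preprocess_recording()`
is the single entry point that enforces it. The second average reference is
retained deliberately: ASR's per-window reconstruction can reintroduce a small
common-mode component, and re-referencing is idempotent on already-referenced
data.

Numerical choices worth knowing:

* **Resampling** is rational polyphase (zero-stuff by *p*, windowed-FIR
  anti-alias low-pass at π/max(p, q), take every *q*-th sample). The
  symmetric FIR is applied with exact group-delay compensation, so resampled
  signals have no residual lag; a 10 Hz sine at 500→250 Hz survives with
  amplitude error below 0.1%. Event sample indices rescale by the rate ratio
  with round-half-even.
* **High-pass**: Hamming-window FIR sized for a ~1 Hz transition band,
  applied with group-delay compensation (zero net phase). Channel means are
  removed first so constant offsets map exactly to zero.
* **Line noise** is removed by sliding-window sinusoid regression at the
  mains frequency and its first harmonic (4 s windows, Hann-weighted
  overlap-add). Only a rank-4 subspace per window is touched, so broadband
  power changes by well under 5% while a pure line component loses ≥ 99% of
  its power. This tracks slow amplitude/phase drift, which a single global
  regression would not.
* **Bad channels** are flagged by two criteria mirroring common automated
  pipelines: flatline ≥ 5 s, or a median windowed correlation below 0.8
  between the channel and its best spherical-spline estimate from random
  subsets of the other channels (12 subsets of 50%). The subset scheme makes
  the estimate robust: one or two bad channels cannot drag their neighbours
  below threshold. Subjects with ≥ 5 flagged channels are excluded
  (exclusive bound: 4 pass, 5 fail).
* **Spherical splines** use the standard order m = 4 kernel with 50 Legendre
  terms and ridge 1e-5, for both interpolation and the surface Laplacian
  (current source density, reported as µV/m² for a 0.09 m head radius). For
  a degree-1 spherical harmonic the Laplacian output is proportional to the
  input with the sign of the potential, consistent with the n(n+1)
  eigenrelation of the Laplace–Beltrami operator up to the spline's
  smoothing bias (tests allow 30% on the scale, and require correlation
  ≥ 0.999).
* **ASR** is the offline calibrate-then-clean form with Euclidean
  statistics: calibration (≥ 30 s of pre-trigger rest) yields a mixing
  matrix and per-direction robust thresholds (median + k·1.4826·MAD of
  windowed component RMS, k = 20 by default); each 0.5 s window of task data
  is eigendecomposed, directions whose variance exceeds the calibration
  threshold are reconstructed from the retained subspace, and windows are
  blended by raised-cosine overlap-add. `cutoff = Inf` is exactly the
  identity; data matching the calibration statistics pass through with < 5%
  RMS change.

## Microstate analysis

Prototype fitting operates on maps at GFP peaks (GFP = per-sample population
SD across channels). Peaks must be ≥ 10 ms apart (the larger peak wins);
peaks whose GFP exceeds mean + 1 population SD of all peak GFPs are rejected
as artifact-dominated; at most 1000 peaks per epoch are kept by seeded
subsampling.

The modified K-means is polarity-invariant: similarity is the squared spatial
Pearson correlation, and each prototype is updated as the dominant
eigenvector of the outer-product sum of its assigned maps, which is the
maximum-likelihood topography under the single-map-plus-noise model.
Initialization is k-means++-style on the polarity-folded squared Euclidean
distance; the polarity fold is used only for seeding, correlation for
assignment. Defaults: 100 restarts, 1000 iterations, relative convergence
1e-6; the best restart by global explained variance (GEV) is kept and
prototypes are sorted by decreasing per-state GEV.

The number of microstates is chosen over K = 2…8 by the predictive
cross-validation criterion — residual noise variance with the small-sample
correction ((C−1)/(C−1−K))², C = channels — whose minimum marks the best
solution (the correction diverges as K approaches C−1, which the code
reports as `Inf` with a warning). On synthetic data generated from six
well-separated prototypes, the criterion's minimum falls at K = 6, which is
how the test suite exercises it. GEV itself grows (weakly) with K and is not
a selection criterion.

Backfitting labels each sample with the best-correlated prototype (squared
correlation; the polarity sign is reported separately). Temporal smoothing
uses small-segment rejection: runs shorter than 30 ms are dissolved into
whichever flanking state correlates better, iterated to a fixed point. The
30 ms default is a design choice from the typical microstate duration
literature; a windowed-penalty smoother was considered and rejected as
needlessly parameter-heavy for this pipeline.

## Regularized CSP and LDA

For expert/novice scatter matrices C₁, C₂ (sums of XᵀX over epochs; per-epoch
trace normalization is available but off by default, matching the raw
variance-ratio objective), the two Tikhonov-regularized eigenproblems

> M₁ = (C₂ + αK)⁻¹C₁  and  M₂ = (C₁ + αK)⁻¹C₂,  K = I

give the discriminative spatial filters; the leading eigenvector of each
branch is the class-specific filter, and eigenvalues equal the projected
variance ratios (asserted numerically in tests, with a dense
symmetric-whitening generalized eigensolver as the independent oracle at
1e-8). Filters are unit-norm with the largest-magnitude coefficient positive
— eigenvectors are sign/scale-ambiguous and some convention is required for
reproducibility. The decomposition is required to be real; a complex residual
above 1e-8 raises an error rather than being silently truncated. α defaults
to 0.1·tr(C₂)/C, a scale-free ridge; it is exposed everywhere.

Features are log mean-square amplitudes of the epoch projected on the top
filter of each branch (2 features per epoch by default). Classification is a
Fisher discriminant with the pooled covariance shrunk toward its average
diagonal (λ = 1e-3 default), which keeps the fit defined when a feature
degenerates; 10-fold stratified cross-validation re-fits CSP and the
discriminant inside every training fold, so no information leaks from test
epochs into the filters.

Microstate conditioning restricts each class's scatter to samples of one
microstate. `state = "auto"` uses each epoch's dominant backfitted state —
the modal label over the 10 s task-onset window — rather than the literal
first sample's label, which is fragile to single-sample jitter at the epoch
edge. A fixed global state index is also supported, for designs where the
group difference is confined to one state.

## Tensorization

Electrode positions are flattened by an azimuthal equidistant projection
centred at the vertex (radial distance ∝ polar angle, azimuth preserved),
scaled into a 16×16 grid with a 1-cell margin; rows run nasion→occiput and
columns left→right, so the lower-left quadrant is the left parieto-occipital
scalp. Continuous coordinates are kept for interpolation; rounding is used
only to check that all 32 electrodes land on distinct cells.

Each frame is interpolated by a biharmonic Green's-function spline
(G(r) = r²(log r − 1)) with exact collocation, augmented with a constant term
(coefficients constrained to sum to zero) so constant maps are reproduced
exactly; cells outside the electrode convex hull are zero-filled rather than
extrapolated, because the biharmonic interpolant diverges at the grid
corners. Because collocation is linear, the whole frame operator is a single
precomputed 256×32 matrix, making tensorization one matrix product per
window and exactly linear in the signal.

Epochs are taken from 2 s before the start trigger, resampled to 120 Hz, and
cut into 3 s windows sliding by 1 s: a span of S seconds yields
⌊S − 3⌋ + 1 windows, so the full protocol (182 s per trial, 21 subjects × 3
trials) yields 180 windows per trial and 11,340 tensors of 16×16×360.

## The CNN and TAP

Three valid (unpadded) conv blocks (conv → batch norm → ReLU) with
kernel/stride (2,2,10)/(2,2,4), (2,2,2)/(2,2,2), (2,2,3)/(2,2,2) and channel
widths 16/32/64 reduce a 16×16×360 input to feature maps of 8×8×88, 4×4×44,
and 2×2×21. These temporal lengths are derived from the kernel arithmetic
and asserted programmatically at build time; no standard padding convention
produces an intermediate temporal length of 46 for this input, so the
implementation treats all shapes as derived, never hard-coded.

TAP collapses time in two stages: spatial attentive pooling multiplies the
2×2×21×64 feature elementwise by a trainable tensor φ (initialized to ones)
and sums over space, giving a 21×64 summary; a channel-collapsing FC
(64 → 1 per time step) followed by a time-mixing FC (21 → 21) and a softmax
yields the temporal attention, and the attended sum over time returns a
2×2×64 feature. The two-stage FC is a design choice for the
under-specified "classified by an FC layer" step: it consumes the channel
dimension and realizes a t→t mapping with softmax over t. Uniform attention
reduces TAP to temporal averaging and one-hot attention to slicing — both
limits are tested, and the full layer is verified index-by-index against a
loop-based oracle and by central finite differences (relative error ≤ 1e-4).

The head is FC(256→64) → batch norm → ReLU → dropout(0.5) → FC(64→2) →
softmax. Training minimizes cross-entropy plus L2 (factor 0.01) on all FC
kernels and biases (including TAP's FCs), with Adam at learning rate 0.001,
batch size 32, uniform Glorot initialization, and per-run re-initialization
from the seed. Adam and the 0.5 dropout rate are the package's choices where
the protocol leaves the optimizer and rate open. The evaluation protocol
holds out a stratified 10% of windows once, then repeats 5-fold partitions
of the remaining 90% with fresh initializations; every fold's model is
scored on the fixed holdout and summarized as mean ± SD and max per repeat.
Window-level splitting follows the emulated protocol (windows of one subject
may span train and validation); `make_splits()` also supports subject-level
stratification via its `labels` argument for leakage-safe designs.

The whole network is implemented directly in R: convolutions as precomputed
im2col index gathers plus BLAS matrix products, with the backward scatter as
a precomputed sparse matrix. Batch-norm backward distinguishes training mode
(batch statistics are functions of the input) from evaluation mode (running
statistics are constants) — the latter matters for Grad-CAM, which
back-propagates a class logit through the evaluation-mode network and weights
each channel of the chosen layer by its average gradient before the ReLU-
rectified channel sum.

## The synthetic-data generator

No public recording of the emulated protocol exists, so validation rests on
synthetic cohorts with planted structure:

* **Cohort layout**: 8 experts and 13 novices, 3 trials each; per trial a
  rest-like pre-trigger segment (30 s default, enough for ASR calibration),
  180 s of task, 120 s of rest, a `start` event at task onset, 32 channels
  at 500 Hz.
* **Signal**: a piecewise-constant microstate sequence (dwell uniform
  50–150 ms — the typical literature range) draws prototypes from a bank of
  smooth unit-norm topographies; the first bank entry is left
  lateral-posterior and the second a right-frontal/occipital dipole, the two
  classes whose balance differs between skill groups. Group weighting
  applies during the task (defaults: 0.40 on the own prototype, 0.05 on the
  other group's); rest segments use uniform weights. The active prototype is
  scaled by a 4–20 Hz band-limited oscillation under a slow positive
  envelope, so GFP peaks mark stable topographies as in real EEG.
* **Noise**: 1/f (exponent 1) sources mixed through ten smooth random scalp
  fields — spatially correlated, as volume conduction makes real EEG — plus
  an 8% independent sensor-noise floor, scaled to the requested SNR (0 dB
  default, defined on average-referenced broadband power); 60 Hz line noise
  with per-channel amplitude and phase jitter; optional bad channels
  replaced by high-amplitude uncorrelated noise.

The tensor-level generator (`simulate_tensor_dataset()`) plants a smooth
oscillatory component confined to one grid quadrant on top of smooth
background fields, for exercising the CNN branch without the full
acquisition path. Its `transient` mode gives both classes equal whole-window
energy in the planted component — experts as a 20% burst, novices sustained —
which makes whole-window variance features (CSP's log-variances) blind by
construction while temporally resolved features still separate the classes.

What the generator does **not** emulate: ocular and muscle artifacts beyond
amplitude bursts, biophysical forward modelling from cortical sources,
nonstationary microstate syntax, inter-subject montage variation, and
electrode drift. Passing tests therefore demonstrate the pipeline's
correctness and its sensitivity to planted topographic structure — not
expected accuracy on clinical recordings.

## Problem sizes used by tests and the acceptance script

Simulation sizes are chosen so the whole suite runs comfortably on a single
CPU while every claim is still measured, not assumed: cohort runs for the
CSP branch use 4+4 subjects × 2 trials of 15 s task at 10 dB SNR with
disjoint prototype weights (the high-SNR regime in which near-perfect
hold-out separation is expected); CNN runs use 160–240 tensors of the full
16×16×360 shape trained for 10–15 epochs with a strong planted signature;
structural counts of the full protocol (63 recordings, 180 windows/trial,
11,340 tensors, 1,134 holdout windows) are computed by running the package's
own cohort and windowing machinery on full-length spans without
materializing full-scale tensor arrays. Label-permutation controls average
8–12 permutations (CSP) and score 120 held-out windows (CNN) so that chance
level is estimated with a standard error below 0.05.

## Known limitations

* The CSP branch assumes two classes; multi-class extensions are out of
  scope.
* ASR is the offline Euclidean variant; Riemannian and online/RLS variants
  are not implemented.
* Biharmonic interpolation is exact at electrodes but, like any scattered
  interpolant, unreliable outside the electrode hull — hence the zero mask.
* The CNN implementation favours clarity and testability over speed; it is
  adequate for the package's reduced-scale protocols but not tuned for
  full-scale (11,340-tensor, 200-epoch) training on a single CPU.
* Microstate model selection inherits the CV criterion's known small-K bias
  on very noisy data; the K = 2…8 scan bounds the damage.
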