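---
title: "Holographic flow cytometry in silico: models, reconstruction and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holographic flow cytometry in silico: models, reconstruction and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`holocyte` is an end-to-end, fully synthetic test bench for label-free
cell classification with off-axis digital holographic microscopy in
flow. It covers the whole chain a holographic flow cytometer needs in
software: rendering interference patterns of transparent cells
(quantitative phase phantoms), reconstructing quantitative phase maps
(QPMs) from those holograms, extracting a 12-feature
morpho-textural-phase descriptor per cell, analysing and selecting
features, and classifying two unbalanced cell populations with eight
classical models and a compact convolutional network.

The package simulates an ovarian-cancer-versus-monocyte discrimination
setting: a majority population of larger-phase-delay cancer-like cells
("OC") and a minority of monocyte-like cells ("MONO") at a ratio of
roughly 6.36 cancer cells per monocyte (2550 and 401 cells at full
scale, 2951 phase maps in total), split 97.3%/2.7% into training and
holdout test sets. Because no raw holographic recordings of the real
experiment are publicly deposited, every quantity the package reports
is computed on synthetic data; the phantom generator is therefore a
first-class, tested component, not a fixture.

# The synthetic scene

## Cell phantoms

A cell is modelled as a smooth, compactly supported, non-negative phase
bump: on the ellipse with semi-axes $a$ (`radius_px`) and $a/\mathrm{AR}$
(aspect ratio $\mathrm{AR} \ge 1$), the profile is

$$\varphi(\rho) = \varphi_{\max}\cos^2\!\big(\tfrac{\pi}{2}\rho^{m}\big),
\qquad \rho \le 1,$$

with elliptical radius $\rho$ and flatness order $m$ (default 4: a flat
top with a steep but $C^1$-smooth rim, vanishing exactly at the support
boundary). Internal structure is added as a band-limited Gaussian
random field (correlation length `texture_correlation_px`, default 9 px)
scaled by `texture_amplitude_rad` and by the envelope, so texture fades
at the rim and the map stays non-negative. The texture field lives in
cell-local coordinates: translating a cell translates its texture with
it, which makes the extracted features translation-invariant on clean
data. This is the simplest shape that exercises all twelve descriptor
features; it does not attempt biophysical realism (no refractive-index
model, no organelles, no membrane fluctuations).

## Population model and the separation knob

The two class-conditional phantom distributions overlap deliberately in
morphology (radius $\sim \mathcal N(40, 5^2)$ px truncated to [22, 58],
aspect ratio $1 + |\mathcal N(0, 0.22^2)|$ capped at 1.7) and in texture
(amplitude $\sim \mathcal N(0.22, 0.04^2)$ rad). A single scalar
`separation` $s \in [0, 1]$ moves only the peak phase delay apart:
$\varphi_{\max} \sim \mathcal N(1.8 \pm 0.5\,s,\ 0.15^2)$ rad (OC high,
MONO low). At $s = 0$ the populations are exchangeable; at the default
$s = 1$ the discriminative signal is concentrated in the
quantitative-phase statistics, which reproduces the qualitative
structure of the real experiment: weak natural clustering of the
feature cloud, and a consistent accuracy drop when the QPI feature
group is removed. The phase-delay range (roughly 1–2.5 rad peak at
488 nm) is a nominal choice for suspended cells of ~8 µm diameter at
0.1 µm/px sampling; the true phase and size distributions of either
cell line are not publicly tabulated, so these defaults are plausible
rather than calibrated.

## Hologram formation

The scene renders each phantom into an off-axis hologram as

$$I = \big|\,\mathcal P_z[\mathrm e^{i\varphi}]\cdot
\mathrm e^{iA}\cdot s_{\mathrm{spk}} + R\,\big|^2 + n,$$

where $\mathcal P_z$ is angular-spectrum propagation by the true
defocus $z$ (drawn uniformly from `defocus_range_um`), $A$ a low-order
polynomial aberration phase shared by the whole dataset (defaults
$0.6x - 0.4y + 0.8x^2 + 0.6y^2 + 0.4xy$ rad on [-1, 1]-normalised
coordinates: a realistic ~1.5 rad of tilt, astigmatic defocus and
field curvature), $s_{\mathrm{spk}} = \sqrt{1-c^2} + c\,g$ a
unit-power multiplicative speckle field ($g$ a smoothed complex
Gaussian field, contrast $c$ default 0.1), $R$ a tilted plane
reference wave with carrier (0.30, 0.30) cycles/px, and $n$ additive
shot noise (1% of the mean intensity). A cell-free reference hologram
with the same carrier and aberration (and an independent speckle
realisation) accompanies every dataset. The carrier default keeps the
+1 order, its passband and the DC term well separated on a 512-px
frame while staying below Nyquist.

All randomness flows from the single `seed` in `scene_config()`;
dataset generation is bit-reproducible.

# Reconstruction

The per-frame chain in `reconstruct_qpm()` is: Tukey apodization
(taper 0.2) → carrier location (strongest off-DC peak in the
$f_x > 0$ half-plane) → demodulation (integer-bin spectrum shift, a
circular low-pass of radius half the carrier magnitude, and removal of
the residual sub-bin tilt) → reference-phase compensation →
Tamura-guided autofocus → propagation to focus → congruent
least-squares unwrapping → adaptive denoising → segmentation, background
zero-referencing and centred cropping.

Two ordering choices deserve comment.

**Tilt removal before propagation.** The estimated carrier is accurate
only to one FFT bin; the residual sub-bin tilt is estimated from the
mean wrapped phase gradient and removed in the spatial domain *before*
refocusing, because a tilted field walks laterally under propagation
(at 60 µm defocus a half-bin tilt displaces the cell by several
pixels, which would misregister the reconstruction).

**Compensation before refocusing.** The shared aberration phase is
subtracted (via the demodulated reference field) at the collection
plane, and the autofocus then runs on the compensated field.
Back-propagating through the uncorrected aberration instead treats its
quadratic part as a weak lens: it refocuses and laterally displaces
the cell, which in our experiments inflated the in-support phase RMSE
by a factor 2–4 and biased the autofocus by 1–2 µm. The exported
`compensate()` operation itself is plane-agnostic (a wrapped phase
subtraction of two fields).

**Autofocus.** The Tamura coefficient
$\mathrm{TC} = \sqrt{\sigma(A)/\bar A}$ of the amplitude image is
*minimised*: an in-focus pure-phase object has minimal amplitude
contrast. The metric is evaluated on the central 60% of the field
(the apodization taper carries focus-independent contrast), on a
coarse grid (default 5 µm step) computed on a 2x-decimated copy of the
field for speed, followed by golden-section refinement at full
resolution (tolerance 0.25 µm). On noise-free synthetic data the found
focus agrees with the ground-truth defocus to well under 1 µm.

**Unwrapping.** The least-squares phase surface is obtained from the
wrapped gradients by the DCT-based discrete Poisson solver (Neumann
boundaries), then projected onto the congruent lattice: each output
pixel equals the wrapped input plus the nearest multiple of $2\pi$ to
the least-squares surface. The output therefore satisfies the
congruence contract `wrap(output) == input` at every pixel, and on
residue-free inputs it is exact up to one global $2\pi k$. The residue
density (fraction of elementary plaquettes with nonzero circulation)
is attached as a quality flag; above 1% the smooth surface is
unreliable and the flag is raised (the congruence contract still
holds).

**Denoising.** The noise level is estimated as the MAD of the
difference between the map and its 3x3 median. Below 0.01 rad the map
is returned untouched, so clean reconstructions are never degraded;
above it, a 3x3 median pass (vectorised selection network) removes
speckle spikes and a mild Gaussian ($\sigma$ = 0.8 px) removes the
remaining grain. Both stages preserve the in-mask mean to well within
1%.

**Segmentation.** The threshold is the background median plus
`max(0.1 rad, 5% of the 99th-percentile-above-background)`; a plain
Otsu threshold was rejected because it bisects the smooth rim of a
flat-topped cell and underestimates the support area by ~35%, whereas
the low-fraction threshold tracks the true support within 10%. An
apodization-wide border margin is excluded (the tapered region carries
meaningless phase), holes are filled, the largest 8-connected
component wins (the tie-break for multi-blob frames), and a square
crop (default 384 px, 192 px in the scaled runs) is cut centred on the
integer centroid, zero-padded at frame borders. Frames with no
component above 50 px are skipped and logged, never silently dropped.

# The 12-feature descriptor

Three groups, computed per crop on the mask/phase pair:

* **morphological** — area (pixel count), eccentricity
  ($\sqrt{1-(b/a)^2}$ of the second-central-moment equivalent ellipse,
  with the 1/12 pixel-variance term), perimeter (length of the
  8-connected outer boundary polygon through pixel centres; a
  $k \times k$ square gives $4(k-1)$, pinned by a regression test);
* **texture** — homogeneity $\sum_{ij} P_{ij}/(1+|i-j|)$, energy
  $\sum P_{ij}^2$ and entropy $-\sum P_{ij}\log_2 P_{ij}$ of the
  grey-level co-occurrence matrix (in-mask values linearly quantised
  to 8 levels over their min–max range, horizontal offset (0, 1),
  symmetrised, both-pixels-in-mask pairs only), plus skewness and
  kurtosis;
* **QPI** — maximum, minimum, mean and population standard deviation
  of the in-mask phase values (radians; no conversion to optical path
  delay — only a scale factor, and all learners handle scaling).

Skewness and kurtosis are conventionally listed with the GLCM texture
block, but they are not standard co-occurrence statistics; by default
they are computed as the standardised third and fourth central moments
of the in-mask phase distribution (kurtosis non-excess: Gaussian → 3),
with a config switch (`texture_on = "glcm"`) that instead derives them
from the GLCM marginal, since the original attribution is ambiguous.
The GLCM level count and offset are likewise unstated upstream; 8
levels and the distance-1 horizontal offset are common defaults and
configurable.

# Feature analysis and selection

`kendall_matrix()` computes tie-corrected Kendall $\tau_b$ with
two-sided p-values for every feature pair (exact tail for small
tie-free samples, normal approximation with tie correction otherwise,
via `stats::cor.test`); rank correlation is appropriate because several
features are grossly non-normal. `prune_features()` then removes, among
pairs with $|\tau| > 0.9$ and $p < 0.05$, the member with the larger
mean absolute correlation against the remaining features, iteratively
and deterministically (ties broken toward the later feature in
canonical order); the procedure is idempotent. On the real data this
pruned exactly one feature (kurtosis, against skewness); on synthetic
data the number pruned depends on the generator and is not constrained.

`relief_rank()` implements ReliefF: min–max scaled features, Manhattan
distances, k = 10 nearest hits and misses (k = 1 recovers original
Relief, which is what the hand-computed oracle in the tests checks),
all instances used by default. `embed_pca()` standardises columns
first (the descriptor mixes pixels, radians and dimensionless ratios);
`embed_tsne()` wraps seeded Barnes–Hut t-SNE (perplexity 30 by
default).

# Classical classification

`holdout_split()` draws the 97.3/2.7 holdout split, stratified, with
round-half-up sizing and largest-remainder per-class allocation
(N = 2951 at 2.7% gives exactly 80 test rows). By default the split is
grouped by cell so the 1–4 frames of one cell never straddle the
boundary (frame-level splitting is available via a flag, since the
original protocol is silent on this; grouping is the conservative
choice against leakage).

The eight models mirror common preset semantics: decision trees with
at most 100/20/4 splits (implemented as `rpart` with cost-complexity
pruning off and depth `ceil(log2(splits+1))`), LDA and QDA, and
polynomial SVMs of degree 1/2/3 (`e1071::svm`, standardised features,
box constraint 1, `coef0 = 1`). Validation accuracy is the mean
held-out-fold accuracy of a stratified 10-fold cross-validation; the
reported model is refit on all training rows. `ablation_study()` runs
the 4 feature configurations (all, no-morphological, no-texture,
no-QPI) x 8 models x {validation, test} grid, applying correlation
pruning before grouping. No class rebalancing or cost weighting is
applied — training on the unbalanced set is deliberate, mirroring the
rare-event regime the method targets.

# The compact CNN

No deep-learning framework is assumed: the package ships a small CNN
engine in vectorised base R (BLAS matrix products plus precomputed
gather indices; analytic gradients verified against finite differences
in the test-suite) with inverted-residual bottleneck blocks (1x1
expansion → 3x3 depthwise → linear 1x1 projection, shortcut exactly
when stride 1 and equal channel counts), ReLU6 or hard-swish
activations, an optional squeeze-and-excite gate, and a ResNet-style
basic-block variant. Phase crops are block-averaged to 96 x 96 and fed in radians — the
values are naturally order-one, and keeping the fixed physical scale
(rather than per-image standardisation) preserves the quantitative
phase magnitude that carries the class signal.

The default architecture is deliberately small (a stride-2 stem of 8
channels, a fixed 2x2 average pool, stages of 16/32/64 channels with
expansion 4, ~53k weight parameters): pretrained backbones are out of
scope (no downloads), and a from-scratch network of this size trains
in minutes on one CPU core while still exercising the full protocol —
5-fold stratified cross-validation, 10 epochs, batch 16, Adam
($\beta = (0.9, 0.999)$, no weight decay, no schedule) at learning
rate $10^{-4}$, cross-entropy loss. Training is bit-deterministic
given the seed. Holdout-test evaluation uses the fold model with the
best validation accuracy (whether the original protocol averaged fold
models or refit one is unstated).

# Numerical and testing notes

* Coordinates: row index = y, column index = x; frequencies in
  cycles/px (FFT ordering); propagation in object-plane micrometres
  with the derived pixel `camera_pixel_um / magnification`.
* Degenerate inputs: constant in-mask values give the single-bin GLCM
  (homogeneity 1, energy 1, entropy 0) and zero-variance
  skewness/kurtosis flagged as 0; constant feature columns are
  excluded from correlation with a flag; a spectrum without a
  prominent off-axis peak raises a "no carrier" error.
* Problem sizes: the test-suite and the acceptance script run the
  reconstruction-fidelity property on 50 noise-free 512-px frames at
  +/-60 µm defocus, and the learning half on an N = 600-cell dataset
  (518:82, ~6.36:1) rendered at 256 px with 192-px crops, +/-35 µm
  defocus, speckle contrast 0.1 and 1% shot noise. Frames smaller than
  512 px cannot hold the laterally walking high-frequency content of
  strongly defocused cells (a component at spatial frequency $f$
  displaces by $z\lambda f$), which is why the fidelity property keeps
  the full frame while the classification runs, which only need the
  low-frequency phase statistics, use the smaller frame.
* What passing tests show — and what they do not: the synthetic bench
  validates the reconstruction mathematics exactly and the learning
  chain's behaviour qualitatively (signal in the phase statistics ⇒
  QPI features dominate; no separation ⇒ chance-level accuracy). It
  does not validate biological realism: real cells have
  refractive-index microstructure, motion blur, coherent artefacts and
  inter-sample variability that no low-parameter phantom reproduces,
  so real-data accuracies cannot be inferred from the synthetic ones.

# Known limitations

* The phantom is a single smooth blob; clusters, debris and
  overlapping cells are not simulated, so the largest-component rule
  is never stressed by realistic confluence.
* Speckle is modelled as a smoothed multiplicative complex Gaussian
  field; real speckle from coherent stray reflections is neither
  Gaussian nor stationary.
* The least-squares unwrapper is exact only on residue-free maps; at
  high residue density it returns a congruent but possibly blocky
  surface (flagged).
* The CNN engine is CPU-bound R; it is meant for protocol-faithful
  experiments at desk scale, not for large-scale training.
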