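---
title: "Radiomics texture maps and CNN-ViT ensembles for volumetric CT: methods"
author: "radct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics texture maps and CNN-ViT ensembles for volumetric CT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radct)
```

# The problem

Diffuse interstitial lung diseases such as pulmonary sarcoidosis lack a
well-defined lesion boundary on chest CT, which makes the usual radiomics
workflow — segment a region of interest, extract descriptors from it —
awkward or impossible. `radct` implements an ROI-free alternative: compute
*per-voxel* Haralick texture maps over the whole volume, let a random
forest decide which map carries the class signal, and feed that map
together with the CT volume into a two-branch deep ensemble (a 3D CNN for
local structure, a 3D vision transformer for long-range context) fused
before a sigmoid classification head. The package's positive class (label
1) is the diffuse-texture, sarcoidosis-like condition; label 0 is the
focal-nodule, lung-cancer-like condition.

Everything is testable at desk scale through a synthetic phantom
generator, so no clinical data are required to exercise, validate or
extend any stage.

# Preprocessing

`preprocessVolume()` center-crops the axial plane (the central 75% of each
in-plane axis by default — the crop fraction is a package choice, exposed
as `cropFraction`, since only the intent "focus on the lung region" is
fixed), clips intensities to the lung window of (−1000, 400) HU, and
resamples trilinearly to a target grid, 256 × 256 × 64 by default.
Clipping precedes resampling so interpolation cannot manufacture values
outside the window. Trilinear interpolation is used because it is the
standard deterministic choice for CT resampling; constant volumes are
resize-invariant, which keeps degenerate fixtures meaningful.
Min–max normalization maps each volume (or texture map) to [0, 1]; a
constant array maps to zeros rather than NaN so that synthetic degenerate
inputs stay usable.

# Haralick texture maps

For every voxel, a cubic window (edge 3 by default) is quantized into `G`
equal-width gray-level bins and a symmetric, normalized gray-level
co-occurrence matrix (GLCM) `p(i, j)` is accumulated for each of the 13
unique 3D offset directions at distance 1. The eight statistics

* Energy = Σ p², Entropy = −Σ p log₂ p, Inertia = Σ (i−j)² p,
  InverseDifferenceMoment = Σ p / (1 + (i−j)²),
* Correlation = (Σ i j p − μ²)/σ², ClusterShade = Σ (i+j−2μ)³ p,
  ClusterProminence = Σ (i+j−2μ)⁴ p,
* HaralickCorrelation = (Σ i j p − μ_t²)/σ_t²,

are evaluated per offset and averaged across the 13 directions
("one feature map per texture feature" with no preferred direction), with
borders handled by edge replication so maps are full-size.

Numerical and definitional choices worth knowing:

* **Quantization.** `bin = floor(G (x − lo)/(hi − lo))`, with `x = hi`
  mapped to `G − 1`; `G = 32` by default. The bin range is the volume's
  own range unless `quantizeRange` fixes it; the pipeline fixes it to the
  lung window so bins are comparable across volumes, which is the usual
  radiomics practice for HU data. Quantization is computed once per
  volume for determinism and speed; a per-window mode
  (`perWindowQuantize = TRUE`) exists as a slow reference for fidelity
  experiments.
* **HaralickCorrelation.** For a *symmetric* GLCM, defining μ_t/σ_t² as
  the moments of the gray-level index under the marginal p_x makes
  HaralickCorrelation algebraically identical to Correlation (both reduce
  to Cov/Var). The package therefore follows the ITK texture-feature
  convention, where μ_t and σ_t² are the mean and population variance of
  the *values* of p_x across its G bins (so μ_t = 1/G). This keeps the
  two maps genuinely distinct — HaralickCorrelation grows with the
  gray-level spread of the neighbourhood and its co-occurrence cross
  moment, with the large dynamic range familiar from ITK output — and is
  almost certainly what any ITK-based texture pipeline computes under
  this name.
* **Degenerate windows.** A constant window has zero index variance, so
  Correlation returns 0; a marginal that is uniform across all G bins has
  zero bin-value variance, so HaralickCorrelation returns 0. Air and
  padded background make both cases common, and 0 keeps the maps finite.
* **Texture input.** Maps are computed on window-clipped intensities by
  default (`textureOnClipped`), since the clip range also defines the
  quantization range; raw-HU computation is one flag away.

Every per-voxel value is covered by a from-scratch oracle in the test
suite (naive window extraction, exhaustive pair counting, double-loop
feature sums).

# Patch features and map selection

Each of the 8 maps is divided into non-overlapping cubic patches (16³ at
full scale; trailing voxels are discarded). Patch mean and standard
deviation of each map give a 16-element feature vector per patch, and
every patch inherits its volume's label. A random forest with 100 trees
is fitted in a k-fold (default 5) cross-validation, and the mean decrease
in Gini impurity — the forest's per-tree importance averaged over trees —
is recorded per fold. Folds are split at *volume* level so patches from
one subject never leak across the train/validation boundary (patch-level
splitting is available behind `foldBy = "patch"`). The per-map score is
the sum of the map's mean-column and sd-column importances, and the map
with the maximal score becomes the radiomics input channel. On the
package's phantom cohorts this procedure selects HaralickCorrelation,
consistently with the qualitative outcome reported for clinical ILD
data.

# The ensemble architecture

`EnsembleConfig()` carries the full-scale defaults:

* **CNN branch** — 7 convolution blocks, each 3D convolution → ReLU →
  batch normalization. The published description lists 7 blocks but six
  filter widths (16, 32, 64, 128, 256, 512); the package resolves this as
  one stride-1 block (kernel 3³) at width 16 followed by six stride-2
  downsampling blocks (kernel 4³) at the six widths, which honours both
  statements and yields a valid shape chain for 256 × 256 × 64 input
  (down to 4 × 4 × 1 × 512). Global 3D average pooling and a fully
  connected layer produce a 768-long feature vector. The conv → ReLU → BN
  ordering follows the architecture description verbatim even though
  conv → BN → ReLU is more common; `bnAfterRelu = FALSE` swaps it.
* **ViT branch** — non-overlapping 16³ patches (a 16 × 16 × 4 token grid
  for the default anisotropic input), linear patch embedding, a learned
  classification token and learned per-index position embeddings, then 12
  pre-norm transformer blocks with hidden dimension 768, 6 attention
  heads and an MLP ratio of 4. The output is the final class-token
  embedding; the token/pooling scheme is unstated in the source
  description, and the class-token design is the standard one. Per-layer
  head-averaged attention matrices are retained for explanation (full
  head-wise tensors are kept too; at full scale, retaining only the
  head-wise tensors of a forward pass costs several gigabytes, which is
  why rollout consumes the head average).
* **Fusion** — the two feature vectors are concatenated (768 + 768 =
  1536) into a fully connected sigmoid head. `fusion = "cnn_only"` /
  `"vit_only"` realize the single-branch ablation variants.

There is no deep-learning runtime in the package's dependency set, so the
layers, backpropagation and AdamW are implemented natively (R with C++
convolution kernels). Every gradient path is finite-difference checked in
the tests, in both evaluation and batch-statistics mode; forward passes
are deterministic for fixed weights, and weight initialization (He for
convolutional/ReLU paths, N(0, 0.02) for transformer parameters) is fixed
by the construction seed.

# Training and evaluation

Training uses binary cross-entropy with AdamW. Full-scale defaults follow
the published recipe — learning rate 1e-5, 50 epochs — with batch size 2
(unstated in the source; chosen for memory reasons and configurable).
Augmentation applies, each independently with probability 0.5, a random
flip, random Gaussian noise (sd drawn from (0, 0.05) on normalized
intensities), and a random affine transform (rotation up to ±10° about
the axial axis, isotropic scale 0.9–1.1), parameter ranges after the
common medical-augmentation defaults; spatial transforms share one
displacement across input channels, and every resolved value is persisted
in the pipeline's run configuration.

Cross-validation is stratified at volume level with a fixed seed (the
stratification scheme is the package's choice). Confusion matrices use a
0.5 decision threshold; sensitivity, specificity, precision, accuracy and
F1 follow the standard formulas with a positive class of "diffuse
texture / sarcoidosis-like", and metrics with zero denominators are
reported as NA. The *combined AUC* is the trapezoidal AUC of a single ROC
built from out-of-fold scores pooled across folds (per-fold AUCs and
metrics of the pooled confusion counts are reported alongside, since
"mean of fold metrics" and "metrics of pooled counts" are both
defensible summaries). The pooled AUC equals the normalized Mann–Whitney
U statistic, which the tests assert to 1e-10. The five-variant ablation
harness (CT-ViT, CT-CNN, CT-CNNViT, Rad-CNNViT, RadCT-CNNViT) reuses one
fold assignment across variants so they are directly comparable.

**Desk-scale problem sizes.** The package's experiments and tests run on
32 × 32 × 16 phantoms with the reduced configuration (CNN widths 8/16,
feature dimension 64, ViT patch 8, depth 2, dimension 64, 4 heads) and
the reduced recipe (learning rate 1e-3, 12 epochs, batch 8) on cohorts of
30 volumes per class under 3-fold cross-validation. These sizes were
chosen as the smallest at which the two-channel ensemble separates the
easy-regime phantom classes essentially perfectly; the learning rate is
higher than the full-scale default because the reduced network and the
easy synthetic task tolerate — and converge much faster with — larger
steps.

# Explainability

* **HiResCAM** (CNN branch): the gradient of the raw class score (the
  pre-sigmoid logit for class 1, its negation for class 0) with respect
  to a chosen feature layer is multiplied element-wise with the
  activations and summed over channels, Ã = Σ_f (∂s_m/∂A ⊙ A)_f. The
  target layer defaults to the output of the last convolution block; no
  rectification is applied to Ã (the definition has none), raw signed
  values are retained, and display normalization is per-volume min–max.
* **Attention rollout** (ViT branch): R₁ = norm(A₁ + I),
  R_L = norm(A_L + I) R_{L−1}, with A_L the head-averaged attention of
  layer L. The recursion as printed in the source description omits row
  renormalization; the package renormalizes by default (the original
  rollout formulation, which keeps every R_L row-stochastic and
  interpretable as attention flow) and preserves the raw product behind
  `renormalize = FALSE`. Saliency is read from the class-token row over
  patch tokens — the readout is unstated in the source and this is the
  convention the class-token design implies — reshaped to the patch grid
  and upsampled trilinearly.

Both operators are checked against closed forms, explicit product
oracles and finite differences. `overlaySlice()` blends a grayscale CT
slice with the color-mapped saliency at a configurable alpha.

# Synthetic phantoms

`makePhantom()` emulates the two study conditions:

* *diffuse_texture* (label 1): a correlated Gaussian random field
  (smoothed white noise) with correlation length 2.5 voxels, raised 350
  HU above the background mean of −800 HU — a surrogate for the raised
  attenuation and correlated texture of diffuse infiltrates.
* *focal_nodule* (label 0): a weakly correlated background field
  (correlation length 2.2 voxels) at −800 HU plus two spheres of radius
  4 voxels and +650 HU contrast with a soft sigmoid edge — a surrogate
  for focal lesions. The sphere mask is returned for localization tests.

Both fields are normalized to the same *local contrast* (adjacent-voxel
difference sd, 50 HU), so the correlation length controls the
arrangement of gray levels rather than their local spread; white noise of
45 HU (about one gray-level bin under the lung-window quantization) is
added to both classes. Field tails may exceed the lung window, just as
real thoracic CT exceeds it at bone and air; the preprocessing clip
brings every consumer's input into the window. Under these defaults the
volume-mean
HaralickCorrelation separates the classes completely (the margin grows
with the diffuse correlation length over the calibrated range), which
guarantees that the downstream selection and classification tests are
well-posed, and an `effect`-style "hard" regime (smaller shift and
contrast, more noise) is available for ablation-ordering experiments.

What the phantoms deliberately are *not*: anatomically realistic lungs.
There is no airway/vessel structure, no scanner protocol variation, no
slice-thickness anisotropy effects, and the class difference is designed
to be recoverable. Passing tests therefore demonstrate correctness of the
machinery — texture mathematics, selection logic, optimization,
evaluation — not clinical performance; headline clinical metrics from any
real cohort are out of reach of this package's data and are not claimed.

# Known limitations

* Training at the full 256 × 256 × 64 scale is functional but slow on
  CPU; the package's own experiments are desk-scale by design.
* The DICOM reader covers explicit-VR little-endian uncompressed series
  only — enough for the supported round-trip and rescale semantics, not
  a general DICOM implementation.
* The statistical comparison between ablation variants (significance
  testing) is intentionally not implemented; the harness reports the
  metric table and pooled ROCs only.
* Haralick transform-based (wavelet/LoG) texture families are out of
  scope.
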