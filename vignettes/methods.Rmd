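---
title: "Micro-expert ensembles with variance-based uncertainty: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-expert ensembles with variance-based uncertainty: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Multi-class classification of grayscale medical images under a hard
complexity budget: the whole model must stay around 0.05M parameters,
0.18 GFLOPs per image and 0.2 MB serialized, so it can run on CPU-only
edge hardware, while still flagging its own unreliable predictions.

`microexperts` meets this with an ensemble of five micro convolutional
networks, each specialized for one feature family by its input operators
and small architectural changes, fused by confidence weighting and scored
for uncertainty by cross-expert variance. One forward pass per expert is
the entire inference and uncertainty budget — no sampling, no dropout
ensembles, no conformal machinery.

### The base network

Three convolutional blocks with channel plan 16/32/64 (3×3 kernels, batch
norm, ReLU, 2×2 max-pooling), global average pooling and a fully connected
softmax head. With plain 3×3 convolutions this plan costs about 26k
parameters — incompatible with the ~10k per-expert budget, which we treat
as binding. Blocks 2 and 3 therefore use depthwise-separable convolutions
(depthwise 3×3 followed by pointwise 1×1), the standard substitution that
preserves the channel plan and kernel size; the base lands at 6,120
parameters and 0.0228 GFLOPs for a 224×224 input.

### The five experts

* **texture** — input is the raw channel plus 12 Gabor responses
  (orientations 0°/45°/90°/135°, wavelengths 2/4/8 px, ψ = 0, γ = 0.5,
  σ = 2). The bank both feeds fixed input channels and initializes the
  first convolution (center 3×3 crops of the matching kernels on the
  matching channels), which stays trainable. An extra 3×3 convolution to 8
  channels refines texture features. With 13 input channels a stride-1
  first convolution would cost 94M MACs, far over the per-expert compute
  budget, so the first convolution uses stride 2.
* **shape** — raw plus Sobel Gx/Gy channels; a deeper (32-channel) first
  convolution, again stride 2 for the same budget reason; the 32-d global
  average of block 1 is concatenated with the final 64-d vector before the
  head ("skip connection to the final layer" realized without any spatial
  size conflict).
* **intensity** — the input is adaptively histogram-equalized; a 1×1 first
  convolution (16 channels) and a micro dense block (two depthwise-
  separable 3×3 convolutions with growth 8, each consuming the
  concatenation of prior outputs).
* **spatial** — dilation rates 1, 2 and 3 across the three convolution
  layers; a 1×1-projected residual connects the block-2 output to the
  block-3 output (projection chosen over zero-padding so the residual is
  learnable; +2,112 parameters, still within budget).
* **multiscale** — spatial pyramid pooling (1×1, 2×2, 4×4 grids) on the
  block-2 output; the 21-bin pyramid passes through a 1×1 convolution (32
  channels) and squeeze-excitation channel attention (reduction 4), is then
  averaged over bins and concatenated with the block-3 global average
  before the head. Averaging over bins is our choice: concatenating all
  672 pyramid values would make the head alone cost 29k parameters.

All five land between 6.0k and 9.0k parameters and 0.017–0.030 GFLOPs;
the ensemble totals 40,792 parameters, 0.115 GFLOPs, 0.163 MB.

### Fusion and uncertainty

Weights are normalized row maxima of the expert probability matrices;
fusion is the convex combination of the rows. The uncertainty score is the
mean over classes of the **population** variance (divisor 5) of the five
per-class probabilities. The population divisor is deliberate: its
supremum for five experts is 0.24 per class, matching the "approximately
0.25" ceiling usually quoted for uniform disagreement, whereas the sample
variance (divisor 4) tops out at 0.30. Band boundaries 0.02 and 0.04 are
both assigned to the medium band (a closed interval — the printed range
"0.02–0.04" read literally; the boundaries have measure zero in practice).

## Numerical conventions

* **Convolution** in the networks and in the Sobel operator is
  cross-correlation (the CNN convention); this is what makes an increasing
  unit ramp produce +8 under the Sobel x-kernel. The exported
  `dilated_conv()` instead implements the textbook definition
  `(I *ℓ k)(x,y) = Σ I(x−ℓm, y−ℓn) k(m,n)` exactly (kernel flip, then
  cross-correlation); for learned kernels the two differ only by a
  reflection of the weights.
* **Padding** is mirror (reflect) everywhere, with the mirror axis on the
  border pixel; outputs keep the input's spatial size at stride 1.
* **Gabor kernels** default to 11×11 (odd, ≥ 4σ+1) and are DC-corrected
  (mean subtracted) before use as input operators so constant regions give
  exactly zero response; `gabor_kernel()` itself returns the raw analytic
  kernel. Responses are rescaled per channel by their own maximum absolute
  value, so every input channel lives in [−1, 1].
* **Histogram equalization** is tile-based with bilinear blending between
  tile mappings (clip limit available but disabled by default);
  `tiles = 1` reduces exactly to the global formula
  `I' = floor(CDF(I) · 255)`. The default tile grid follows a ~28-pixel
  tile geometry — 8×8 tiles at 224 px input, 2×2 at 64 px — because a
  fixed tile *count* at small image sizes equalizes tiny neighborhoods and
  amplifies noise into the network input.
* **FLOPs** count one multiply-accumulate of the convolutional and fully
  connected layers as one operation; elementwise normalization, activation
  and pooling are excluded. Every report states this convention. It is the
  only reading under which the budget figures are attainable.
* **Batch norm** affine parameters count toward the parameter budget;
  running statistics do not. Max-pooling and SPP break ties by first index
  (row-major) — irrelevant to values, relevant only to gradients.
* The training engine is a hand-written reverse-mode tape over
  Rcpp/RcppArmadillo kernels (im2col + GEMM convolution with grouped and
  dilated variants, direct-loop depthwise path, pure-GEMM pointwise path).
  Every layer's analytic gradient is finite-difference checked in the
  development suite to ~1e-5 relative error.

## Training recipe

AdamW (learning rate 1e-3, decoupled weight decay 1e-5 on convolution and
fully connected weights only), batch size 32, up to 100 epochs.
Cross-entropy with label smoothing 0.1 and inverse-frequency class weights
(normalized to mean 1, recomputed after oversampling). Mixup with
α = 0.2, one λ ~ Beta(α, α) per batch; both mixed targets are smoothed
first and the loss is the λ-weighted sum of the two terms, keeping the
loss linear in λ. `ReduceLROnPlateau` (factor 0.5, patience 10) and early
stopping (patience 15) both monitor the validation loss in min mode with
tolerance 1e-4 — the monitored metric is not dictated by the recipe, and
validation loss is the conventional choice; the validation F1 is recorded
in the history for inspection. Best weights (and batch-norm statistics)
are restored at the end. Experts train independently: the fusion has no
learned parameters and each expert has its own input pipeline, so nothing
couples their objectives.

Augmentation (flips 50%, rotations ±10°, brightness ±0.2, contrast jitter
0.1, Gaussian noise σ = 0.01) is applied to the raw standardized image
each epoch, *before* the Gabor/Sobel/equalization operators, so the
specialization operators see realistic perturbations. Hue/saturation
jitter is a no-op on single-channel images, so "color jitter" reduces to
contrast. Oversampling duplicates rare-class training records (with
replacement, seeded) up to the 100-sample threshold; duplicates are
re-augmented independently each epoch.

## The phantom generator

The synthetic study sets emulate the statistical shape of a large
multi-class MRI collection: many classes (default 40) with heavy
imbalance (default 8 rare classes whose rarity weights are calibrated in
closed form so each receives ≈60 samples — below the 100-sample
oversampling threshold — at the default 4,000-image size), three
contrast-analogue "modalities" (identity, inversion, gamma), a small
fraction of corrupted all-zero images (default 1%), and a 68/12/20
stratified split whose rounding rule (floor for train, ceiling for test,
remainder for validation, largest-remainder per class) exactly reproduces
the canonical 22,858/4,034/6,724 partition of 33,616 images.

Each image is a 256×256 field: a sinusoidal background texture at the
class's spatial frequency, elliptical lesions with the class's
eccentricity, radius and radial boundary perturbation, and additive
Gaussian noise. Classes differ along exactly the five feature axes the
experts specialize in. Two generator decisions matter for testability:

* Intensity-axis classes carry **mixed-polarity** lesions (alternating
  hyper-/hypointense) rather than a pure global-mean shift. Histogram
  equalization is a rank transform: it erases global level differences by
  construction, so a mean-shift class would be invisible to the intensity
  expert's own preprocessing. Polarity mixture survives any monotone
  remapping and contrast inversion, emulating edema-like contrast
  differentials.
* `generate_axis_pair()` builds two-class sets that differ along exactly
  one axis, with a 20 px reference lesion radius so the cue survives
  downsampling to desk-scale training resolutions. Specialization
  experiments run these under a single contrast analogue (T1-like):
  mixing the inverting T2-like transform makes lesion polarity ambiguous
  with modality, which is a confound for the axis being tested rather
  than part of it.

What the phantoms do **not** emulate: anatomy, partial-volume effects,
bias fields, scanner noise spectra, inter-subject variability, or any
correlation structure between classes. A passing suite shows the
mechanisms work — specialized inputs are learnable by their experts,
fusion is never worse than the weakest expert, disagreement tracks error
and rises under covariate shift — not that any particular clinical
accuracy would be reached on real data.

## Desk-scale experiment sizes

The mechanism checks in the test suite use: 400-image single-axis pairs
(T1-like, 64 px inputs, ≤ 30 epochs with an early exit once training
accuracy reaches 92%) for the five specialization runs; a 2,000-image
5-class set (T1-like, 64 px, every expert trained to mastery — early exit
at 95% training accuracy, at most 25 epochs) for the ensemble,
uncertainty-vs-error and noise-shift checks; and a 500-image
mixed-modality set for the nearest-centroid separability baseline. The
uncertainty-vs-error comparison needs every ensemble member competent: a
member stuck near chance adds cross-expert variance to *correct*
predictions everywhere, while the fused model's errors are confident
consensus mistakes, which inverts the relation — disagreement tracks
difficulty only among experts that agree on the easy cases. The networks end in global
average pooling, so they are resolution-agnostic: training at 64 px uses
the identical parameterization as 224 px, and all complexity figures are
always reported at 224 px. Augmentation is disabled in these runs
(phantom classes are separable without it, and disabling it allows the
expert-input pipelines to be computed once per image).

## Known limitations

* The uncertainty score is a heuristic agreement measure, not a posterior
  approximation; its thresholds (0.02/0.04) were adopted as printed, and
  their calibration on real data is outside what phantoms can establish.
* Batch-norm statistics make training-mode forward passes batch-dependent;
  determinism guarantees apply to a fixed (seed, batch size, data order)
  configuration, and evaluation mode is exactly deterministic.
* The FLOP accountant covers convolution and fully connected layers; for
  these architectures everything else is O(HWC) elementwise work, under
  3% of the total at any input size.
* Single-channel 8-bit inputs only; no DICOM/NIfTI ingestion, no 3-D
  volumes, no quantization or export tooling.
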