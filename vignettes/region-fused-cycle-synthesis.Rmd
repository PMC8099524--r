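---
title: "Region-fused cycle-consistent synthesis of paired medical images and ROI masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-fused cycle-consistent synthesis of paired medical images and ROI masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Medical-imaging studies are chronically short of labelled data: a mammogram
or brain-MRI slice is expensive to acquire, and a tumor region-of-interest
(ROI) mask is even more expensive to annotate. Generative adversarial
synthesis can expand such datasets, but two things decide whether the
synthetic samples are usable: the *structural consistency* between a
synthetic image and a real one, and the availability of a *paired ROI* for
each synthetic image, since most downstream tasks (segmentation training,
radiomics classification) consume image/mask pairs.

`roicycle` implements a cycle-consistent translation model between two
domains — the medical-image domain X and the ROI-mask domain Y — that
additionally *fuses a-priori regional features into the input domain*. The
image is multiplied elementwise with its binary mask to form the *region
image* (tumor intensities only); a small convolutional network, the
regional feature extraction block (RFB), turns this region image into
feature maps that are concatenated with the image as extra channels. The
generator `G : X -> Y` therefore sees, alongside the raw tissue, an
explicit encoding of where the tumor is and what it looks like, which
sharpens the contrast it learns between ROI and non-ROI tissue. A second
generator `F : Y -> X` maps ROI masks back to images, and two
discriminators `D_y`, `D_x` judge realism in each domain.

Both synthesis products come from cycles:

* medical image synthesis: `x -> G(x) -> F(G(x)) ≈ x`;
* ROI synthesis: `y -> F(y) -> G(F(y)) ≈ y`, binarized at a threshold.

Every synthetic image is emitted together with the ROI synthesized from
the same cycle, so the output is always a usable pair.

## Model and objective

The adversarial objective for `G` and `D_y` is the classic saturating GAN
value function

    L_GAN(G, D_y) = E_y[ log D_y(y) ] + E_x[ log(1 - D_y(G(x))) ],

which `G` minimizes and `D_y` maximizes (symmetrically for `F` and
`D_x`). The cycle-consistency term is the per-pixel L1 of both
reconstructions,

    L_cyc = E_x | F(G(x)) - x |_1  +  E_y | G(F(y)) - y |_1,

and the full objective is `L_GAN(G,D_y) + L_GAN(F,D_x) + lambda L_cyc`.
Notes on conventions, each of which is a deliberate choice:

* **Per-pixel L1 normalization.** The cycle norm is written as an
  unnormalized norm in the usual formulation; `roicycle` divides by the
  pixel count so loss magnitudes are resolution-independent and the
  cycle weight means the same thing at 64 px and 256 px.
* **lambda = 10.** The cycle weight is not stated in the formulation this
  package follows; 10 is the published default of the cycle-consistent
  GAN literature and is exposed as `cycle_weight`.
* **Cycle target.** The domain-X input is the fused (image + RFB
  features) grid, but the cycle reconstruction `F(G(x))` is compared
  against the *image channel* only: the generators translate between
  image and ROI, and the fused channels are derived features rather than
  a synthesis target.
* **Saturating generator loss.** Generators minimize
  `log(1 - D(fake))` exactly as written. The common non-saturating
  `-log D(fake)` variant is available behind
  `train_config(non_saturating = TRUE)`.
* **Log clamping.** Discriminator probabilities are clamped to
  `[1e-7, 1 - 1e-7]` inside logs so the objective stays finite when a
  discriminator saturates.
* **Adam with default moments.** "Default parameters" is read literally:
  `beta = (0.9, 0.999)`, learning rate 2e-4, both configurable. 300
  epochs is the default budget of `train_config()`.
* **Batch size 1.** Instance normalization is per-sample and
  per-channel; batch-1 optimization makes train/eval behavior identical
  by construction and keeps the implementation free of batch statistics.
* **Update order.** Per step: `D_x` and `D_y` first (one discriminator
  step per generator step), then `G`, `F` and the RFB jointly. The RFB
  is trained jointly with the generators — it is part of the model, not
  a pretrained front end.
* **Weight initialization.** Gaussian(0, 0.02), the cycle-GAN
  convention; biases zero; instance norm carries no learnable affine.

## Architectures

All three architectures are *declarative specs* (`build_rfb_spec()`,
`build_generator_spec()`, `build_discriminator_spec()`) whose shape
arithmetic is auditable without parameters via `shape_trace()` and
`layer_census()`.

**Generator** (both `G` and `F`): a 3-pixel mirror pad (256 -> 262), four
convolutions — 7x7/32 stride 1, 3x3/64 stride 2, 3x3/128 stride 2
(producing the 128-channel bottleneck at one quarter resolution, 64x64
for a 256 input), 3x3/128 stride 1 — then two stride-2 transposed
convolutions back to full resolution with two fusion layers that
concatenate the encoder features at the half and full resolutions and
merge them with a 1x1 convolution. Each conv block is conv + instance
norm + ReLU. The stated inventory (four convs, two fusions, two deconvs)
and the two printed shape anchors (262x262 after padding, 64x64x128
after the third conv) pin the encoder down almost uniquely; the decoder
channel plan (64, 32) mirrors the encoder. One deliberate deviation from
an obvious alternative: rather than appending a fifth 7x7 output
convolution after the second fusion, the second fusion's 1x1 channel
merge projects directly to the single output channel, followed by a
sigmoid to [0,1]. This keeps the conv census at exactly four while
meeting every shape anchor; intensities are in [0,1] throughout, so a
sigmoid output head (not tanh) is the natural range map.

**RFB**: two mirror-fill layers, three 3x3 convolutions (16/32/64
channels, strides 1/2/1, each conv + instance norm + ReLU) and one
stride-2 transposed convolution that restores the input resolution with
`feature_channels` (default 8) output maps. Kernel sizes and channel
counts are not pinned by the stated structure (only the layer kinds
are); this plan is small enough to train jointly and wide enough to give
the generator a useful regional code. Whether fusion means concatenation
or addition is also not pinned; concatenation is used because it
preserves the image channel exactly (channel 1 of the fused input is
asserted to be the unmodified image).

**Discriminator**: four 4x4 stride-2 convolutions with channels
64/128/256/512 and leaky-ReLU slope 0.2 (the DCGAN convention), then
flatten, a dense layer to one unit and a sigmoid — a scalar
real-vs-synthetic score strictly inside (0,1). `D_x` scores 1-channel
medical images (real image vs `F(y)`), matching the stated inputs of the
domain-X discriminator ("real and synthetic medical images"), rather
than the 9-channel fused grid.

The forward/backward passes are implemented as an interpreter over the
layer list: im2col/col2im patch extraction in C++ feeding BLAS matrix
multiplications, with hand-derived adjoints per layer kind. The test
suite verifies every layer's gradient against central finite differences
and the transposed convolution against the exact conv adjoint identity.

## Synthetic phantoms: what they emulate, and what they do not

The phantom generator (`generate_phantoms()`) produces the statistical
structure the method actually depends on: a tissue background
(`background_level`, default 0.35), one compact high-contrast tumor
(`tumor_contrast`, default 0.4, the additive in-mask intensity shift)
with an exactly known elliptical mask (semi-axes 6–13 px at 64 px),
optional spatially correlated background texture (a smoothed Gaussian
field; pure-constant backgrounds make SSIM degenerate, since every
variance in its contrast term vanishes), and optional i.i.d. Gaussian
pixel noise, clipped to [0,1] last so the normalization-range invariant
holds. Ellipses (rather than irregular tumor outlines) are deliberate:
shape realism is irrelevant to the fusion/cycle mechanism, while smooth
convex masks give clean, non-trivial Dice and Hausdorff surfaces.

Phantoms do **not** emulate mammographic or MRI physics — no
anatomy-scale structure, partial-volume effects, bias fields, or
multi-sequence contrast. A model that passes the desk-scale tests has
demonstrated that the mechanism (fusion, cycles, alternating
optimization) works and that every metric is computed correctly; it says
nothing about synthesis quality on real clinical data, which requires
the full-resolution datasets and training budgets out of this package's
scope.

## Desk-scale problem sizes

The package's own study conditions, used in the tests and the acceptance
script, are sized for a single CPU: 16 noise-free 64x64 phantom pairs,
300 optimizer steps (about 19 passes over the data), held-out evaluation
on 8 phantoms from a different seed. At these sizes the cycle loss drops
to roughly a third of its initial value, held-out ROI synthesis reaches
Dice well above 0.7 at the 0.5 binarization threshold, and the
reconstruction error of `F(G(x))` is an order of magnitude below the
tumor contrast. The unit-test model is smaller still (32x32, 150 steps).
These are internal calibration targets on phantom data, not comparable
to any full-scale figure.

## Preprocessing conventions

* Maximum normalization `x / max(x)` maps intensities to [0,1] with the
  maximum exactly 1; all-zero images are a degenerate-input error.
* Lesion crops are centered on the mask bounding-box center, clamped to
  the image bounds; lesions larger than the window are cropped to their
  bounding box and resized (bilinear for images, nearest-neighbor for
  masks, which preserves binarity).
* Slice extraction uses 1-based indices along the third array axis (the
  idiomatic R convention; "the 90th slice" is an ordinal), binarizes
  multi-valued label volumes at > 0, max-normalizes each slice, and
  excludes pairs whose mask slice is empty.
* The 7:3 train/test split is a seeded uniform permutation with
  nearest-integer train count: 107 pairs split 75/32. Whether the
  original split was random or ordered is not stated; a recorded-seed
  random split is the reproducible choice.
* PNG export is 8-bit grayscale (the depth the available PNG writers
  emit), so [0,1] intensities survive a round trip to within 1/255 and
  binary masks exactly; quantization at this depth is negligible
  relative to the phantom noise floor.

## Metric conventions

* **PSNR** uses the maximum pixel value over both images as the peak and
  the pixel count of the evaluated region; identical images return an
  `Inf` sentinel, excluded (and counted) in aggregates.
* **SSIM** is computed from *global* region statistics exactly as the
  printed formula states — mean, population variance and covariance over
  the evaluated region — with constants `c1 = (0.01 L)^2`,
  `c2 = (0.03 L)^2`, `L = 1`. A Gaussian sliding-window mode
  (`windowed = TRUE`, 11x11, sigma 1.5) is available for comparison with
  image-library implementations.
* **MS-SSIM** uses 2x2 average-pooled dyadic scales with the standard
  five-scale weights, truncated and renormalized for small images;
  contrast/structure terms are floored at 0 before exponentiation. With
  one scale and unit weight it reduces exactly to SSIM.
* **Tumor-region restriction** means the PSNR/SSIM statistics run over
  mask-foreground pixels only (with the mask-restricted pixel count as
  N); the alternative whole-image N is not used.
* **Dice** of two empty masks is defined as 1 with a warning (perfect
  agreement); **Hausdorff** of an empty mask is an error (the distance
  to an empty set is undefined). Hausdorff is computed exactly on the
  foreground coordinate sets (integer squared distances), which matches
  a brute-force double loop bit for bit.
* **Histograms** use 256 equal-width bins on [0,1] by default and the
  total-variation distance `0.5 * sum |p - q|`.
* Paired comparisons between methods use two-sided paired-samples
  t-tests at significance level 0.05.

## Synthesis contract

Inference needs a real (image, mask) seed pair, because the fused
domain-X input requires the region image — there is no noise-driven
unconditional sampler in this model. This matches the augmentation
use-case: new pairs are synthesized from existing pairs, preserving the
group label. The ROI binarization threshold defaults to 0.5 (no rule is
stated in the formulation; 0.5 is the symmetric choice for a sigmoid
output). Degenerate inputs are rejected: non-finite checkpoint
parameters error at inference, masks must be exactly binary, and images
must be in [0,1].

## Classification protocol

The augmentation-benefit experiment mirrors the radiomics protocol:
extract a fixed-length feature vector per image (the first 500 entries
of the extractor's output, in extractor order), reduce to 30 features by
SVM-based recursive feature elimination with five-fold cross-validation
(drop the lowest-ranked 10% per iteration, fold-averaged squared
linear-SVM weights as the ranking criterion — the internal ranking
estimator is not pinned by the protocol, and a linear ranker is the
classic SVM-RFE choice), then classify with an RBF-kernel SVM (`cost =
1`, default bandwidth). The positive class is the HGG analogue, matching
the stated TP definition. No pretrained deep feature extractor is
shipped — none is available offline — so the extractor is pluggable and
the default is a deterministic intensity/texture map (histogram, pooled
intensities, moments, gradient statistics); the planted-feature
simulation (5 informative among 495 noise columns) verifies the
selection machinery with known ground truth. Synthetic samples are
structurally barred from test sets.

## Known limitations

* Desk-scale training budgets demonstrate mechanism, not clinical image
  quality; no comparison against other synthesis families is included.
* The Hausdorff implementation materializes the pairwise distance
  matrix, which is exact and fast for desk-scale masks but would need
  chunking for masks with hundreds of thousands of foreground pixels.
* `D_x` sees 1-channel images; scoring the full fused grid is a
  plausible alternative reading that is not implemented.
* Training is batch-1 and single-threaded by design; wall-clock scaling
  to 256x256 full runs is possible but slow without a GPU framework.
* DICOM input is not supported (no offline DICOM reader is available to
  this package); readers cover paired PNG sets and NIfTI volumes.
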