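# roicycle

Region-fused cycle-consistent synthesis of paired medical images and
their region-of-interest (ROI) masks.

## The problem

Training medical-image models — tumor classifiers, segmentation networks,
radiomics pipelines — needs paired data: an image *and* its annotated ROI
mask. Both are scarce. Adversarial synthesis can expand a dataset, but a
synthetic image is only useful downstream if it is structurally
consistent with real images **and** comes with its own ROI.

`roicycle` implements a cycle-consistent GAN between the medical-image
domain X and the ROI-mask domain Y that *fuses a-priori regional
features into the input domain*. The image is multiplied elementwise
with its mask to form the **region image** (tumor intensities only); a
small convolutional **regional feature extraction block (RFB)** encodes
it into feature maps concatenated with the image as extra input
channels. Two generators and two discriminators are trained with the
adversarial objective

```
L_GAN(G, D_y) = E_y[log D_y(y)] + E_x[log(1 − D_y(G(x)))]
```

in both directions plus a cycle-consistency term

```
L_cyc = E_x |F(G(x)) − x|_1 + E_y |G(F(y)) − y|_1,    L = L_GAN + L_GAN' + λ·L_cyc
```

Paired synthesis then runs the two cycles: a synthetic image is
`F(G(x))` and its ROI is `G(F(y))` thresholded at 0.5, always emitted as
a pair from the same source sample.

The package also ships the surrounding protocol: a synthetic phantom
generator (so everything is testable without data downloads), the
preprocessing recipe (lesion cropping, slice extraction from 3D label
volumes, maximum normalization, seeded 7:3 splitting), an evaluation
suite (PSNR, SSIM, MS-SSIM, Dice, Hausdorff, grayscale-histogram
distance, paired t-tests, whole-image vs tumor-region restriction), and
the downstream augmentation-benefit experiment (feature extraction,
SVM-RFE to 30 features with five-fold CV, RBF-SVM, Acc/Sen/Spe/AUC).

## Worked example

```r
library(roicycle)

# 1. paired phantoms: tissue background + high-contrast tumor with exact mask
cfg <- phantom_config(image_size = 64, n_samples = 16,
                      noise_sd = 0, texture_scale = 0, seed = 101)
train_set <- generate_phantoms(cfg)
train_set[[1]]
#> <paired_sample 'phantom_001'> 64x64, mask area 169 px, group NA

# 2. desk-scale training: 300 optimizer steps, ~5 min on one CPU
state <- train(train_set, train_config(image_size = 64, seed = 1,
                                       max_steps = 300))
state
#> <train_state> 300 step(s), image size 64, lambda 10.0
#>   final losses: gan_fwd -0.0000, gan_bwd -1.3892, cyc 0.2158

# 3. synthesize paired image/ROI for held-out phantoms and score them
held_out <- generate_phantoms(phantom_config(image_size = 64, n_samples = 8,
                                             noise_sd = 0, texture_scale = 0,
                                             seed = 202))
synth <- lapply(held_out, function(s) {
  paired_sample(synthesize_image(s, state)$synthetic_image,
                synthesize_roi(s, state)$synthetic_roi,
                paste0(s$sample_id, "_syn"), s$group_label)
})
evaluate(held_out, synth, region = "whole")
#> <metric_report> method roicycle, region whole, n = 8
#>   psnr      31.6560 ± 0.8538 (n=8)
#>   ssim      0.9757 ± 0.0090 (n=8)
#>   ms_ssim   0.9936 ± 0.0049 (n=8)
#>   dice      0.9652 ± 0.0218 (n=8)
#>   hausdorff 1.0000 ± 0.0000 (n=8)
```

Reading the report: the cycle loss fell from ≈0.58 (first 20 steps) to
≈0.22, the model reconstructs held-out images at ≈32 dB PSNR, and the
synthesized ROIs overlap the true masks at Dice ≈0.97 with worst-case
boundary error of one pixel — on noise-free phantoms, i.e. a mechanism
check, not a clinical result. `evaluate(..., region = "tumor")`
restricts PSNR/SSIM statistics to mask-foreground pixels.

A thin command-line interface wraps the same functions
(`inst/cli/roicycle.R` with subcommands `phantom`, `preprocess`,
`train`, `synthesize`, `evaluate`); see `?cli_main`.

## Documentation

The methods vignette
(`vignettes/region-fused-cycle-synthesis.Rmd`) documents the model and
its assumptions, every tunable parameter with its default and rationale,
the phantom generator's scope, numerical conventions (log clamping,
SSIM statistics, empty-mask semantics, tie handling in AUC), and known
limitations.
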