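Package: roicycle
Title: Region-Fused Cycle-Consistent Synthesis of Paired Medical Images
    and ROI Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for synthesizing paired 2D medical images and their
    region-of-interest (ROI) masks with a cycle-consistent adversarial
    model that fuses a-priori regional (tumor) features into the input
    domain. Includes a synthetic phantom generator for paired image/mask
    data, the preprocessing recipe (lesion cropping, slice extraction,
    maximum normalization, train/test splitting), declarative network
    specifications with hard shape contracts for the regional feature
    extraction block, generators and discriminators, adversarial and
    cycle-consistency losses with an alternating training loop, paired
    image/ROI inference pipelines, an evaluation suite (PSNR, SSIM,
    MS-SSIM, Dice, Hausdorff, grayscale histogram comparison, paired
    t-tests), and a downstream classification protocol (feature
    extraction, SVM-based recursive feature elimination, kernel SVM,
    accuracy/sensitivity/specificity/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
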