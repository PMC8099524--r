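# Inference pipelines of the trained model: (i) paired medical-image
# synthesis x -> G(x) -> F(G(x)) and (ii) ROI synthesis
# y -> F(y) -> G(F(y)). Both require a seed (image, mask) pair because the
# fused domain-X input needs the region image.

check_trained <- function(state) {
  if (!inherits(state, "train_state"))
    stop("`state` must be a train_state from train()")
  ok <- vapply(state$params, function(p)
    all(vapply(p, function(l)
      is.null(l) || all(is.finite(unlist(l))), TRUE)), TRUE)
  if (!all(ok)) stop("train state contains non-finite parameters")
  invisible(state)
}

#' Synthesize a medical image from a paired sample
#'
#' Pipeline (i): computes the region image, RFB features and fused
#' domain-X input, maps to the ROI domain with `G`, and back to the image
#' domain with `F`. The synthesized image is `F(G(x))`.
#'
#' @param sample A [paired_sample()] matching the trained image size.
#' @param state A `train_state` from [train()].
#' @return A `synthesis_result` list with `source`, `g_of_x` (the
#'   ROI-domain intermediate) and `synthetic_image` (both 2D matrices in
#'   [0,1]).
#' @export
synthesize_image <- function(sample, state) {
  check_trained(state)
  gf <- fused_g_forward(state$specs, state$params, sample$image, sample$mask)
  xrec <- network_forward(state$specs$F, state$params$F, gf$yhat)
  structure(list(source = sample,
                 g_of_x = gf$yhat[, , 1L],
                 synthetic_image = xrec[, , 1L]),
            class = "synthesis_result")
}

#' Synthesize an ROI mask from a paired sample
#'
#' Pipeline (ii): maps the ROI `y` to the image domain with `F`, rebuilds
#' the fused input from `F(y)` and `y`, and maps back to the ROI domain
#' with `G`. The soft map `G(F(y))` is binarized at `threshold`.
#'
#' @param sample A [paired_sample()].
#' @param state A `train_state`.
#' @param threshold Binarization threshold in (0,1); default 0.5.
#' @return A `synthesis_result` list with `source`, `f_of_y` (image-domain
#'   intermediate), `synthetic_roi_soft` in [0,1] and the binary
#'   `synthetic_roi`.
#' @export
synthesize_roi <- function(sample, state, threshold = 0.5) {
  check_trained(state)
  if (threshold <= 0 || threshold >= 1)
    stop_field("threshold", "must lie in (0,1)")
  specs <- state$specs; params <- state$params
  msk <- as_hwc(sample$mask)
  xtil <- network_forward(specs$F, params$F, msk)
  region2 <- xtil * msk
  feat2 <- network_forward(specs$rfb, params$rfb, region2)
  soft <- network_forward(specs$G, params$G,
                      fuse_regional_features(xtil, feat2))
  structure(list(source = sample,
                 f_of_y = xtil[, , 1L],
                 synthetic_roi_soft = soft[, , 1L],
                 synthetic_roi = (soft[, , 1L] >= threshold) + 0),
            class = "synthesis_result")
}

#' Synthesize and write a batch of paired image/ROI samples
#'
#' Runs both inference pipelines on every sample and writes the resulting
#' pairs as grayscale PNGs plus a manifest tagging each record as
#' `synthetic`, preserving group labels for downstream classification.
#' Every written image is paired with the ROI synthesized from the same
#' source sample, never mixed across samples.
#'
#' @param samples List of [paired_sample()] objects.
#' @param state A `train_state`.
#' @param out_dir Output directory.
#' @param threshold ROI binarization threshold (default 0.5).
#' @return The manifest `data.frame` (also written as `manifest.csv`).
#' @export
synthesize_batch <- function(samples, state, out_dir, threshold = 0.5) {
  check_trained(state)
  synth <- lapply(samples, function(s) {
    si <- synthesize_image(s, state)
    sr <- synthesize_roi(s, state, threshold)
    paired_sample(pmin(pmax(si$synthetic_image, 0), 1), sr$synthetic_roi,
                  paste0(s$sample_id, "_syn"), s$group_label)
  })
  write_sample_set(synth, out_dir, provenance = "synthetic")
}
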