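# Data-preparation recipe: maximum normalization, lesion-area cropping,
# slice extraction from 3D volumes, region-image computation, and the
# train/test split. Geometric operations are always applied identically to
# image and mask so pairs stay aligned.
#
# Conventions: matrices are (row, column); 3D volumes are (row, column,
# slice) with 1-based slice indices; images are expected in [0,1] after
# normalize_max().

#' Maximum normalization to [0,1]
#'
#' Divides an image by its maximum, linearly mapping intensities to [0,1]
#' with the maximum mapped exactly to 1. Idempotent on images whose
#' maximum is already 1, and order-preserving.
#'
#' @param image 2D numeric grid with at least one positive pixel.
#' @return The normalized grid; `image / max(image)`.
#' @export
normalize_max <- function(image) {
  m <- max(image)
  if (!is.finite(m) || m <= 0)
    stop("normalize_max: degenerate input (no positive pixel)")
  image / m
}

#' Elementwise region image
#'
#' Multiplies a medical image with its binary ROI mask, zeroing everything
#' outside the region of interest. This "region image" is what the
#' regional feature extraction block consumes.
#'
#' @param image 2D numeric grid.
#' @param mask Binary 2D grid of identical dimensions.
#' @return `image * mask`.
#' @export
compute_region_image <- function(image, mask) {
  if (!all(dim(as.matrix(image)) == dim(as.matrix(mask))))
    stop("image and mask must have identical dimensions")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  image * mask
}

#' Crop an image/mask pair to a window centered on the lesion
#'
#' Returns an `out_size` x `out_size` window centered on the mask's
#' bounding-box center, clamped so the window never leaves the image.
#' When the mask's bounding box is larger than the window, the pair is
#' cropped to the (square) bounding box and resized to `out_size`
#' (bilinear for the image, nearest-neighbor for the mask so it stays
#' binary).
#'
#' @param image 2D grid in [0,1].
#' @param mask Non-empty binary 2D grid, same dimensions.
#' @param out_size Output side length, at most `min(dim(image))`.
#' @param sample_id Identifier for the resulting pair.
#' @param group_label Optional category label.
#' @return A [paired_sample()].
#' @export
crop_to_roi <- function(image, mask, out_size, sample_id = "crop",
                        group_label = NA_character_) {
  image <- as.matrix(image); mask <- as.matrix(mask)
  if (sum(mask) == 0) stop("crop_to_roi: mask is empty")
  if (out_size > min(dim(image)))
    stop("crop_to_roi: out_size exceeds image dimensions")
  fg <- which(mask == 1, arr.ind = TRUE)
  rr <- range(fg[, 1]); cr <- range(fg[, 2])
  bb_h <- rr[2] - rr[1] + 1L; bb_w <- cr[2] - cr[1] + 1L
  if (bb_h > out_size || bb_w > out_size) {
    # lesion larger than the window: crop to the square bounding box, then
    # resize down to out_size
    side <- max(bb_h, bb_w)
    win_r <- clamp_window(round((rr[1] + rr[2]) / 2), side, nrow(image))
    win_c <- clamp_window(round((cr[1] + cr[2]) / 2), side, ncol(image))
    img_c <- image[win_r, win_c, drop = FALSE]
    msk_c <- mask[win_r, win_c, drop = FALSE]
    img_c <- resize_image(img_c, out_size, bilinear = TRUE)
    msk_c <- resize_image(msk_c, out_size, bilinear = FALSE)
    img_c <- pmin(pmax(img_c, 0), 1)
  } else {
    win_r <- clamp_window(round((rr[1] + rr[2]) / 2), out_size, nrow(image))
    win_c <- clamp_window(round((cr[1] + cr[2]) / 2), out_size, ncol(image))
    img_c <- image[win_r, win_c, drop = FALSE]
    msk_c <- mask[win_r, win_c, drop = FALSE]
  }
  paired_sample(img_c, round(msk_c), sample_id, group_label)
}

# window of `size` indices centered at `center`, clamped into 1..n
clamp_window <- function(center, size, n) {
  if (size > n) stop("window larger than image")
  start <- round(center - size / 2 + 0.5)
  start <- min(max(start, 1L), n - size + 1L)
  seq.int(start, start + size - 1L)
}

resize_image <- function(m, out_size, bilinear = TRUE) {
  filt <- if (bilinear) "bilinear" else "none"
  # EBImage indexes (x, y) = (column, row); transpose in and out
  t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m)), w = out_size,
                                       h = out_size, filter = filt)))
}

#' Extract paired 2D slices from a 3D volume and its label volume
#'
#' Takes the image and mask slice at each requested index (slice axis =
#' third array dimension, 1-based). Pairs whose mask slice contains no
#' tumor are excluded. Image slices are rescaled to [0,1] by
#' [normalize_max()] (all-zero slices are left as zeros) and label slices
#' are binarized (`> 0`), matching the preprocessing recipe for
#' multi-label segmentation volumes.
#'
#' @param volume 3D numeric array (row, column, slice).
#' @param mask_volume 3D label array of identical dimensions.
#' @param slice_indices Integer vector of slice indices (1-based).
#' @param id_prefix Prefix for generated sample ids.
#' @param group_label Optional category label for all extracted pairs.
#' @return List of [paired_sample()] objects (possibly shorter than
#'   `slice_indices` after empty-mask exclusion).
#' @export
extract_slices <- function(volume, mask_volume, slice_indices,
                           id_prefix = "slice", group_label = NA_character_) {
  stopifnot(length(dim(volume)) == 3L, all(dim(volume) == dim(mask_volume)))
  nz <- dim(volume)[3]
  bad <- slice_indices[slice_indices < 1L | slice_indices > nz]
  if (length(bad))
    stop(sprintf("slice index out of range (1..%d): %s", nz,
                 paste(bad, collapse = ", ")))
  out <- list()
  for (idx in slice_indices) {
    msk <- (mask_volume[, , idx] > 0) + 0
    if (sum(msk) == 0) next  # slices without tumor are excluded
    img <- volume[, , idx]
    if (max(img) > 0) img <- normalize_max(img)
    out[[length(out) + 1L]] <-
      paired_sample(img, msk, sprintf("%s_%03d", id_prefix, idx), group_label)
  }
  out
}

#' Read a NIfTI volume as a 3D array
#'
#' Thin wrapper over RNifti; returns the voxel array with voxel spacing
#' (mm) attached as attribute `"spacing"` when available.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return 3D numeric array.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  pd <- attr(img, "pixdim")
  if (!is.null(pd)) attr(arr, "spacing") <- pd
  arr
}

#' Split paired samples into train and test sets
#'
#' Uniform random permutation under `seed`; the train count is the nearest
#' integer to `ratio * n` (clamped so both sets are non-empty). 107
#' samples at ratio 0.7 give the 75/32 partition of a 7:3 split.
#'
#' @param samples List of [paired_sample()] objects (length >= 2).
#' @param ratio Train fraction in (0,1); default 0.7.
#' @param seed RNG seed for the permutation.
#' @return List with elements `train`, `test`, `ratio`, `seed`.
#' @export
split_train_test <- function(samples, ratio = 0.7, seed = 1L) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples to split")
  if (ratio <= 0 || ratio >= 1) stop_field("ratio", "must lie in (0,1)")
  n_train <- round(ratio * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  perm <- with_seed(seed, sample.int(n))
  structure(list(train = samples[perm[seq_len(n_train)]],
                 test = samples[perm[(n_train + 1L):n]],
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_result")
}
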