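# Synthetic paired image/mask phantoms. Each phantom is a grayscale tissue
# background with one compact, high-contrast elliptical "tumor" whose
# binary mask is known exactly; downstream stages (fusion, training,
# synthesis, metrics, classification) are all testable on these without
# any external data.

#' Phantom generator configuration
#'
#' Parameters of the paired image/mask phantom generator. Defaults are the
#' desk-scale study conditions used throughout the package: 64x64 images,
#' tissue background 0.35, tumor contrast 0.4, tumor radii 6-13 px, mild
#' correlated background texture, and light Gaussian noise.
#'
#' @param image_size Pixels per side (64 for desk-scale runs, 256 for full
#'   runs).
#' @param n_samples Number of phantoms to generate.
#' @param background_level Mean tissue intensity in [0,1].
#' @param tumor_contrast Additive intensity shift of the tumor region in
#'   [0,1]; `background_level + tumor_contrast` must not exceed 1.
#' @param tumor_radius_range Length-2 vector, min/max ellipse semi-axis in
#'   pixels; both positive and below `image_size / 2`.
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise
#'   (applied last, then clipped to [0,1]).
#' @param texture_scale Correlation length (pixels) of the smoothed
#'   Gaussian background texture; 0 disables texture.
#' @param texture_sd Amplitude (SD) of the background texture field.
#' @param seed RNG seed; identical config + seed reproduces identical
#'   phantoms bit for bit.
#' @param group_label Optional category attached to every sample (e.g. an
#'   HGG/LGG analogue for classification experiments).
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(image_size = 64L, n_samples = 16L,
                           background_level = 0.35, tumor_contrast = 0.4,
                           tumor_radius_range = NULL, noise_sd = 0.02,
                           texture_scale = 8, texture_sd = 0.04,
                           seed = 1L, group_label = NA_character_) {
  if (is.null(tumor_radius_range))
    tumor_radius_range <- c(max(3, round(0.09 * image_size)),
                            round(0.2 * image_size))
  cfg <- list(image_size = as.integer(image_size),
              n_samples = as.integer(n_samples),
              background_level = background_level,
              tumor_contrast = tumor_contrast,
              tumor_radius_range = tumor_radius_range,
              noise_sd = noise_sd, texture_scale = texture_scale,
              texture_sd = texture_sd, seed = as.integer(seed),
              group_label = group_label)
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$image_size < 8L) stop_field("image_size", "must be at least 8")
  if (cfg$n_samples < 1L) stop_field("n_samples", "must be positive")
  if (cfg$background_level < 0 || cfg$background_level > 1)
    stop_field("background_level", "must lie in [0,1]")
  if (cfg$tumor_contrast < 0 || cfg$tumor_contrast > 1)
    stop_field("tumor_contrast", "must lie in [0,1]")
  if (cfg$background_level + cfg$tumor_contrast > 1 + 1e-12)
    stop_field("tumor_contrast",
               "background_level + tumor_contrast must not exceed 1")
  r <- cfg$tumor_radius_range
  if (length(r) != 2L || any(r <= 0) || r[1] > r[2] ||
      r[2] >= cfg$image_size / 2)
    stop_field("tumor_radius_range",
               "need 0 < min <= max < image_size / 2")
  if (cfg$noise_sd < 0) stop_field("noise_sd", "must be non-negative")
  if (cfg$texture_scale < 0) stop_field("texture_scale", "must be non-negative")
  invisible(cfg)
}

#' Construct a paired image/mask sample
#'
#' @param image 2D matrix of intensities in [0,1].
#' @param mask 2D binary matrix (values exactly 0 or 1) with the same
#'   dimensions as `image`.
#' @param sample_id Identifier string.
#' @param group_label Optional category label.
#' @return A `paired_sample` object.
#' @export
paired_sample <- function(image, mask, sample_id,
                          group_label = NA_character_) {
  image <- as.matrix(image); mask <- as.matrix(mask)
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must have identical dimensions")
  if (any(image < -1e-12) || any(image > 1 + 1e-12))
    stop("image intensities must lie in [0,1]")
  if (!all(mask %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1")
  structure(list(image = image, mask = mask,
                 sample_id = as.character(sample_id),
                 group_label = group_label),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample '%s'> %dx%d, mask area %d px, group %s\n",
              x$sample_id, nrow(x$image), ncol(x$image), sum(x$mask),
              x$group_label))
  invisible(x)
}

# smoothed Gaussian random field: white noise convolved with a Gaussian
# kernel of the requested correlation length, rescaled to unit SD
gaussian_field <- function(n, scale) {
  z <- matrix(rnorm(n * n), n, n)
  if (scale <= 0) return(z)
  half <- max(1L, ceiling(2 * scale))
  k <- dnorm(seq(-half, half), sd = scale)
  k <- k / sum(k)
  pad <- function(m) m[c(rep(1, half), 1:n, rep(n, half)), , drop = FALSE]
  smooth1 <- function(m) {
    # separable convolution along rows (apply twice with transposes)
    mp <- pad(m)
    out <- matrix(0, n, n)
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  z <- t(smooth1(t(smooth1(z))))
  s <- sd(as.vector(z))
  if (s > 0) z / s else z
}

ellipse_mask <- function(n, cx, cy, rx, ry, theta) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Generate paired image/mask phantoms
#'
#' Draws `n_samples` phantoms under `config`: a random ellipse (position,
#' semi-axes within `tumor_radius_range`, orientation) defines the tumor
#' mask, fully inside the image; the image is
#' `background_level (+ texture) + tumor_contrast * mask (+ noise)`,
#' clipped to [0,1]. With `noise_sd = 0` and `texture_scale = 0` the image
#' is an exact two-level function of the mask. The mean in-mask intensity
#' exceeds the out-of-mask mean by `tumor_contrast` before noise.
#'
#' @param config A [phantom_config()].
#' @return List of [paired_sample()] objects of length `n_samples`.
#' @examples
#' set <- generate_phantoms(phantom_config(image_size = 32, n_samples = 2))
#' range(set[[1]]$image)
#' @export
generate_phantoms <- function(config) {
  validate_phantom_config(config)
  n <- config$image_size
  r <- config$tumor_radius_range
  with_seed(config$seed, {
    lapply(seq_len(config$n_samples), function(i) {
      rx <- runif(1, r[1], r[2])
      ry <- runif(1, r[1], r[2])
      theta <- runif(1, 0, pi)
      margin <- max(rx, ry) + 1
      cx <- runif(1, margin + 1, n - margin)
      cy <- runif(1, margin + 1, n - margin)
      mask <- ellipse_mask(n, cx, cy, rx, ry, theta)
      img <- matrix(config$background_level, n, n)
      if (config$texture_scale > 0 && config$texture_sd > 0)
        img <- img + config$texture_sd * gaussian_field(n, config$texture_scale)
      img <- img + config$tumor_contrast * mask
      if (config$noise_sd > 0)
        img <- img + matrix(rnorm(n * n, 0, config$noise_sd), n, n)
      img <- pmin(pmax(img, 0), 1)
      paired_sample(img, mask + 0, sprintf("phantom_%03d", i),
                    config$group_label)
    })
  })
}

#' Write a phantom set as paired PNG files plus a manifest
#'
#' Mirrors the preprocessed paired-PNG layout: `image_###.png` /
#' `mask_###.png` (8-bit grayscale: intensities round-trip to within
#' 1/255, masks exactly) and a `manifest.csv` with columns `sample_id`,
#' `image_path`, `mask_path`, `group_label`, `provenance`.
#'
#' @param samples List of [paired_sample()] objects.
#' @param dir Output directory (created if missing).
#' @param provenance Tag recorded per sample (default `"real"`).
#' @return Invisibly, the manifest `data.frame`.
#' @export
write_sample_set <- function(samples, dir, provenance = "real") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    ip <- file.path(dir, sprintf("image_%03d.png", i))
    mp <- file.path(dir, sprintf("mask_%03d.png", i))
    # EBImage uses x = columns as the first index; transpose so files are
    # laid out in the conventional row/column order
    EBImage::writeImage(EBImage::Image(t(s$image)), ip, type = "png")
    EBImage::writeImage(EBImage::Image(t(s$mask)), mp, type = "png")
    data.frame(sample_id = s$sample_id, image_path = basename(ip),
               mask_path = basename(mp), group_label = s$group_label,
               provenance = provenance, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a paired sample set written by [write_sample_set()]
#'
#' @param dir Directory containing `manifest.csv` and the PNG pairs.
#' @return List of [paired_sample()] objects; the manifest is attached as
#'   attribute `"manifest"`.
#' @export
read_sample_set <- function(dir) {
  mf <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(mf)), function(i) {
    img <- t(EBImage::imageData(EBImage::readImage(file.path(dir, mf$image_path[i]))))
    msk <- t(EBImage::imageData(EBImage::readImage(file.path(dir, mf$mask_path[i]))))
    paired_sample(img, round(msk), mf$sample_id[i], mf$group_label[i])
  })
  attr(samples, "manifest") <- mf
  samples
}
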