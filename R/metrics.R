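# Image-quality and overlap metrics: PSNR, SSIM (global statistics, with
# an optional sliding-window mode), MS-SSIM, Dice, Hausdorff distance,
# grayscale histogram comparison, paired t-tests, and the whole-image /
# tumor-region evaluation protocol.

region_values <- function(x, region_mask) {
  if (is.null(region_mask)) as.vector(x)
  else {
    if (!all(dim(as.matrix(x)) == dim(as.matrix(region_mask))))
      stop("region mask dimensions do not match the image")
    as.vector(x)[as.vector(region_mask) > 0]
  }
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(MAX_range^2 / MSE)` where `MAX_range` is the maximum pixel
#' value over both images and the mean squared error is taken over the
#' evaluated region (all pixels, or mask-foreground pixels when
#' `region_mask` is given). Identical images have zero MSE and return
#' `Inf` (a sentinel excluded from aggregate statistics).
#'
#' @param x,recon Equal-dimension numeric grids.
#' @param region_mask Optional binary mask restricting the evaluation.
#' @return PSNR in decibels; higher is better.
#' @export
psnr <- function(x, recon, region_mask = NULL) {
  if (!all(dim(as.matrix(x)) == dim(as.matrix(recon))))
    stop("psnr: dimension mismatch")
  xv <- region_values(x, region_mask)
  rv <- region_values(recon, region_mask)
  mx <- max(max(x), max(recon))
  mse <- mean((xv - rv)^2)
  if (mse == 0) return(Inf)
  10 * log10(mx^2 / mse)
}

#' Structural similarity (SSIM)
#'
#' `((2 mu_x mu_r + c1)(2 cov_xr + c2)) /
#'  ((mu_x^2 + mu_r^2 + c1)(var_x + var_r + c2))`, with means, variances
#' (population, i.e. divided by N) and covariance computed globally over
#' the evaluated region. `windowed = TRUE` instead averages SSIM over an
#' 11x11 Gaussian sliding window (sigma 1.5), the form used by most image
#' libraries; the global form follows the printed definition.
#'
#' @param x,recon Equal-dimension numeric grids.
#' @param c1,c2 Stabilization constants; defaults `(0.01 * L)^2` and
#'   `(0.03 * L)^2` with dynamic range `L = 1`.
#' @param region_mask Optional binary mask restricting the statistics to
#'   mask-foreground pixels (global mode only).
#' @param windowed Use the Gaussian sliding-window variant.
#' @return SSIM value; 1 for identical non-constant images.
#' @export
ssim <- function(x, recon, c1 = 0.01^2, c2 = 0.03^2, region_mask = NULL,
                 windowed = FALSE) {
  if (!all(dim(as.matrix(x)) == dim(as.matrix(recon))))
    stop("ssim: dimension mismatch")
  if (windowed) {
    if (!is.null(region_mask))
      stop("windowed SSIM does not support region masks")
    return(ssim_windowed(as.matrix(x), as.matrix(recon), c1, c2))
  }
  xv <- region_values(x, region_mask)
  rv <- region_values(recon, region_mask)
  n <- length(xv)
  mx <- mean(xv); mr <- mean(rv)
  vx <- mean((xv - mx)^2); vr <- mean((rv - mr)^2)
  cxr <- mean((xv - mx) * (rv - mr))
  ((2 * mx * mr + c1) * (2 * cxr + c2)) /
    ((mx^2 + mr^2 + c1) * (vx + vr + c2))
}

gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1L) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# 'valid' separable Gaussian filtering
filter_valid <- function(m, k) {
  n <- length(k)
  conv1 <- function(a) {
    out <- 0
    for (j in seq_len(n))
      out <- out + k[j] * a[j:(nrow(a) - n + j), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

ssim_windowed <- function(x, r, c1, c2, size = 11L, sigma = 1.5) {
  if (any(dim(x) < size)) stop("image too small for an 11x11 window")
  k <- gaussian_kernel_1d(size, sigma)
  mx <- filter_valid(x, k); mr <- filter_valid(r, k)
  vx <- filter_valid(x * x, k) - mx^2
  vr <- filter_valid(r * r, k) - mr^2
  cxr <- filter_valid(x * r, k) - mx * mr
  mean(((2 * mx * mr + c1) * (2 * cxr + c2)) /
         ((mx^2 + mr^2 + c1) * (vx + vr + c2)))
}

downsample2 <- function(m) {
  n1 <- nrow(m) %/% 2L; n2 <- ncol(m) %/% 2L
  m <- m[seq_len(2L * n1), seq_len(2L * n2), drop = FALSE]
  0.25 * (m[seq(1, 2 * n1, 2), seq(1, 2 * n2, 2), drop = FALSE] +
          m[seq(2, 2 * n1, 2), seq(1, 2 * n2, 2), drop = FALSE] +
          m[seq(1, 2 * n1, 2), seq(2, 2 * n2, 2), drop = FALSE] +
          m[seq(2, 2 * n1, 2), seq(2, 2 * n2, 2), drop = FALSE])
}

ssim_components <- function(x, r, c1, c2, region_mask = NULL) {
  xv <- region_values(x, region_mask)
  rv <- region_values(r, region_mask)
  mx <- mean(xv); mr <- mean(rv)
  vx <- mean((xv - mx)^2); vr <- mean((rv - mr)^2)
  cxr <- mean((xv - mx) * (rv - mr))
  list(l = (2 * mx * mr + c1) / (mx^2 + mr^2 + c1),
       cs = (2 * cxr + c2) / (vx + vr + c2))
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' Dyadic pyramid of 2x2 average-pooled images; the contrast/structure
#' component is measured at every scale and the luminance component at
#' the coarsest scale, combined as a weighted product with the standard
#' five-scale weights (0.0448, 0.2856, 0.3001, 0.2363, 0.1333). The scale
#' count is reduced automatically (weights renormalized) when the image
#' is too small; with `scales = 1` and unit weight the value reduces
#' exactly to [ssim()]. Components are floored at 0 before
#' exponentiation. When `region_mask` is given, statistics at each scale
#' are restricted to the mask, pooled alongside the images and
#' re-thresholded at 0.5.
#'
#' @param x,recon Equal-dimension numeric grids.
#' @param scales Number of scales (default 5, auto-reduced).
#' @param weights Per-scale weights; defaults to the standard set,
#'   truncated and renormalized with `scales`.
#' @param c1,c2 Stabilization constants as in [ssim()].
#' @param region_mask Optional binary region restriction.
#' @param min_size Smallest admissible side length at the coarsest scale.
#' @return MS-SSIM value in [0,1] (1 for identical images).
#' @export
ms_ssim <- function(x, recon, scales = 5L, weights = NULL,
                    c1 = 0.01^2, c2 = 0.03^2, region_mask = NULL,
                    min_size = 8L) {
  x <- as.matrix(x); r <- as.matrix(recon)
  if (!all(dim(x) == dim(r))) stop("ms_ssim: dimension mismatch")
  std_w <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  max_scales <- max(1L, floor(log2(min(dim(x)) / min_size)) + 1L)
  if (scales > max_scales) {
    if (max_scales < 1L)
      stop("image too small for multi-scale evaluation; use fewer scales")
    scales <- max_scales
  }
  if (is.null(weights)) {
    weights <- std_w[seq_len(min(scales, length(std_w)))]
    weights <- weights / sum(weights)
  }
  if (length(weights) != scales) stop("need one weight per scale")
  msk <- if (is.null(region_mask)) NULL else as.matrix(region_mask)
  val <- 1
  for (s in seq_len(scales)) {
    comp <- ssim_components(x, r, c1, c2, msk)
    cs <- max(comp$cs, 0)
    if (s == scales) {
      l <- max(comp$l, 0)
      val <- val * (l * cs)^weights[s]
    } else {
      val <- val * cs^weights[s]
      x <- downsample2(x); r <- downsample2(r)
      if (!is.null(msk)) msk <- (downsample2(msk) >= 0.5) + 0
    }
  }
  val
}

#' Dice overlap coefficient
#'
#' `2 |y & pred| / (|y| + |pred|)` between two binary masks. Two empty
#' masks agree perfectly and return 1 (with a warning).
#'
#' @param y,pred Equal-dimension binary masks.
#' @return Dice coefficient in [0,1].
#' @export
dice <- function(y, pred) {
  if (!all(dim(as.matrix(y)) == dim(as.matrix(pred))))
    stop("dice: dimension mismatch")
  if (!all(y %in% c(0, 1)) || !all(pred %in% c(0, 1)))
    stop("dice: masks must be binary")
  sy <- sum(y); sp <- sum(pred)
  if (sy + sp == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(y * pred) / (sy + sp)
}

#' Hausdorff distance between two binary masks (pixels)
#'
#' The larger of the two directed max-min Euclidean distances between the
#' foreground pixel coordinate sets. Undefined (an error) when either
#' mask is empty.
#'
#' @param y,pred Equal-dimension non-empty binary masks.
#' @return Hausdorff distance in pixel units.
#' @export
hausdorff <- function(y, pred) {
  y <- as.matrix(y); pred <- as.matrix(pred)
  if (!all(dim(y) == dim(pred))) stop("hausdorff: dimension mismatch")
  a <- which(y == 1, arr.ind = TRUE)
  b <- which(pred == 1, arr.ind = TRUE)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("hausdorff: distance to an empty mask is undefined")
  # squared distances stay exact integers, so the result matches a
  # double-loop computation bit for bit
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  h_ab <- max(apply(d2, 1, min))   # directed a -> b
  h_ba <- max(apply(d2, 2, min))   # directed b -> a
  sqrt(max(h_ab, h_ba))
}

#' Grayscale histogram comparison
#'
#' Bins both images over [0,1] with `n_bins` equal-width bins, normalizes
#' the counts to relative frequencies, and reports the total-variation
#' distance `0.5 * sum |p - q|` (0 for identical distributions, 1 for
#' disjoint supports).
#'
#' @param a,b Images with intensities in [0,1].
#' @param n_bins Number of bins (default 256, >= 2).
#' @return List with `hist_a`, `hist_b` (frequencies), `breaks`, and
#'   `distance`.
#' @export
histogram_compare <- function(a, b, n_bins = 256L) {
  if (n_bins < 2L) stop_field("n_bins", "need at least 2 bins")
  if (any(a < 0 | a > 1) || any(b < 0 | b > 1))
    stop("histogram_compare: intensities must lie in [0,1]")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- function(x) {
    idx <- pmin(pmax(findInterval(as.vector(x), breaks,
                                  rightmost.closed = TRUE), 1L), n_bins)
    tabulate(idx, n_bins) / length(x)
  }
  pa <- bin(a); pb <- bin(b)
  list(hist_a = pa, hist_b = pb, breaks = breaks,
       distance = 0.5 * sum(abs(pa - pb)))
}

#' Paired-samples t-test
#'
#' Two-sided paired t-test on matched measurement vectors, with the
#' significance call at level `alpha`.
#'
#' @param values_a,values_b Equal-length numeric vectors (n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return List with `t`, `p` and logical `significant` (`p < alpha`).
#' @export
paired_t_test <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) != length(values_b) || length(values_a) < 2L)
    stop("paired_t_test: need two equal-length vectors with n >= 2")
  if (sd(values_a - values_b) == 0)
    stop("paired_t_test: zero-variance differences; t statistic undefined")
  ht <- t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha)
}

#' Evaluate synthesized samples against their originals
#'
#' Computes per-sample PSNR, SSIM and MS-SSIM between original and
#' synthetic images (restricted to the tumor mask when
#' `region = "tumor"`), plus Dice and Hausdorff between the mask pairs,
#' and aggregates each metric as mean and standard deviation. Infinite
#' PSNR values (identical images) are excluded from the aggregates and
#' counted.
#'
#' @param originals,synthetics Equal-length lists of [paired_sample()]
#'   objects, matched by position.
#' @param region `"whole"` or `"tumor"`.
#' @param method Label recorded in the report.
#' @return A `metric_report`: list with `per_sample` (`data.frame`) and
#'   `aggregate` (mean, sd, n per metric).
#' @export
evaluate <- function(originals, synthetics, region = c("whole", "tumor"),
                     method = "roicycle") {
  region <- match.arg(region)
  if (length(originals) == 0 || length(originals) != length(synthetics))
    stop("evaluate: need matched, non-empty sample lists")
  rows <- lapply(seq_along(originals), function(i) {
    o <- originals[[i]]; s <- synthetics[[i]]
    msk <- if (region == "tumor") o$mask else NULL
    data.frame(
      sample_id = o$sample_id,
      psnr = psnr(o$image, s$image, msk),
      ssim = ssim(o$image, s$image, region_mask = msk),
      ms_ssim = ms_ssim(o$image, s$image, region_mask = msk),
      dice = dice(o$mask, s$mask),
      hausdorff = if (sum(s$mask) > 0 && sum(o$mask) > 0)
        hausdorff(o$mask, s$mask) else NA_real_,
      stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  agg <- lapply(c("psnr", "ssim", "ms_ssim", "dice", "hausdorff"),
                function(mn) {
    v <- per_sample[[mn]]
    fin <- v[is.finite(v)]
    data.frame(metric = mn, mean = mean(fin), sd = sd(fin),
               n = length(fin), n_excluded = sum(!is.finite(v)),
               stringsAsFactors = FALSE)
  })
  structure(list(per_sample = per_sample, aggregate = do.call(rbind, agg),
                 region = region, method = method),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> method %s, region %s, n = %d\n",
              x$method, x$region, nrow(x$per_sample)))
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-9s %.4f ± %.4f (n=%d%s)\n", a$metric[i], a$mean[i],
                a$sd[i], a$n[i],
                if (a$n_excluded[i] > 0)
                  sprintf(", %d excluded", a$n_excluded[i]) else ""))
  invisible(x)
}
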