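# Independent brute-force / direct-formula oracles used to cross-check the
# package implementations. These deliberately share no code with R/: plain
# loops and longhand formulas only.

psnr_oracle <- function(x, r, mask = NULL) {
  xv <- as.vector(x); rv <- as.vector(r)
  if (!is.null(mask)) {
    keep <- as.vector(mask) > 0
    xv <- xv[keep]; rv <- rv[keep]
  }
  mx <- max(c(x, r))
  mse <- sum((xv - rv)^2) / length(xv)
  10 * log10(mx * mx / mse)
}

ssim_oracle <- function(x, r, c1 = 1e-4, c2 = 9e-4, mask = NULL) {
  xv <- as.vector(x); rv <- as.vector(r)
  if (!is.null(mask)) {
    keep <- as.vector(mask) > 0
    xv <- xv[keep]; rv <- rv[keep]
  }
  n <- length(xv)
  mx <- sum(xv) / n; mr <- sum(rv) / n
  vx <- sum((xv - mx)^2) / n
  vr <- sum((rv - mr)^2) / n
  cv <- sum((xv - mx) * (rv - mr)) / n
  (2 * mx * mr + c1) * (2 * cv + c2) /
    ((mx^2 + mr^2 + c1) * (vx + vr + c2))
}

# step-by-step multiscale reimplementation: 2x2 mean pooling, per-scale
# contrast/structure, luminance at the coarsest scale
msssim_oracle <- function(x, r, scales, weights, c1 = 1e-4, c2 = 9e-4) {
  pool <- function(m) {
    h <- nrow(m) %/% 2; w <- ncol(m) %/% 2
    out <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w))
      out[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    out
  }
  total <- 1
  for (s in seq_len(scales)) {
    xv <- as.vector(x); rv <- as.vector(r); n <- length(xv)
    mx <- mean(xv); mr <- mean(rv)
    vx <- mean((xv - mx)^2); vr <- mean((rv - mr)^2)
    cv <- mean((xv - mx) * (rv - mr))
    cs <- max((2 * cv + c2) / (vx + vr + c2), 0)
    if (s == scales) {
      l <- max((2 * mx * mr + c1) / (mx^2 + mr^2 + c1), 0)
      total <- total * (l * cs)^weights[s]
    } else {
      total <- total * cs^weights[s]
      x <- pool(x); r <- pool(r)
    }
  }
  total
}

hausdorff_oracle <- function(a, b) {
  pa <- which(a == 1, arr.ind = TRUE)
  pb <- which(b == 1, arr.ind = TRUE)
  directed <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sqrt((p[i, 1] - q[j, 1])^2 + (p[i, 2] - q[j, 2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

hist_distance_oracle <- function(a, b, n_bins) {
  count <- function(x) {
    cnt <- numeric(n_bins)
    for (v in as.vector(x)) {
      idx <- if (v >= 1) n_bins else floor(v * n_bins) + 1
      cnt[idx] <- cnt[idx] + 1
    }
    cnt / length(x)
  }
  0.5 * sum(abs(count(a) - count(b)))
}

# longhand paired t statistic and two-sided p value
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, p = 2 * pt(-abs(tval), df = n - 1))
}

# Mann-Whitney concordant-pair AUC with ties counted half
auc_oracle <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (i in seq_along(sp)) for (j in seq_along(sn))
    tot <- tot + (sp[i] > sn[j]) + 0.5 * (sp[i] == sn[j])
  tot / (length(sp) * length(sn))
}

# naive direct convolution (zero padding) for cross-checking the
# im2col/GEMM path
conv_oracle <- function(x, W4, stride, pad) {
  k <- dim(W4)[1]; cin <- dim(W4)[3]; cout <- dim(W4)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  ho <- (H + 2 * pad - k) %/% stride + 1
  wo <- (Wd + 2 * pad - k) %/% stride + 1
  out <- array(0, c(ho, wo, cout))
  for (oc in seq_len(cout)) for (oh in seq_len(ho)) for (ow in seq_len(wo)) {
    acc <- 0
    for (ic in seq_len(cin)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
      hi <- (oh - 1) * stride - pad + kh
      wi <- (ow - 1) * stride - pad + kw
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= Wd)
        acc <- acc + x[hi, wi, ic] * W4[kh, kw, ic, oc]
    }
    out[oh, ow, oc] <- acc
  }
  out
}
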