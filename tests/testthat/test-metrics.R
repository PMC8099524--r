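# Metric suite against independent brute-force oracles, plus symmetry,
# monotonicity and the Dice/Hausdorff anti-correlation property.

test_that("PSNR matches its closed form and the brute-force oracle", {
  # MAX_range 1, uniform absolute error 0.1 (MSE 0.01) -> 20 dB
  x <- matrix(0.9, 16, 16)
  expect_equal(psnr(x, x + 0.1), 20, tolerance = 1e-9)
  expect_identical(psnr(x, x), Inf)
  set.seed(30)
  for (i in 1:50) {
    a <- matrix(runif(256), 16, 16)
    b <- matrix(runif(256), 16, 16)
    expect_equal(psnr(a, b), psnr_oracle(a, b), tolerance = 1e-9)
    m <- random_mask()
    expect_equal(psnr(a, b, m), psnr_oracle(a, b, m), tolerance = 1e-9)
  }
})

test_that("SSIM matches the direct formula, including degenerate cases", {
  set.seed(31)
  a <- matrix(runif(256), 16, 16)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  # constant images with unit separation: only the luminance term survives
  z <- matrix(0, 16, 16); o <- matrix(1, 16, 16)
  expect_equal(ssim(z, o), 1e-4 / (1 + 1e-4), tolerance = 1e-9)
  for (i in 1:50) {
    x <- matrix(runif(256), 16, 16)
    r <- matrix(runif(256), 16, 16)
    expect_equal(ssim(x, r), ssim_oracle(x, r), tolerance = 1e-9)
    m <- random_mask()
    expect_equal(ssim(x, r, region_mask = m), ssim_oracle(x, r, mask = m),
                 tolerance = 1e-9)
    expect_equal(ssim(x, r), ssim(r, x), tolerance = 1e-12)  # symmetry
  }
})

test_that("MS-SSIM reduces to SSIM at one scale and matches its oracle", {
  set.seed(32)
  x <- matrix(runif(64 * 64), 64, 64)
  r <- pmin(pmax(x + rnorm(64 * 64, 0, 0.05), 0), 1)
  expect_equal(ms_ssim(x, x), 1, tolerance = 1e-9)
  expect_equal(ms_ssim(x, r, scales = 1, weights = 1), ssim(x, r),
               tolerance = 1e-12)
  for (i in 1:5) {
    a <- matrix(runif(64 * 64), 64, 64)
    b <- matrix(runif(64 * 64), 64, 64)
    w <- c(0.2, 0.3, 0.5)
    expect_equal(ms_ssim(a, b, scales = 3, weights = w),
                 msssim_oracle(a, b, 3, w), tolerance = 1e-6)
  }
  expect_error(ms_ssim(matrix(0.2, 4, 4), matrix(0.3, 4, 4), scales = 5,
                       weights = rep(0.2, 5)), "weight")
})

test_that("Dice handles identity, disjoint and arithmetic cases", {
  m <- random_mask(8)
  expect_equal(dice(m, m), 1)
  a <- matrix(0, 8, 8); a[1:2, 1:2] <- 1
  b <- matrix(0, 8, 8); b[5:6, 5:6] <- 1
  expect_equal(dice(a, b), 0)
  y <- matrix(0, 4, 4); y[1, 1:4] <- 1
  p <- matrix(0, 4, 4); p[1, 3:4] <- 1; p[2, 1:2] <- 1
  expect_equal(dice(y, p), 0.5)   # |y|=4, |p|=4, overlap 2
  expect_warning(d0 <- dice(matrix(0, 4, 4), matrix(0, 4, 4)), "empty")
  expect_equal(d0, 1)
})

test_that("Hausdorff matches the exhaustive double-loop oracle exactly", {
  a <- matrix(0, 6, 6); a[1, 1] <- 1
  b <- matrix(0, 6, 6); b[4, 5] <- 1
  expect_identical(hausdorff(a, b), 5)   # 3-4-5 triangle
  expect_identical(hausdorff(a, a), 0)
  set.seed(33)
  for (i in 1:50) {
    x <- random_mask(10, 0.2)
    y <- random_mask(10, 0.2)
    expect_identical(hausdorff(x, y), hausdorff_oracle(x, y))
    expect_identical(hausdorff(x, y), hausdorff(y, x))
  }
  expect_error(hausdorff(a, matrix(0, 6, 6)), "empty")
})

test_that("histogram comparison matches exact bin counting", {
  a <- matrix(runif(256), 16, 16)
  expect_equal(histogram_compare(a, a, 32)$distance, 0)
  expect_equal(histogram_compare(matrix(0, 8, 8), matrix(1, 8, 8),
                                 16)$distance, 1)
  set.seed(34)
  for (i in 1:25) {
    x <- matrix(runif(256), 16, 16)
    y <- matrix(runif(256), 16, 16)
    h <- histogram_compare(x, y, 64)
    expect_identical(h$distance, hist_distance_oracle(x, y, 64))
    expect_identical(h$distance, histogram_compare(y, x, 64)$distance)
  }
  expect_error(histogram_compare(a, a, 1), "n_bins")
})

test_that("paired t-test matches the longhand formula", {
  set.seed(35)
  a <- rnorm(30, 1, 1); b <- a + rnorm(30, 0.5, 0.5)
  got <- paired_t_test(a, b)
  want <- paired_t_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)
  expect_identical(got$significant, want$p < 0.05)
  sym <- paired_t_test(c(1, 2), c(2, 1))   # differences +1, -1
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  expect_error(paired_t_test(a, a), "zero-variance")
})

test_that("noise monotonically degrades expected PSNR and SSIM", {
  set.seed(36)
  ph <- generate_phantoms(phantom_config(image_size = 32, n_samples = 1,
                                         seed = 50))[[1]]
  amps <- c(0.01, 0.05, 0.1, 0.2)
  mp <- ms <- numeric(length(amps))
  for (k in seq_along(amps)) {
    ps <- ss <- numeric(20)
    for (r in 1:20) {
      noisy <- pmin(pmax(ph$image + rnorm(length(ph$image), 0, amps[k]), 0), 1)
      noisy <- matrix(noisy, 32, 32)
      ps[r] <- psnr(ph$image, noisy)
      ss[r] <- ssim(ph$image, noisy)
    }
    mp[k] <- mean(ps); ms[k] <- mean(ss)
  }
  expect_true(all(diff(mp) < 0))
  expect_true(all(diff(ms) < 0))
})

test_that("erosion trades Dice against Hausdorff in opposite directions", {
  n <- 48
  disk <- function(r) {
    d <- sqrt(outer((1:n - n / 2)^2, (1:n - n / 2)^2, "+"))
    (d <= r) + 0
  }
  y <- disk(16)
  radii <- c(16, 13, 10, 7, 4)
  dices <- vapply(radii, function(r) dice(y, disk(r)), numeric(1))
  hds <- vapply(radii, function(r) hausdorff(y, disk(r)), numeric(1))
  expect_true(all(diff(dices) <= 0))
  expect_true(all(diff(hds) >= 0))
})

test_that("evaluate aggregates per-sample metrics like Tables of mean ± SD", {
  set.seed(37)
  orig <- generate_phantoms(phantom_config(image_size = 32, n_samples = 4,
                                           seed = 60))
  synt <- lapply(orig, function(s) {
    img <- matrix(pmin(pmax(s$image + rnorm(1024, 0, 0.03), 0), 1), 32, 32)
    paired_sample(img, s$mask, paste0(s$sample_id, "_s"), s$group_label)
  })
  rep <- evaluate(orig, synt, region = "whole")
  expect_equal(nrow(rep$per_sample), 4)
  agg <- rep$aggregate
  expect_equal(agg$mean[agg$metric == "psnr"], mean(rep$per_sample$psnr),
               tolerance = 1e-12)
  expect_equal(agg$sd[agg$metric == "ssim"], sd(rep$per_sample$ssim),
               tolerance = 1e-12)
  # per-sample rows match direct recomputation
  expect_equal(rep$per_sample$psnr[2], psnr(orig[[2]]$image, synt[[2]]$image),
               tolerance = 1e-12)
  expect_true(all(rep$per_sample$dice == 1))
  expect_true(all(rep$per_sample$hausdorff == 0))

  # identical pairs: similarity metrics saturate, PSNR becomes the sentinel
  perfect <- evaluate(orig, orig, region = "tumor")
  expect_true(all(perfect$per_sample$ssim == 1))
  expect_true(all(is.infinite(perfect$per_sample$psnr)))
  expect_equal(perfect$aggregate$n_excluded[perfect$aggregate$metric == "psnr"], 4)
})
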