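# Architecture contracts: layer censuses, the printed shape anchors, and
# forward-pass behavior of the three network builders.

test_that("RFB census and restoration contract hold", {
  spec <- build_rfb_spec(64L, feature_channels = 8L)
  cen <- layer_census(spec)
  expect_equal(cen[["mirror_pad"]], 2L)
  expect_equal(cen[["conv"]], 3L)
  expect_equal(cen[["deconv"]], 1L)
  set.seed(10)
  params <- init_network_params(spec)
  region <- matrix(runif(64 * 64), 64, 64)
  out <- network_forward(spec, params, region)
  expect_identical(dim(out), c(64L, 64L, 8L))
  spec5 <- build_rfb_spec(64L, feature_channels = 5L)
  tr <- shape_trace(spec5)
  expect_equal(tr$channels[nrow(tr)], 5L)
})

test_that("generator shows the printed shape anchors at 256", {
  spec <- build_generator_spec(256L, in_channels = 9L)
  tr <- shape_trace(spec)
  expect_equal(unlist(tr[tr$layer == "pad", c("height", "width")]),
               c(height = 262L, width = 262L))
  post3 <- tr[tr$layer == "conv3", ]
  expect_equal(c(post3$height, post3$width, post3$channels), c(64L, 64L, 128L))
  expect_equal(unlist(tr[nrow(tr), c("height", "width", "channels")]),
               c(height = 256L, width = 256L, channels = 1L))
  cen <- layer_census(spec)
  expect_equal(cen[["conv"]], 4L)
  expect_equal(cen[["concat_fusion"]], 2L)
  expect_equal(cen[["deconv"]], 2L)
  expect_error(build_generator_spec(130L), "image_size")
})

test_that("generator output matches the input size for several sizes", {
  for (S in c(32L, 64L)) {
    spec <- build_generator_spec(S, in_channels = 2L)
    set.seed(11)
    params <- init_network_params(spec)
    out <- network_forward(spec, params, array(runif(S * S * 2), c(S, S, 2)))
    expect_identical(dim(out), c(S, S, 1L))
    expect_true(all(out >= 0 & out <= 1))
  }
  # shape arithmetic alone for the full-scale sizes
  for (S in c(128L, 256L)) {
    tr <- shape_trace(build_generator_spec(S))
    expect_equal(tr$height[nrow(tr)], S)
  }
})

test_that("generator shape trace matches a hand-computed table at 64", {
  tr <- shape_trace(build_generator_spec(64L, in_channels = 9L))
  expect_equal(tr[tr$layer == "pad", "height"], 70L)
  expect_equal(tr[tr$layer == "conv1", "height"], 64L)
  expect_equal(tr[tr$layer == "conv1", "channels"], 32L)
  expect_equal(tr[tr$layer == "conv2", "height"], 32L)
  expect_equal(tr[tr$layer == "conv3", "height"], 16L)
  expect_equal(tr[tr$layer == "conv4", "height"], 16L)
  expect_equal(tr[tr$layer == "conv4", "channels"], 128L)
  expect_equal(tr[tr$layer == "deconv1", "height"], 32L)
  expect_equal(tr[tr$layer == "fuse1", "channels"], 64L)
  expect_equal(tr[tr$layer == "deconv2", "height"], 64L)
  expect_equal(tr[tr$layer == "fuse2", "channels"], 1L)
})

test_that("discriminator census and output range hold", {
  spec <- build_discriminator_spec(64L)
  cen <- layer_census(spec)
  expect_equal(cen[["conv"]], 4L)
  expect_equal(cen[["flatten"]], 1L)
  expect_equal(cen[["dense"]], 1L)
  sig <- vapply(spec$layers, function(l)
    identical(l$activation_name, "sigmoid"), TRUE)
  expect_equal(sum(sig), 1L)
  expect_identical(spec$layers[[length(spec$layers)]]$activation_name,
                   "sigmoid")

  set.seed(12)
  params <- init_network_params(spec)
  for (i in 1:3) {
    out <- network_forward(spec, params, matrix(rnorm(64 * 64, sd = 3), 64, 64))
    expect_length(out, 1L)
    expect_true(out > 0 && out < 1)
  }
  # all-zero weights: sigmoid(0) = 0.5 exactly
  zero <- rapply(params, function(x) x * 0, how = "replace")
  expect_equal(network_forward(spec, zero, matrix(runif(64 * 64), 64, 64)),
               0.5)
})

test_that("forward passes are deterministic", {
  spec <- build_generator_spec(32L, in_channels = 1L)
  set.seed(13)
  params <- init_network_params(spec)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(network_forward(spec, params, x),
                   network_forward(spec, params, x))
})

test_that("regional feature fusion concatenates with the image first", {
  img <- matrix(runif(16 * 16), 16, 16)
  feats <- array(runif(16 * 16 * 8), c(16, 16, 8))
  fused <- fuse_regional_features(img, feats)
  expect_identical(dim(fused), c(16L, 16L, 9L))
  expect_identical(fused[, , 1], img)
  expect_identical(fused[, , 2:9], feats)
  expect_error(fuse_regional_features(img, array(0, c(8, 8, 2))),
               "mismatch")
})

test_that("network specs round-trip through their JSON serialization", {
  spec <- build_generator_spec(64L, in_channels = 9L)
  path <- file.path(withr::local_tempdir(), "gen.json")
  spec_to_json(spec, path)
  back <- spec_from_json(path)
  expect_identical(shape_trace(back), shape_trace(spec))
  expect_identical(layer_census(back), layer_census(spec))
  set.seed(15)
  p1 <- init_network_params(spec)
  set.seed(15)
  p2 <- init_network_params(back)
  x <- array(runif(64 * 64 * 9), c(64, 64, 9))
  expect_identical(network_forward(spec, p1, x), network_forward(back, p2, x))
})

test_that("forward input contracts are enforced", {
  spec <- build_generator_spec(32L, in_channels = 9L)
  set.seed(14)
  params <- init_network_params(spec)
  expect_error(network_forward(spec, params, matrix(0.5, 32, 32)), "channel")
})
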