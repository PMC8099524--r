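# Declarative network specifications for the three architectures: the
# regional feature extraction block (RFB), the image<->ROI generators, and
# the discriminators. A spec is an ordered list of layer descriptions with
# hard shape contracts; parameters live in a separate named list so the
# architecture itself is auditable plain data.

new_layer <- function(kind, name, kernel = NULL, stride = 1L, pad = 0L,
                      out_pad = 0L, out_channels = NULL,
                      activation_name = NULL, slope = NULL, with = NULL) {
  if (!is.null(slope) && (slope <= 0 || slope >= 1))
    stop_field("slope", "leaky-ReLU negative slope must lie in (0,1)")
  list(kind = kind, name = name, kernel = kernel, stride = as.integer(stride),
       pad = as.integer(pad), out_pad = as.integer(out_pad),
       out_channels = out_channels, activation_name = activation_name,
       slope = slope, with = with)
}

# Walk the layer list, fill per-layer input shapes/channels and resolve
# fusion references; errors if the shape arithmetic breaks down.
propagate_shapes <- function(layers, input_size, input_channels) {
  h <- input_size; w <- input_size; c <- input_channels
  flat <- NA_integer_
  trace <- vector("list", length(layers))
  shapes <- vector("list", length(layers))
  names_ <- vapply(layers, `[[`, "", "name")
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    l$in_channels <- c
    l$in_size <- c(h, w)
    switch(l$kind,
      mirror_pad = { h <- h + 2L * l$pad; w <- w + 2L * l$pad },
      conv = {
        h2 <- (h + 2L * l$pad - l$kernel) %/% l$stride + 1L
        w2 <- (w + 2L * l$pad - l$kernel) %/% l$stride + 1L
        if (h2 < 1L || w2 < 1L)
          stop(sprintf("layer '%s': input %dx%d too small for kernel %d stride %d",
                       l$name, h, w, l$kernel, l$stride))
        h <- h2; w <- w2; c <- l$out_channels
      },
      deconv = {
        h2 <- (h - 1L) * l$stride - 2L * l$pad + l$kernel + l$out_pad
        w2 <- (w - 1L) * l$stride - 2L * l$pad + l$kernel + l$out_pad
        # the scatter implementation requires the reverse conv map to be exact
        if ((h2 + 2L * l$pad - l$kernel) %/% l$stride + 1L != h)
          stop(sprintf("layer '%s': transposed-conv geometry inconsistent", l$name))
        h <- h2; w <- w2; c <- l$out_channels
      },
      instance_norm = NULL,
      activation = NULL,
      flatten = { flat <- h * w * c },
      dense = {
        if (is.na(flat)) stop("dense layer requires a preceding flatten")
        l$in_features <- flat
        flat <- l$out_channels
      },
      concat_fusion = {
        idx <- match(l$with, names_)
        if (is.na(idx) || idx >= i)
          stop(sprintf("fusion layer '%s': unknown source '%s'", l$name, l$with))
        sh <- shapes[[idx]]
        if (sh$h != h || sh$w != w)
          stop(sprintf("fusion layer '%s': spatial dims %dx%d vs skip %dx%d",
                       l$name, h, w, sh$h, sh$w))
        l$with_idx <- idx
        l$in_channels_total <- c + sh$c
        c <- l$out_channels
      },
      stop("unknown layer kind: ", l$kind))
    shapes[[i]] <- list(h = h, w = w, c = c)
    trace[[i]] <- data.frame(layer = l$name, kind = l$kind,
                             height = if (l$kind %in% c("flatten", "dense")) NA_integer_ else h,
                             width = if (l$kind %in% c("flatten", "dense")) NA_integer_ else w,
                             channels = if (l$kind == "flatten") flat
                                        else if (l$kind == "dense") l$out_channels
                                        else c,
                             stringsAsFactors = FALSE)
    layers[[i]] <- l
  }
  list(layers = layers, trace = do.call(rbind, trace))
}

new_network_spec <- function(name, layers, input_size, input_channels) {
  ps <- propagate_shapes(layers, input_size, input_channels)
  structure(list(name = name, layers = ps$layers,
                 input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 trace = ps$trace),
            class = "network_spec")
}

#' Layer-kind census of a network specification
#'
#' Counts how many layers of each kind a [network spec][build_rfb_spec]
#' contains, e.g. `c(mirror_pad = 2, conv = 3, deconv = 1)` for the RFB.
#'
#' @param spec A `network_spec`.
#' @return Named integer vector of layer-kind counts.
#' @export
layer_census <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  table(kinds) |> c()
}

#' Per-layer shape trace of a network specification
#'
#' Runs the spec's shape arithmetic without touching any parameters and
#' returns the output height/width/channels after every layer. This is how
#' the hard shape contracts (e.g. mirror pad 256 -> 262, bottleneck
#' 64x64x128) are audited.
#'
#' @param spec A `network_spec`.
#' @return `data.frame` with columns `layer`, `kind`, `height`, `width`,
#'   `channels` (spatial dims are `NA` after flattening).
#' @export
shape_trace <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  spec$trace
}

#' Regional feature extraction block (RFB) specification
#'
#' The RFB is a small convolutional network applied to the *region image*
#' (image x mask elementwise product). It consists of two mirror-fill
#' layers, three convolutional layers (each followed by instance
#' normalization and a ReLU), and one transposed-convolution layer that
#' restores the spatial dimensions so its output can be channel-fused with
#' the image. Channel plan 16/32/64 with 3x3 kernels, strides (1, 2, 1),
#' and a stride-2 transposed conv back to full resolution.
#'
#' @param image_size Side length in pixels (even, >= 16).
#' @param feature_channels Number of regional feature maps produced
#'   (default 8).
#' @param in_channels Channels of the region image (default 1).
#' @return A `network_spec`.
#' @export
build_rfb_spec <- function(image_size, feature_channels = 8L, in_channels = 1L) {
  if (image_size < 16L || image_size %% 2L != 0L)
    stop_field("image_size", "RFB stride plan requires an even size >= 16")
  layers <- list(
    new_layer("mirror_pad", "pad1", pad = 1L),
    new_layer("conv", "conv1", kernel = 3L, stride = 1L, pad = 0L, out_channels = 16L),
    new_layer("instance_norm", "in1"),
    new_layer("activation", "act1", activation_name = "relu"),
    new_layer("mirror_pad", "pad2", pad = 1L),
    new_layer("conv", "conv2", kernel = 3L, stride = 2L, pad = 0L, out_channels = 32L),
    new_layer("instance_norm", "in2"),
    new_layer("activation", "act2", activation_name = "relu"),
    new_layer("conv", "conv3", kernel = 3L, stride = 1L, pad = 1L, out_channels = 64L),
    new_layer("instance_norm", "in3"),
    new_layer("activation", "act3", activation_name = "relu"),
    new_layer("deconv", "deconv1", kernel = 3L, stride = 2L, pad = 1L,
              out_pad = 1L, out_channels = as.integer(feature_channels)),
    new_layer("instance_norm", "in4"),
    new_layer("activation", "act4", activation_name = "relu"))
  new_network_spec("rfb", layers, image_size, in_channels)
}

#' Generator specification (image-domain <-> ROI-domain translators)
#'
#' Encoder-decoder generator used for both translation directions. The
#' input is first mirror-filled by 3 pixels (256x256 -> 262x262), then four
#' convolutional layers (7x7/32 stride 1; 3x3/64 stride 2; 3x3/128 stride
#' 2 — yielding the 128-channel bottleneck at a quarter of the input
#' resolution, 64x64 for a 256 input; 3x3/128 stride 1) extract structural
#' features. Two transposed-convolution layers restore the resolution, and
#' two fusion layers concatenate encoder features at the half and full
#' resolutions (preserving low-level image information) followed by a 1x1
#' channel merge. The second fusion's merge projects to the output channel
#' and a sigmoid maps intensities to [0,1].
#'
#' @param image_size Side length in pixels, divisible by 4.
#' @param in_channels Input channels (1 for the plain ROI/image, 1 +
#'   `feature_channels` for the fused domain-X input).
#' @param out_channels Output channels (default 1).
#' @return A `network_spec`.
#' @export
build_generator_spec <- function(image_size, in_channels = 1L, out_channels = 1L) {
  if (image_size %% 4L != 0L)
    stop_field("image_size", "generator downsampling requires a multiple of 4")
  layers <- list(
    new_layer("mirror_pad", "pad", pad = 3L),
    new_layer("conv", "conv1", kernel = 7L, stride = 1L, pad = 0L, out_channels = 32L),
    new_layer("instance_norm", "in1"),
    new_layer("activation", "act1", activation_name = "relu"),
    new_layer("conv", "conv2", kernel = 3L, stride = 2L, pad = 1L, out_channels = 64L),
    new_layer("instance_norm", "in2"),
    new_layer("activation", "act2", activation_name = "relu"),
    new_layer("conv", "conv3", kernel = 3L, stride = 2L, pad = 1L, out_channels = 128L),
    new_layer("instance_norm", "in3"),
    new_layer("activation", "act3", activation_name = "relu"),
    new_layer("conv", "conv4", kernel = 3L, stride = 1L, pad = 1L, out_channels = 128L),
    new_layer("instance_norm", "in4"),
    new_layer("activation", "act4", activation_name = "relu"),
    new_layer("deconv", "deconv1", kernel = 3L, stride = 2L, pad = 1L,
              out_pad = 1L, out_channels = 64L),
    new_layer("instance_norm", "in5"),
    new_layer("activation", "act5", activation_name = "relu"),
    new_layer("concat_fusion", "fuse1", with = "act2", out_channels = 64L),
    new_layer("instance_norm", "in6"),
    new_layer("activation", "act6", activation_name = "relu"),
    new_layer("deconv", "deconv2", kernel = 3L, stride = 2L, pad = 1L,
              out_pad = 1L, out_channels = 32L),
    new_layer("instance_norm", "in7"),
    new_layer("activation", "act7", activation_name = "relu"),
    new_layer("concat_fusion", "fuse2", with = "act1",
              out_channels = as.integer(out_channels)),
    new_layer("activation", "act_out", activation_name = "sigmoid"))
  new_network_spec("generator", layers, image_size, in_channels)
}

#' Discriminator specification
#'
#' Four strided convolutional layers (4x4 kernels, stride 2, channel plan
#' 64/128/256/512, DCGAN-style leaky-ReLU with slope 0.2 after every conv
#' block), a flatten layer, a dense layer reducing the features to one
#' dimension, and a sigmoid activation that scores the input as real
#' (near 1) or synthetic (near 0).
#'
#' @param image_size Side length in pixels, a multiple of 16 and >= 16.
#' @param in_channels Input channels (default 1).
#' @return A `network_spec`.
#' @export
build_discriminator_spec <- function(image_size, in_channels = 1L) {
  if (image_size < 16L || image_size %% 16L != 0L)
    stop_field("image_size", "four stride-2 convolutions require a multiple of 16")
  layers <- list(
    new_layer("conv", "conv1", kernel = 4L, stride = 2L, pad = 1L, out_channels = 64L),
    new_layer("activation", "act1", activation_name = "leaky_relu", slope = 0.2),
    new_layer("conv", "conv2", kernel = 4L, stride = 2L, pad = 1L, out_channels = 128L),
    new_layer("activation", "act2", activation_name = "leaky_relu", slope = 0.2),
    new_layer("conv", "conv3", kernel = 4L, stride = 2L, pad = 1L, out_channels = 256L),
    new_layer("activation", "act3", activation_name = "leaky_relu", slope = 0.2),
    new_layer("conv", "conv4", kernel = 4L, stride = 2L, pad = 1L, out_channels = 512L),
    new_layer("activation", "act4", activation_name = "leaky_relu", slope = 0.2),
    new_layer("flatten", "flat"),
    new_layer("dense", "dense", out_channels = 1L),
    new_layer("activation", "act_out", activation_name = "sigmoid"))
  new_network_spec("discriminator", layers, image_size, in_channels)
}

#' Initialize network parameters
#'
#' Weights are drawn from a Gaussian with mean 0 and standard deviation
#' 0.02 (the usual initialization for cycle-consistent GANs); biases start
#' at zero. Instance normalization carries no learnable affine parameters.
#' Draws come from the current R RNG stream, so seeding the session (or
#' the training configuration) makes initialization reproducible.
#'
#' @param spec A `network_spec`.
#' @param sd Initialization standard deviation (default 0.02).
#' @return Named list of per-layer parameter lists.
#' @export
init_network_params <- function(spec, sd = 0.02) {
  stopifnot(inherits(spec, "network_spec"))
  params <- list()
  for (l in spec$layers) {
    params[[l$name]] <- switch(l$kind,
      conv = list(
        W = matrix(rnorm(l$kernel^2 * l$in_channels * l$out_channels, 0, sd),
                   nrow = l$kernel^2 * l$in_channels),
        b = numeric(l$out_channels)),
      deconv = list(
        W = matrix(rnorm(l$kernel^2 * l$out_channels * l$in_channels, 0, sd),
                   nrow = l$kernel^2 * l$out_channels),
        b = numeric(l$out_channels)),
      dense = list(
        W = matrix(rnorm(l$in_features * l$out_channels, 0, sd),
                   nrow = l$in_features),
        b = numeric(l$out_channels)),
      concat_fusion = list(
        W = matrix(rnorm(l$in_channels_total * l$out_channels, 0, sd),
                   nrow = l$in_channels_total),
        b = numeric(l$out_channels)),
      NULL)
  }
  params
}

#' Run a network forward pass
#'
#' Applies the layers of `spec` with parameters `params` to a single input
#' sample. Deterministic: the same spec, parameters and input always give
#' the same output.
#'
#' @param spec A `network_spec`.
#' @param params Parameters from [init_network_params()] (or trained).
#' @param input A matrix or H x W x C array matching the spec's input
#'   size and channel count.
#' @return The network output: an H x W x C array, or a numeric vector for
#'   networks ending in a dense layer (the discriminator returns a single
#'   scalar strictly inside (0,1)).
#' @export
network_forward <- function(spec, params, input) {
  stopifnot(inherits(spec, "network_spec"))
  net_forward(spec, params, input)$out
}

#' Fuse an image with its regional feature maps
#'
#' Concatenates the image (channel 1) with the RFB feature maps along the
#' channel axis, producing the fused domain-X input. Channel 1 of the
#' result is always the unmodified image.
#'
#' @param image 2D matrix or single-channel array.
#' @param rfb_features H x W x C array of regional feature maps with the
#'   same spatial dimensions as `image`.
#' @return H x W x (1 + C) array.
#' @export
fuse_regional_features <- function(image, rfb_features) {
  img <- as_hwc(image)
  f <- as_hwc(rfb_features)
  di <- dim(img); df <- dim(f)
  if (di[1] != df[1] || di[2] != df[2])
    stop("image and feature maps have mismatched spatial dimensions")
  array(c(img, f), c(di[1], di[2], di[3] + df[3]))
}

#' Serialize a network specification to plain text (JSON)
#'
#' Writes the layer inventory (kind, kernel, stride, padding, channels,
#' activations, fusion sources) plus input size/channels as JSON so an
#' architecture can be audited or diffed outside R. `spec_from_json()`
#' rebuilds the `network_spec`, re-running the shape arithmetic.
#'
#' @param spec A `network_spec`.
#' @param path Destination file (`spec_to_json`) or source file
#'   (`spec_from_json`).
#' @return `spec_to_json()` returns `path` invisibly; `spec_from_json()`
#'   returns the reconstructed `network_spec`.
#' @export
spec_to_json <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  fields <- c("kind", "name", "kernel", "stride", "pad", "out_pad",
              "out_channels", "activation_name", "slope", "with")
  layers <- lapply(spec$layers, function(l) {
    keep <- l[fields]
    keep[!vapply(keep, is.null, TRUE)]
  })
  obj <- list(name = spec$name, input_size = spec$input_size,
              input_channels = spec$input_channels, layers = layers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  obj <- jsonlite::read_json(path)
  layers <- lapply(obj$layers, function(l) {
    new_layer(kind = l$kind, name = l$name,
              kernel = if (is.null(l$kernel)) NULL else as.integer(l$kernel),
              stride = if (is.null(l$stride)) 1L else as.integer(l$stride),
              pad = if (is.null(l$pad)) 0L else as.integer(l$pad),
              out_pad = if (is.null(l$out_pad)) 0L else as.integer(l$out_pad),
              out_channels = if (is.null(l$out_channels)) NULL else
                as.integer(l$out_channels),
              activation_name = l$activation_name,
              slope = l$slope, with = l$with)
  })
  new_network_spec(obj$name, layers, as.integer(obj$input_size),
                   as.integer(obj$input_channels))
}
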