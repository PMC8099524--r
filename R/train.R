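# Alternating optimization of the region-fused cycle model. One training
# step processes one paired sample (batch size 1, instance-norm friendly):
# the discriminators D_y and D_x take a gradient step on the adversarial
# objective first, then the generators G, F and the RFB take a joint step
# on the full objective (both adversarial terms plus the weighted cycle
# term).

#' Training configuration
#'
#' @param epochs Number of passes over the training set (default 300).
#' @param learning_rate Adam learning rate (default 0.0002).
#' @param adam_beta1,adam_beta2 Adam moment decay rates; defaults are
#'   Adam's standard (0.9, 0.999).
#' @param batch_size Samples per optimizer step; fixed at 1 (per-sample
#'   instance normalization).
#' @param cycle_weight Weight `lambda` of the cycle-consistency term
#'   (default 10).
#' @param seed RNG seed controlling initialization and sample order.
#' @param image_size Side length of the training images (multiple of 16).
#' @param feature_channels RFB output channels fused with the image
#'   (default 8).
#' @param max_steps Optional cap on the total number of optimizer steps
#'   (overrides `epochs` when smaller); useful for desk-scale runs.
#' @param non_saturating If `TRUE`, generators minimize `-log D(fake)`
#'   instead of `log(1 - D(fake))`. Off by default: the objective is
#'   optimized exactly as written.
#' @return A validated `train_config` list.
#' @export
train_config <- function(epochs = 300L, learning_rate = 2e-4,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         batch_size = 1L, cycle_weight = 10,
                         seed = 1L, image_size = 64L,
                         feature_channels = 8L, max_steps = NULL,
                         non_saturating = FALSE) {
  if (learning_rate <= 0) stop_field("learning_rate", "must be positive")
  if (epochs < 0) stop_field("epochs", "must be non-negative")
  if (cycle_weight < 0) stop_field("cycle_weight", "must be non-negative")
  if (batch_size != 1L) stop_field("batch_size", "only batch size 1 is supported")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = 1L, cycle_weight = cycle_weight,
                 seed = as.integer(seed), image_size = as.integer(image_size),
                 feature_channels = as.integer(feature_channels),
                 max_steps = max_steps, non_saturating = non_saturating),
            class = "train_config")
}

build_model_specs <- function(image_size, feature_channels) {
  list(rfb = build_rfb_spec(image_size, feature_channels),
       G = build_generator_spec(image_size, 1L + feature_channels),
       F = build_generator_spec(image_size, 1L),
       Dx = build_discriminator_spec(image_size, 1L),
       Dy = build_discriminator_spec(image_size, 1L))
}

# forward through RFB + fusion + G for a (image, mask) pair; the region
# image is image * mask
fused_g_forward <- function(specs, params, image, mask) {
  region <- as_hwc(image * mask)
  fr <- net_forward(specs$rfb, params$rfb, region)
  xf <- fuse_regional_features(image, fr$out)
  fg <- net_forward(specs$G, params$G, xf)
  list(fr = fr, xf = xf, fg = fg, yhat = fg$out)
}

check_finite <- function(value, step, term) {
  if (!all(is.finite(value)))
    stop(sprintf("non-finite %s at step %d: training aborted", term, step),
         call. = FALSE)
  value
}

#' Train the region-fused cycle model
#'
#' Runs alternating adversarial optimization over the paired samples.
#' Per step: the sample's region image is passed through the RFB and
#' fused with the image to form the domain-X input; the ROI mask is the
#' domain-Y input. `D_y` and `D_x` are updated to maximize the
#' adversarial objective on (real ROI, `G(x)`) and (real image, `F(y)`)
#' respectively; then `G`, `F` and the RFB are updated jointly to
#' minimize both adversarial terms plus `cycle_weight` times the
#' cycle-consistency loss. Fully deterministic for a fixed seed on a
#' fixed machine.
#'
#' @param samples List of [paired_sample()] objects whose images match
#'   `config$image_size`.
#' @param config A [train_config()].
#' @return A `train_state` object: network specs, parameters, optimizer
#'   state, epoch counter, and the per-step loss history (`data.frame`
#'   with columns `step`, `l_gan_fwd`, `l_gan_bwd`, `l_cyc`, `total`).
#' @export
train <- function(samples, config) {
  stopifnot(inherits(config, "train_config"), length(samples) >= 1L)
  for (s in samples)
    if (!all(dim(s$image) == config$image_size))
      stop(sprintf("sample '%s' does not match image_size %d",
                   s$sample_id, config$image_size))
  specs <- build_model_specs(config$image_size, config$feature_channels)
  state <- with_seed(config$seed, {
    params <- lapply(specs, init_network_params)
    opt <- lapply(params, adam_init)
    st <- list(specs = specs, params = params, opt = opt, epoch = 0L,
               config = config, history = NULL)
    class(st) <- "train_state"
    n <- length(samples)
    total_steps <- config$epochs * n
    if (!is.null(config$max_steps))
      total_steps <- min(total_steps, as.integer(config$max_steps))
    history <- vector("list", total_steps)
    ord <- integer(0)
    step <- 0L
    while (step < total_steps) {
      if (step %% n == 0L) ord <- sample.int(n)
      step <- step + 1L
      s <- samples[[ord[(step - 1L) %% n + 1L]]]
      st <- train_step(st, s, step)
      history[[step]] <- st$last_losses
      st$epoch <- step %/% n
    }
    st$history <- if (total_steps > 0L)
      do.call(rbind, history) else
      data.frame(step = integer(), l_gan_fwd = numeric(),
                 l_gan_bwd = numeric(), l_cyc = numeric(), total = numeric())
    st$last_losses <- NULL
    st
  })
  state
}

# one alternating optimization step on a single paired sample
train_step <- function(st, s, step) {
  specs <- st$specs; params <- st$params; cfg <- st$config
  img <- as_hwc(s$image)
  msk <- as_hwc(s$mask)
  npx <- length(s$image)
  lam <- cfg$cycle_weight

  # ---- forward cycle (i): x -> G(x) -> F(G(x)) ---------------------------
  gf <- fused_g_forward(specs, params, s$image, s$mask)
  yhat <- gf$yhat
  ff <- net_forward(specs$F, params$F, yhat)
  xrec <- ff$out
  # ---- backward cycle (ii): y -> F(y) -> G(F(y)) -------------------------
  fy <- net_forward(specs$F, params$F, msk)
  xtil <- fy$out
  region2 <- xtil * c(msk)
  fr2 <- net_forward(specs$rfb, params$rfb, region2)
  xf2 <- fuse_regional_features(xtil, fr2$out)
  fg2 <- net_forward(specs$G, params$G, xf2)
  yrec <- fg2$out

  # ---- discriminator updates --------------------------------------------
  upd_d <- function(dspec, dp, dopt, real, fake) {
    fr <- net_forward(dspec, dp, real)
    fk <- net_forward(dspec, dp, fake)
    pr <- clamp01(fr$out); pk <- clamp01(fk$out)
    # D maximizes log(p_real) + log(1 - p_fake): descend on the negative
    gr <- net_backward(dspec, dp, fr, -1 / pr)$dparams
    gk <- net_backward(dspec, dp, fk, 1 / (1 - pk))$dparams
    a <- adam_step(dp, add_grads(gr, gk), dopt, cfg$learning_rate,
                   cfg$adam_beta1, cfg$adam_beta2)
    list(params = a$params, opt = a$state,
         loss = mean(log(pr)) + mean(log(1 - pk)))
  }
  dy <- upd_d(specs$Dy, params$Dy, st$opt$Dy, msk, yhat)
  dx <- upd_d(specs$Dx, params$Dx, st$opt$Dx, img, xtil)
  params$Dy <- dy$params; st$opt$Dy <- dy$opt
  params$Dx <- dx$params; st$opt$Dx <- dx$opt
  l_gan_fwd <- check_finite(dy$loss, step, "forward adversarial loss")
  l_gan_bwd <- check_finite(dx$loss, step, "backward adversarial loss")

  # ---- generator-side gradients (updated discriminators, frozen) --------
  dyf <- net_forward(specs$Dy, params$Dy, yhat)
  dxf <- net_forward(specs$Dx, params$Dx, xtil)
  py <- clamp01(dyf$out); px <- clamp01(dxf$out)
  # d/dp of the generator's adversarial term
  gy_scal <- if (cfg$non_saturating) -1 / py else -1 / (1 - py)
  gx_scal <- if (cfg$non_saturating) -1 / px else -1 / (1 - px)
  d_yhat_adv <- net_backward(specs$Dy, params$Dy, dyf, gy_scal,
                             want_params = FALSE)$dinput
  d_xtil_adv <- net_backward(specs$Dx, params$Dx, dxf, gx_scal,
                             want_params = FALSE)$dinput

  # cycle gradients (per-pixel L1)
  d_xrec <- lam * sign(xrec - img) / npx
  d_yrec <- lam * sign(yrec - msk) / npx

  # path (i): through F then G then RFB
  bF1 <- net_backward(specs$F, params$F, ff, d_xrec)
  d_yhat <- d_yhat_adv + bF1$dinput
  bG1 <- net_backward(specs$G, params$G, gf$fg, d_yhat)
  d_feat1 <- bG1$dinput[, , -1L, drop = FALSE]
  bR1 <- net_backward(specs$rfb, params$rfb, gf$fr, d_feat1)

  # path (ii): through G (fused on F(y)) then RFB and back into F
  bG2 <- net_backward(specs$G, params$G, fg2, d_yrec)
  d_xtil <- d_xtil_adv + bG2$dinput[, , 1L, drop = FALSE]
  d_feat2 <- bG2$dinput[, , -1L, drop = FALSE]
  bR2 <- net_backward(specs$rfb, params$rfb, fr2, d_feat2)
  d_xtil <- d_xtil + bR2$dinput * c(msk)   # region2 = xtil * mask
  bF2 <- net_backward(specs$F, params$F, fy, d_xtil)

  gG <- add_grads(bG1$dparams, bG2$dparams)
  gF <- add_grads(bF1$dparams, bF2$dparams)
  gR <- add_grads(bR1$dparams, bR2$dparams)
  for (nm in c("G", "F", "rfb")) {
    gr <- switch(nm, G = gG, F = gF, rfb = gR)
    a <- adam_step(params[[nm]], gr, st$opt[[nm]], cfg$learning_rate,
                   cfg$adam_beta1, cfg$adam_beta2)
    params[[nm]] <- a$params
    st$opt[[nm]] <- a$state
  }

  l_cyc <- check_finite(mean(abs(xrec - img)) + mean(abs(yrec - msk)),
                        step, "cycle loss")
  st$params <- params
  st$last_losses <- data.frame(
    step = step, l_gan_fwd = l_gan_fwd, l_gan_bwd = l_gan_bwd,
    l_cyc = l_cyc,
    total = total_objective(l_gan_fwd, l_gan_bwd, l_cyc, lam))
  st
}

#' @export
print.train_state <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<train_state> %d step(s), image size %d, lambda %.1f\n",
              n, x$config$image_size, x$config$cycle_weight))
  if (n > 0)
    cat(sprintf("  final losses: gan_fwd %.4f, gan_bwd %.4f, cyc %.4f\n",
                x$history$l_gan_fwd[n], x$history$l_gan_bwd[n],
                x$history$l_cyc[n]))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' Checkpoints are written with `saveRDS` and carry the full train state
#' (specs, parameters, optimizer state, loss history) so training can be
#' resumed or synthesis run later.
#'
#' @param state A `train_state`.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `train_state`.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "train_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "train_state")) stop("not a train_state checkpoint")
  state
}
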