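# Adversarial and cycle-consistency losses. Discriminator outputs are
# probabilities; logs are clamped at 1e-7 from both ends so the
# adversarial objective stays finite even when a discriminator saturates.

LOG_EPS <- 1e-7

clamp01 <- function(p) pmin(pmax(p, LOG_EPS), 1 - LOG_EPS)

#' Adversarial loss
#'
#' The GAN objective for a mapping G with discriminator D: the batch mean
#' of `log D(y) + log(1 - D(G(x)))`. The generator minimizes this value
#' while the discriminator maximizes it; a perfect discriminator
#' (`D(y) -> 1`, `D(G(x)) -> 0`) drives it to its maximum of 0, and an
#' undecided one (both outputs 0.5) gives `2 * log(0.5) = -1.386294...`.
#'
#' @param d_real_outputs Discriminator outputs on real samples, in (0,1).
#' @param d_fake_outputs Discriminator outputs on generated samples.
#' @return Scalar loss value.
#' @export
adversarial_loss <- function(d_real_outputs, d_fake_outputs) {
  vals <- c(d_real_outputs, d_fake_outputs)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("discriminator outputs must lie in (0,1)")
  mean(log(clamp01(d_real_outputs))) + mean(log(1 - clamp01(d_fake_outputs)))
}

#' Cycle-consistency loss
#'
#' Per-pixel mean absolute reconstruction error of both cycles:
#' `mean |F(G(x)) - x| + mean |G(F(y)) - y|`. The per-pixel normalization
#' makes the value resolution-independent; perfect reconstruction in both
#' directions gives 0, and a uniform 0.1 offset in each direction gives
#' 0.2.
#'
#' @param x Domain-X sample (array).
#' @param f_of_g_x Its reconstruction `F(G(x))`, same shape.
#' @param y Domain-Y sample.
#' @param g_of_f_y Its reconstruction `G(F(y))`, same shape.
#' @return Scalar loss value.
#' @export
cycle_loss <- function(x, f_of_g_x, y, g_of_f_y) {
  if (!identical(dim(as_hwc(x)), dim(as_hwc(f_of_g_x))) ||
      !identical(dim(as_hwc(y)), dim(as_hwc(g_of_f_y))))
    stop("cycle_loss: shape mismatch between samples and reconstructions")
  mean(abs(f_of_g_x - x)) + mean(abs(g_of_f_y - y))
}

#' Combined training objective
#'
#' `adv_xy + adv_yx + lambda * cyc`: the two directional adversarial terms
#' plus the cycle-consistency term weighted by `lambda`.
#'
#' @param adv_xy Adversarial loss of the X -> Y mapping.
#' @param adv_yx Adversarial loss of the Y -> X mapping.
#' @param cyc Cycle-consistency loss.
#' @param lambda Non-negative cycle weight (default 10).
#' @return Scalar objective value.
#' @export
total_objective <- function(adv_xy, adv_yx, cyc, lambda = 10) {
  if (lambda < 0) stop_field("lambda", "cycle weight must be non-negative")
  adv_xy + adv_yx + lambda * cyc
}
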