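# Layer primitives and the forward/backward interpreter used by every
# network in the package. Tensors are single samples stored as H x W x C
# arrays (column-major, channel last); batches are handled one sample at a
# time, which keeps instance normalization trivially batch-independent.

as_hwc <- function(x) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (length(dim(x)) != 3L) stop("expected a 2D matrix or H x W x C array")
  x
}

# ---- elementary layer forwards/backwards --------------------------------

conv_fwd <- function(x, W, b, k, s, p) {
  d <- dim(x)
  cols <- im2col_cpp(x, d[1], d[2], d[3], k, s, p)
  ho <- (d[1] + 2 * p - k) %/% s + 1L
  wo <- (d[2] + 2 * p - k) %/% s + 1L
  out <- crossprod(cols, W)               # (ho*wo) x Cout
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(ho, wo, ncol(W))), cols = cols)
}

conv_bwd <- function(g, x, cols, W, k, s, p) {
  d <- dim(x)
  gm <- matrix(g, ncol = dim(g)[3])       # (ho*wo) x Cout
  dW <- cols %*% gm
  db <- colSums(gm)
  dcols <- W %*% t(gm)                    # (k*k*Cin) x (ho*wo)
  dx <- col2im_cpp(dcols, d[1], d[2], d[3], k, s, p)
  list(dW = dW, db = db, dx = dx)
}

# Transposed convolution: forward is the scatter (col2im) adjoint of a
# conv whose geometry maps the large output grid back to the input grid.
deconv_fwd <- function(x, W, b, k, s, p, op, cout) {
  d <- dim(x)
  ho <- (d[1] - 1L) * s - 2L * p + k + op
  wo <- (d[2] - 1L) * s - 2L * p + k + op
  xm <- matrix(x, ncol = d[3])            # (h*w) x Cin
  cols <- W %*% t(xm)                     # (k*k*Cout) x (h*w)
  out <- col2im_cpp(cols, ho, wo, cout, k, s, p)
  out <- sweep(out, 3L, b, "+")
  list(out = out, xm = xm)
}

deconv_bwd <- function(g, xm, W, k, s, p, din, cout) {
  dg <- dim(g)
  dcols <- im2col_cpp(g, dg[1], dg[2], dg[3], k, s, p)  # (k*k*Cout) x (h*w)
  dW <- dcols %*% xm
  db <- apply(g, 3L, sum)
  dxm <- t(dcols) %*% W                   # (h*w) x Cin
  dx <- array(dxm, c(din[1], din[2], din[3]))
  list(dW = dW, db = db, dx = dx)
}

reflect_idx <- function(n, p) {
  # PyTorch-style reflection (edge not repeated): pad 2 on 1..4 -> 3 2 |1 2 3 4| 3 2
  idx <- (1L - p):(n + p)
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  idx
}

mirror_pad_fwd <- function(x, p) {
  d <- dim(x)
  ri <- reflect_idx(d[1], p)
  ci <- reflect_idx(d[2], p)
  x[ri, ci, , drop = FALSE]
}

mirror_pad_bwd <- function(g, din, p) {
  dp <- dim(g)
  ri <- reflect_idx(din[1], p)
  ci <- reflect_idx(din[2], p)
  m <- rowsum(matrix(g, dp[1]), ri)                     # H x (Wp*C)
  a <- array(m, c(din[1], dp[2], dp[3]))
  b <- aperm(a, c(2L, 1L, 3L))
  m2 <- rowsum(matrix(b, dp[2]), ci)                    # W x (H*C)
  aperm(array(m2, c(din[2], din[1], din[3])), c(2L, 1L, 3L))
}

inorm_fwd <- function(x, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, ncol = d[3])
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu, "-")
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  y <- sweep(xc, 2L, istd, "*")
  list(out = array(y, d), y = y, istd = istd)
}

inorm_bwd <- function(g, y, istd, d) {
  gm <- matrix(g, ncol = d[3])
  t1 <- sweep(gm, 2L, colMeans(gm), "-")
  t2 <- sweep(y, 2L, colMeans(gm * y), "*")
  array(sweep(t1 - t2, 2L, istd, "*"), d)
}

act_fwd <- function(x, name, slope) {
  switch(name,
    relu = pmax(x, 0),
    leaky_relu = pmax(x, 0) + slope * pmin(x, 0),
    sigmoid = 1 / (1 + exp(-x)),
    tanh = tanh(x),
    stop("unknown activation: ", name))
}

act_bwd <- function(g, x, out, name, slope) {
  switch(name,
    relu = g * (x > 0),
    leaky_relu = g * ((x > 0) + slope * (x <= 0)),
    sigmoid = g * out * (1 - out),
    tanh = g * (1 - out * out))
}

# ---- interpreter ---------------------------------------------------------

#' @noRd
net_forward <- function(spec, params, x) {
  x <- as_hwc(x)
  d <- dim(x)
  if (!is.null(spec$input_channels) && d[3] != spec$input_channels)
    stop(sprintf("network '%s' expects %d input channel(s), got %d",
                 spec$name, spec$input_channels, d[3]))
  L <- length(spec$layers)
  outs <- vector("list", L)
  caches <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    l <- spec$layers[[i]]
    pr <- params[[l$name]]
    r <- switch(l$kind,
      mirror_pad = list(out = mirror_pad_fwd(cur, l$pad)),
      conv = conv_fwd(cur, pr$W, pr$b, l$kernel, l$stride, l$pad),
      deconv = deconv_fwd(cur, pr$W, pr$b, l$kernel, l$stride, l$pad,
                          l$out_pad, l$out_channels),
      instance_norm = inorm_fwd(cur),
      activation = list(out = act_fwd(cur, l$activation_name, l$slope)),
      flatten = list(out = as.vector(cur), dims = dim(cur)),
      dense = list(out = drop(crossprod(pr$W, cur)) + pr$b),
      concat_fusion = {
        skip <- outs[[l$with_idx]]
        dm <- dim(cur)
        z <- array(c(cur, skip), c(dm[1], dm[2], dm[3] + dim(skip)[3]))
        zm <- matrix(z, ncol = dim(z)[3])
        om <- sweep(zm %*% pr$W, 2L, pr$b, "+")
        list(out = array(om, c(dm[1], dm[2], l$out_channels)), zm = zm,
             ca = dm[3])
      },
      stop("unknown layer kind: ", l$kind))
    outs[[i]] <- r$out
    r$out <- NULL
    caches[[i]] <- r
    cur <- outs[[i]]
  }
  list(out = cur, outs = outs, caches = caches, input = x)
}

#' @noRd
net_backward <- function(spec, params, fw, dout, want_params = TRUE) {
  L <- length(spec$layers)
  grads <- vector("list", L + 1L)  # grads[[i+1]] = d(loss)/d(output of layer i)
  acc <- function(i, g) {
    grads[[i + 1L]] <<- if (is.null(grads[[i + 1L]])) g else grads[[i + 1L]] + g
  }
  acc(L, dout)
  dparams <- if (want_params) list() else NULL
  for (i in rev(seq_len(L))) {
    l <- spec$layers[[i]]
    g <- grads[[i + 1L]]
    if (is.null(g)) next
    pr <- params[[l$name]]
    xin <- if (i == 1L) fw$input else fw$outs[[i - 1L]]
    ch <- fw$caches[[i]]
    switch(l$kind,
      mirror_pad = acc(i - 1L, mirror_pad_bwd(g, dim(xin), l$pad)),
      conv = {
        b <- conv_bwd(g, xin, ch$cols, pr$W, l$kernel, l$stride, l$pad)
        if (want_params) dparams[[l$name]] <- list(W = b$dW, b = b$db)
        acc(i - 1L, b$dx)
      },
      deconv = {
        b <- deconv_bwd(g, ch$xm, pr$W, l$kernel, l$stride, l$pad,
                        dim(xin), l$out_channels)
        if (want_params) dparams[[l$name]] <- list(W = b$dW, b = b$db)
        acc(i - 1L, b$dx)
      },
      instance_norm = acc(i - 1L, inorm_bwd(g, ch$y, ch$istd, dim(xin))),
      activation = acc(i - 1L,
        act_bwd(g, xin, fw$outs[[i]], l$activation_name, l$slope)),
      flatten = acc(i - 1L, array(g, ch$dims)),
      dense = {
        g <- as.numeric(g)
        if (want_params)
          dparams[[l$name]] <- list(W = outer(as.numeric(xin), g), b = g)
        acc(i - 1L, as.numeric(pr$W %*% g))
      },
      concat_fusion = {
        gm <- matrix(g, ncol = l$out_channels)
        if (want_params)
          dparams[[l$name]] <- list(W = crossprod(ch$zm, gm), b = colSums(gm))
        dz <- tcrossprod(gm, pr$W)
        dm <- dim(xin)
        ca <- ch$ca
        dz <- array(dz, c(dm[1], dm[2], ncol(dz)))
        acc(i - 1L, dz[, , seq_len(ca), drop = FALSE])
        acc(l$with_idx, dz[, , -seq_len(ca), drop = FALSE])
      })
  }
  list(dparams = dparams, dinput = grads[[1L]])
}

# ---- parameter utilities -------------------------------------------------

# elementwise sum of two nested parameter/gradient lists (NULL-tolerant)
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(b)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

scale_grads <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, scale_grads, s = s))
  a * s
}

adam_init <- function(params) {
  zeros <- function(p) if (is.list(p)) lapply(p, zeros) else p * 0
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    adam_update_cpp(p, g, m, v, lr, b1, b2, eps, t)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
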