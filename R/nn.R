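# Minimal convolutional-network engine.
#
# Everything downstream (DCGAN generator/discriminator, latent-space
# optimization) runs on these primitives. Design: samples are columns of a
# matrix; each sample is a channel-first tensor (C, H, W) flattened
# column-major with the channel index fastest. Convolutions are im2col +
# GEMM; the col2im scatter-add in the backward pass (and the
# fractionally-strided forward pass) is a precomputed sparse-matrix product.
# All parameters are plain numeric matrices/vectors, so models serialize with
# saveRDS and training is bit-reproducible from a seed.

# geometry shared by a strided conv (C_in,H,W) -> (C_out,outH,outW) and its
# adjoint; k = kernel, s = stride, p = zero padding
conv_geometry <- function(c_in, h, w, k, stride, pad) {
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  if ((hp - k) %% stride != 0L || (wp - k) %% stride != 0L)
    stop_arg("incompatible conv geometry: (", h, "x", w, "), k=", k, ", stride=", stride)
  out_h <- (hp - k) %/% stride + 1L
  out_w <- (wp - k) %/% stride + 1L
  cc <- rep(seq_len(c_in), h * w)
  hh <- rep(rep(seq_len(h), each = c_in), w)
  ww <- rep(seq_len(w), each = c_in * h)
  pad_pos <- cc + c_in * (hh + pad - 1L) + c_in * hp * (ww + pad - 1L)
  ckk <- c_in * k * k
  p_out <- out_h * out_w
  c_v <- rep(seq_len(c_in), k * k)
  kh_v <- rep(rep(seq_len(k), each = c_in), k)
  kw_v <- rep(seq_len(k), each = c_in * k)
  oh_v <- rep(seq_len(out_h), out_w)
  ow_v <- rep(seq_len(out_w), each = out_h)
  h_mat <- outer(kh_v, (oh_v - 1L) * stride, `+`)
  w_mat <- outer(kw_v, (ow_v - 1L) * stride, `+`)
  idx <- matrix(c_v, ckk, p_out) + c_in * (h_mat - 1L) + c_in * hp * (w_mat - 1L)
  # re-index from padded to unpadded positions; 0 marks a padding cell,
  # which gather_cols/scatter_cols treat as constant zero
  chw <- c_in * h * w
  inv_pad <- integer(c_in * hp * wp)
  inv_pad[pad_pos] <- seq_len(chw)
  idx_vec <- inv_pad[as.integer(idx)]
  list(c_in = c_in, h = h, w = w, k = k, stride = stride, pad = pad,
       out_h = out_h, out_w = out_w,
       ckk = ckk, p_out = p_out, chw = chw, idx_vec = idx_vec)
}

gauss_init <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

# ---- layer constructors -------------------------------------------------

layer_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(w = gauss_init(n_out, n_in), b = numeric(n_out)))
}

layer_conv <- function(c_in, h, w, c_out, k = 4L, stride = 2L, pad = 1L) {
  g <- conv_geometry(c_in, h, w, k, stride, pad)
  list(type = "conv", g = g, c_out = c_out,
       params = list(w = gauss_init(c_out, g$ckk), b = numeric(c_out)))
}

# fractionally-strided (transposed) conv: (c_in, h, w) -> (c_out, h*stride, w*stride)
layer_tconv <- function(c_in, h, w, c_out, k = 4L, stride = 2L, pad = 1L) {
  g <- conv_geometry(c_out, h * stride, w * stride, k, stride, pad)
  if (g$out_h != h || g$out_w != w)
    stop_arg("transposed conv geometry mismatch")
  list(type = "tconv", g = g, c_in = c_in, c_out = c_out,
       params = list(w = gauss_init(c_in, g$ckk), b = numeric(c_out)))
}

# batch normalization over channels; spatial = spatial positions per sample
layer_bn <- function(channels, spatial, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", channels = channels, spatial = spatial,
       eps = eps, momentum = momentum,
       params = list(gamma = 1 + stats::rnorm(channels, sd = 0.02),
                     beta = numeric(channels)),
       buffers = list(run_mean = numeric(channels),
                      run_var = rep(1, channels)))
}

layer_act <- function(kind, alpha = 0.2) list(type = kind, alpha = alpha)

# ---- forward / backward -------------------------------------------------

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    dense = {
      y <- layer$params$w %*% x + layer$params$b
      list(y = y, cache = x, layer = layer)
    },
    conv = {
      g <- layer$g
      n <- ncol(x)
      cols <- gather_cols(x, g$idx_vec, g$ckk)
      y <- layer$params$w %*% cols + layer$params$b
      dim(y) <- c(layer$c_out * g$p_out, n)
      list(y = y, cache = cols, layer = layer)
    },
    tconv = {
      g <- layer$g
      n <- ncol(x)
      xm <- x
      dim(xm) <- c(layer$c_in, g$p_out * n)
      dcols <- crossprod(layer$params$w, xm)
      y <- scatter_cols(dcols, g$idx_vec, g$chw) +
        rep(layer$params$b, g$h * g$w)
      list(y = y, cache = xm, layer = layer)
    },
    bn = {
      # channel-first layout: a length-C vector recycles exactly over
      # channels, so all per-channel affine steps run without reshaping
      c_ <- layer$channels
      m <- length(x) %/% c_
      if (training) {
        mu <- .rowMeans(x, c_, m)
        va <- .rowMeans(x * x, c_, m) - mu^2
        layer$buffers$run_mean <- (1 - layer$momentum) * layer$buffers$run_mean +
          layer$momentum * mu
        layer$buffers$run_var <- (1 - layer$momentum) * layer$buffers$run_var +
          layer$momentum * va
      } else {
        mu <- layer$buffers$run_mean
        va <- layer$buffers$run_var
      }
      istd <- 1 / sqrt(va + layer$eps)
      xhat <- (x - mu) * istd
      y <- layer$params$gamma * xhat + layer$params$beta
      list(y = y, cache = list(xhat = xhat, istd = istd, training = training),
           layer = layer)
    },
    relu = {
      y <- x * (x > 0)
      list(y = y, cache = x > 0, layer = layer)
    },
    lrelu = {
      pos <- x > 0
      y <- x * (layer$alpha + (1 - layer$alpha) * pos)
      list(y = y, cache = pos, layer = layer)
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = y, layer = layer)
    },
    stop_arg("unknown layer type ", layer$type)
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    dense = {
      list(dx = crossprod(layer$params$w, dy),
           grads = list(w = tcrossprod(dy, cache), b = rowSums(dy)))
    },
    conv = {
      g <- layer$g
      n <- ncol(dy)
      dym <- dy
      dim(dym) <- c(layer$c_out, g$p_out * n)
      dw <- tcrossprod(dym, cache)
      db <- rowSums(dym)
      dcols <- crossprod(layer$params$w, dym)
      dx <- scatter_cols(dcols, g$idx_vec, g$chw)
      list(dx = dx, grads = list(w = dw, b = db))
    },
    tconv = {
      g <- layer$g
      n <- ncol(dy)
      cols <- gather_cols(dy, g$idx_vec, g$ckk)
      dx <- layer$params$w %*% cols
      dim(dx) <- c(layer$c_in * g$p_out, n)
      dw <- tcrossprod(cache, cols)
      db <- .rowSums(dy, layer$c_out, length(dy) %/% layer$c_out)
      list(dx = dx, grads = list(w = dw, b = db))
    },
    bn = {
      c_ <- layer$channels
      m <- length(dy) %/% c_
      xhat <- cache$xhat
      istd <- cache$istd
      dgamma <- .rowSums(dy * xhat, c_, m)
      dbeta <- .rowSums(dy, c_, m)
      dxhat <- dy * layer$params$gamma
      if (cache$training) {
        s1 <- .rowSums(dxhat, c_, m)
        s2 <- .rowSums(dxhat * xhat, c_, m)
        dx <- istd * (dxhat - s1 / m - xhat * (s2 / m))
      } else {
        dx <- dxhat * istd
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dy * cache, grads = NULL),
    lrelu = list(dx = dy * (layer$alpha + (1 - layer$alpha) * cache), grads = NULL),
    tanh = list(dx = dy * (1 - cache^2), grads = NULL),
    stop_arg("unknown layer type ", layer$type)
  )
}

net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    step <- layer_forward(net$layers[[i]], x, training)
    x <- step$y
    caches[[i]] <- step$cache
    net$layers[[i]] <- step$layer
  }
  list(out = x, caches = caches, net = net)
}

net_backward <- function(net, caches, dy) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    step <- layer_backward(net$layers[[i]], caches[[i]], dy)
    dy <- step$dx
    grads[i] <- list(step$grads)  # keep NULL placeholders for layers without params
  }
  list(dx = dy, grads = grads)
}

n_params <- function(net) {
  sum(vapply(net$layers, function(l) {
    if (is.null(l$params)) 0L else sum(vapply(l$params, length, integer(1)))
  }, integer(1)))
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(net) {
  list(t = 0L, m = lapply(net$layers, function(l) {
    if (is.null(l$params)) NULL else lapply(l$params, function(p) p * 0)
  }), v = lapply(net$layers, function(l) {
    if (is.null(l$params)) NULL else lapply(l$params, function(p) p * 0)
  }))
}

adam_step <- function(net, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g[[nm]]
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- state$m[[i]][[nm]] / bc1
      vhat <- state$v[[i]][[nm]] / bc2
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}
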