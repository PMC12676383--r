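# Minimal feed-forward network engine: im2col convolutions, max pooling,
# dropout, dense layers, sigmoid/softmax heads, hand-derived backprop and an
# Adam optimizer with L2 weight decay. Batches are arrays (channels, time,
# batch); dense activations are matrices (features, batch). All matrix work
# goes through BLAS.

# ---- layer constructors ----------------------------------------------------

glorot <- function(nout, nin, fan) {
  lim <- sqrt(6 / fan)
  matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
}

layer_resample <- function(t_in, t_out) {
  if (t_out > t_in)
    stop("resample target (", t_out, ") exceeds the input length (", t_in,
         "); provide epochs with at least ", t_out, " samples")
  # temporal bin-average: output bin u pools input samples t with
  # floor(t * t_out / t_in) == u (0-based); bins hold floor/ceil(t_in/t_out)
  # samples each
  g <- floor((seq_len(t_in) - 1L) * t_out / t_in) + 1L
  A <- matrix(0, t_out, t_in)
  A[cbind(g, seq_len(t_in))] <- 1
  A <- A / rowSums(A)
  list(type = "resample", A = A, t_in = t_in, t_out = t_out)
}

layer_conv_spatial <- function(c_in, n_filters) {
  list(type = "conv_spatial",
       W = glorot(n_filters, c_in, c_in + n_filters),
       b = numeric(n_filters))
}

layer_conv_temporal <- function(c_in, n_filters, k) {
  list(type = "conv_temporal", k = k, c_in = c_in,
       W = glorot(n_filters, c_in * k, c_in * k + n_filters),
       b = numeric(n_filters))
}

layer_relu <- function() list(type = "relu")
layer_maxpool2 <- function() list(type = "maxpool2")
layer_dropout <- function(p) list(type = "dropout", p = p)
layer_flatten <- function() list(type = "flatten")

layer_dense <- function(n_in, n_out) {
  list(type = "dense",
       W = glorot(n_out, n_in, n_in + n_out),
       b = numeric(n_out))
}

layer_sigmoid <- function() list(type = "sigmoid")
layer_softmax <- function() list(type = "softmax")

# ---- forward / backward ----------------------------------------------------

# im2col for temporal "same" convolution: input (C, T, N) -> (C*k, T*N)
im2col <- function(x, k) {
  d <- dim(x)
  left <- (k - 1L) %/% 2L
  pad <- array(0, c(d[1], d[2] + k - 1L, d[3]))
  pad[, left + seq_len(d[2]), ] <- x
  out <- matrix(0, d[1] * k, d[2] * d[3])
  for (o in seq_len(k))
    out[(o - 1L) * d[1] + seq_len(d[1]), ] <-
      matrix(pad[, o + seq_len(d[2]) - 1L, ], d[1], d[2] * d[3])
  out
}

col2im <- function(dcol, d, k) {
  left <- (k - 1L) %/% 2L
  dpad <- array(0, c(d[1], d[2] + k - 1L, d[3]))
  for (o in seq_len(k)) {
    blk <- array(dcol[(o - 1L) * d[1] + seq_len(d[1]), ],
                 c(d[1], d[2], d[3]))
    dpad[, o + seq_len(d[2]) - 1L, ] <-
      dpad[, o + seq_len(d[2]) - 1L, ] + blk
  }
  dpad[, left + seq_len(d[2]), , drop = FALSE]
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    resample = {
      d <- dim(x)
      xt <- matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3])
      yt <- layer$A %*% xt
      y <- aperm(array(yt, c(layer$t_out, d[1], d[3])), c(2, 1, 3))
      list(out = y, cache = d)
    },
    conv_spatial = {
      d <- dim(x)
      xm <- matrix(x, d[1], d[2] * d[3])
      y <- layer$W %*% xm + layer$b
      list(out = array(y, c(nrow(layer$W), d[2], d[3])), cache = list(xm = xm, d = d))
    },
    conv_temporal = {
      d <- dim(x)
      xc <- im2col(x, layer$k)
      y <- layer$W %*% xc + layer$b
      list(out = array(y, c(nrow(layer$W), d[2], d[3])),
           cache = list(xc = xc, d = d))
    },
    relu = {
      m <- x > 0
      list(out = x * m, cache = m)
    },
    maxpool2 = {
      d <- dim(x)
      if (d[2] %% 2L != 0L)
        stop("max pooling needs an even temporal length, got ", d[2])
      a <- x[, seq(1L, d[2], 2L), , drop = FALSE]
      b <- x[, seq(2L, d[2], 2L), , drop = FALSE]
      m <- a >= b
      list(out = pmax(a, b), cache = list(m = m, d = d))
    },
    dropout = {
      if (!training || layer$p <= 0) return(list(out = x, cache = NULL))
      m <- array(stats::runif(length(x)) >= layer$p, dim(x)) / (1 - layer$p)
      list(out = x * m, cache = m)
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1] * d[2], d[3]), cache = d)
    },
    dense = list(out = layer$W %*% x + layer$b, cache = x),
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(out = y, cache = y)
    },
    softmax = {
      e <- exp(sweep(x, 2, apply(x, 2, max)))
      y <- sweep(e, 2, colSums(e), "/")
      list(out = y, cache = y)
    },
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    resample = {
      d <- cache
      dt <- matrix(aperm(dout, c(2, 1, 3)), layer$t_out, d[1] * d[3])
      dx <- aperm(array(crossprod(layer$A, dt), c(d[2], d[1], d[3])),
                  c(2, 1, 3))
      list(dx = dx, grads = NULL)
    },
    conv_spatial = {
      dm <- matrix(dout, nrow(layer$W), length(dout) / nrow(layer$W))
      list(dx = array(crossprod(layer$W, dm), cache$d),
           grads = list(W = tcrossprod(dm, cache$xm), b = rowSums(dm)))
    },
    conv_temporal = {
      dm <- matrix(dout, nrow(layer$W), length(dout) / nrow(layer$W))
      dcol <- crossprod(layer$W, dm)
      list(dx = col2im(dcol, cache$d, layer$k),
           grads = list(W = tcrossprod(dm, cache$xc), b = rowSums(dm)))
    },
    relu = list(dx = dout * cache, grads = NULL),
    maxpool2 = {
      d <- cache$d
      dx <- array(0, d)
      dx[, seq(1L, d[2], 2L), ] <- dout * cache$m
      dx[, seq(2L, d[2], 2L), ] <- dout * !cache$m
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache, grads = NULL)
    },
    flatten = list(dx = array(dout, cache), grads = NULL),
    dense = list(dx = crossprod(layer$W, dout),
                 grads = list(W = tcrossprod(dout, cache), b = rowSums(dout))),
    sigmoid = list(dx = dout * cache * (1 - cache), grads = NULL),
    softmax = {
      s <- colSums(dout * cache)
      list(dx = cache * sweep(dout, 2, s), grads = NULL)
    },
    stop("unknown layer type ", layer$type))
}

forward_net <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- layer_forward(layers[[i]], x, training)
    x <- st$out
    caches[[i]] <- st$cache
  }
  list(out = x, caches = caches)
}

backward_net <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    st <- layer_backward(layers[[i]], dout, caches[[i]])
    dout <- st$dx
    grads[i] <- list(st$grads)
  }
  list(dx = dout, grads = grads)
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

# One Adam step with L2 regularization on weights (not biases).
adam_step <- function(layers, grads, state, t, lr, l2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    gW <- g$W + l2 * layers[[i]]$W
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * gW
    st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W -
      lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b -
      lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

# Parameter count over all layers; biases optionally excluded.
count_params <- function(layers, with_bias = TRUE) {
  sum(vapply(layers, function(l) {
    if (is.null(l$W)) return(0L)
    length(l$W) + if (with_bias) length(l$b) else 0L
  }, integer(1)))
}
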