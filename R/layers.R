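# Internal layer machinery: forward/backward passes over a list of layer
# environments.  Convolutions are stride-1, same-padding 3x3, computed by
# direct C++ kernels; pooling is 2x2/2 ceil-mode.  Batch norm precedes
# ReLU at every hidden layer.
#
# Array conventions: convolutional stages carry channel-last (H, W, N, C)
# arrays (each channel one contiguous plane), fully connected stages carry
# (N, F) matrices.  External batches arrive as (H, W, C, N) and are
# transposed once on entry.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# ---- layer constructors ----------------------------------------------------

new_conv_layer <- function(c_in, c_out, h, w, batch_norm, relu, init_sd) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  ly$c_in <- as.integer(c_in); ly$c_out <- as.integer(c_out)
  ly$h <- as.integer(h); ly$w <- as.integer(w)
  ly$W <- matrix(rtruncnorm2(9L * c_in * c_out, init_sd), 9L * c_in, c_out)
  ly$b <- rtruncnorm2(c_out, init_sd)
  ly$bn <- batch_norm
  ly$relu <- relu
  if (batch_norm) {
    ly$gamma <- rep(1, c_out); ly$beta <- rep(0, c_out)
    ly$rmean <- rep(0, c_out); ly$rvar <- rep(1, c_out)
  }
  ly$params <- if (batch_norm) c("W", "b", "gamma", "beta") else c("W", "b")
  ly
}

new_fc_layer <- function(n_in, n_out, batch_norm, relu, init_sd) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "fc"
  ly$n_in <- as.integer(n_in); ly$n_out <- as.integer(n_out)
  ly$W <- matrix(rtruncnorm2(n_in * n_out, init_sd), n_in, n_out)
  ly$b <- rtruncnorm2(n_out, init_sd)
  ly$bn <- batch_norm
  ly$relu <- relu
  if (batch_norm) {
    ly$gamma <- rep(1, n_out); ly$beta <- rep(0, n_out)
    ly$rmean <- rep(0, n_out); ly$rvar <- rep(1, n_out)
  }
  ly$params <- if (batch_norm) c("W", "b", "gamma", "beta") else c("W", "b")
  ly
}

new_pool_layer <- function(h, w, c) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "pool"
  ly$h <- as.integer(h); ly$w <- as.integer(w); ly$c <- as.integer(c)
  ly$params <- character(0)
  ly
}

new_flatten_layer <- function(h, w, c) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "flatten"
  ly$h <- as.integer(h); ly$w <- as.integer(w); ly$c <- as.integer(c)
  ly$params <- character(0)
  ly
}

# ---- batch norm (fused C++ kernels) ---------------------------------------

# a: channel-last tensor with m = length(a) / C samples per channel
bn_relu_forward <- function(a, m, C, ly, mode, want_cache) {
  if (mode == "train") {
    st <- cpp_channel_stats(a, m, C)
    mu <- st$mu
    v <- pmax(st$ex2 - mu^2, 0)
    ly$rmean <- BN_MOMENTUM * ly$rmean + (1 - BN_MOMENTUM) * mu
    ly$rvar  <- BN_MOMENTUM * ly$rvar  + (1 - BN_MOMENTUM) * v
  } else {
    mu <- ly$rmean; v <- ly$rvar
  }
  ivar <- 1 / sqrt(v + BN_EPS)
  res <- cpp_bnrelu_fwd(a, m, C, ly$gamma, ly$beta, mu, ivar,
                        ly$relu, want_cache)
  y <- res$y
  dim(y) <- dim(a)
  list(y = y,
       cache = if (want_cache) list(xhat = res$xhat, ivar = ivar,
                                    bn_mode = mode, m = m) else NULL)
}

bn_relu_backward <- function(dout, cache, ly, C) {
  res <- cpp_bnrelu_bwd(dout, cache$out, cache$xhat, cache$m, C,
                        ly$gamma, cache$ivar,
                        ly$relu, cache$bn_mode == "train")
  dx <- res$dx
  dim(dx) <- dim(dout)
  if (cache$bn_mode == "train")
    list(dx = dx, dgamma = res$dgamma, dbeta = res$dbeta)
  else
    list(dx = dx, dgamma = NULL, dbeta = NULL)
}

# spatially flipped, channel-transposed weights for the transposed
# convolution (input gradient): (9*Cout) x Cin
flip_weights <- function(Wm, Cin, Cout) {
  arr <- array(Wm, c(3, 3, Cin, Cout))
  arr <- arr[3:1, 3:1, , , drop = FALSE]
  arr <- aperm(arr, c(1, 2, 4, 3))
  dim(arr) <- c(9 * Cout, Cin)
  arr
}

# ---- forward ---------------------------------------------------------------

# Forward through one layer; x in internal layout.  Returns list(out,
# cache); cache is NULL unless want_cache.
layer_forward <- function(ly, x, mode, want_cache) {
  switch(ly$type,
    conv = {
      d <- dim(x); N <- d[3]
      a <- cpp_conv3_fwd(x, ly$h, ly$w, N, ly$c_in, ly$W, ly$b)
      dim(a) <- c(ly$h, ly$w, N, ly$c_out)
      cache <- if (want_cache) list(x_in = x, N = N) else NULL
      if (ly$bn) {
        bn <- bn_relu_forward(a, ly$h * ly$w * N, ly$c_out, ly, mode,
                              want_cache)
        a <- bn$y
        if (want_cache) cache <- c(cache, bn$cache)
      } else if (ly$relu) {
        a <- a * (a > 0)
      }
      if (want_cache) cache$out <- a
      list(out = a, cache = cache)
    },
    pool = {
      d <- dim(x); N <- d[3]
      res <- cpp_maxpool(x, ly$h, ly$w, N * ly$c)
      out <- res$out
      dim(out) <- c(res$Ho, res$Wo, N, ly$c)
      cache <- if (want_cache)
        list(argmax = res$argmax, insize = length(x), N = N) else NULL
      list(out = out, cache = cache)
    },
    flatten = {
      d <- dim(x); N <- d[3]
      # features ordered (h, w, c); samples to rows
      out <- aperm(x, c(1, 2, 4, 3))
      dim(out) <- c(ly$h * ly$w * ly$c, N)
      out <- t(out)
      list(out = out, cache = if (want_cache) list(N = N) else NULL)
    },
    fc = {
      N <- nrow(x)
      a <- x %*% ly$W + rep(ly$b, each = N)
      cache <- if (want_cache) list(x_in = x, N = N) else NULL
      if (ly$bn) {
        bn <- bn_relu_forward(a, N, ly$n_out, ly, mode, want_cache)
        a <- bn$y
        if (want_cache) cache <- c(cache, bn$cache)
      } else if (ly$relu) {
        a <- a * (a > 0)
      }
      if (want_cache) cache$out <- a
      list(out = a, cache = cache)
    },
    stop_locnet("internal", "unknown layer type '%s'", ly$type))
}

# Forward through all layers.  x: (H, W, C, N) external batch or (N, F)
# matrix.  `dropout_rate` applies inverted dropout to the input of the
# final layer (training mode only); `capture` = indices of layers whose
# post-activation outputs to keep (conv outputs in internal layout).
net_forward_layers <- function(layers, x, mode = "eval", want_cache = FALSE,
                               dropout_rate = 0, capture = integer(0)) {
  if (length(dim(x)) == 4L) x <- aperm(x, c(1, 2, 4, 3))
  caches <- if (want_cache) vector("list", length(layers)) else NULL
  acts <- list()
  nl <- length(layers)
  for (i in seq_len(nl)) {
    drop_mask <- NULL
    if (i == nl && dropout_rate > 0 && mode == "train") {
      drop_mask <- (runif(length(x)) >= dropout_rate) / (1 - dropout_rate)
      x <- x * drop_mask
    }
    fw <- layer_forward(layers[[i]], x, mode, want_cache)
    x <- fw$out
    if (want_cache) {
      caches[[i]] <- fw$cache
      if (!is.null(drop_mask)) caches[[i]]$drop_mask <- drop_mask
    }
    if (i %in% capture) acts[[as.character(i)]] <- x
  }
  list(logits = x, caches = caches, activations = acts)
}

# ---- backward --------------------------------------------------------------

# Backward through one layer; dout matches the layer's post-activation
# output shape.  Returns list(dx, grads); dx computation can be skipped
# for the first layer during training (want_dx = FALSE).
layer_backward <- function(ly, dout, cache, want_dx = TRUE) {
  switch(ly$type,
    conv = {
      N <- cache$N
      grads <- list()
      if (ly$bn) {
        bb <- bn_relu_backward(dout, cache, ly, ly$c_out)
        dout <- bb$dx
        grads$gamma <- bb$dgamma; grads$beta <- bb$dbeta
      } else if (ly$relu) {
        dout <- dout * (cache$out > 0)
      }
      dwb <- cpp_conv3_dw(cache$x_in, ly$h, ly$w, N, ly$c_in, dout,
                          ly$c_out)
      grads$W <- dwb$dW
      grads$b <- dwb$db
      dx <- NULL
      if (want_dx) {
        dx <- cpp_conv3_fwd(dout, ly$h, ly$w, N, ly$c_out,
                            flip_weights(ly$W, ly$c_in, ly$c_out),
                            numeric(ly$c_in))
        dim(dx) <- c(ly$h, ly$w, N, ly$c_in)
      }
      list(dx = dx, grads = grads)
    },
    pool = {
      dx <- cpp_maxpool_bwd(dout, cache$argmax, cache$insize)
      dim(dx) <- c(ly$h, ly$w, cache$N, ly$c)
      list(dx = dx, grads = list())
    },
    flatten = {
      dx <- t(dout)
      dim(dx) <- c(ly$h, ly$w, ly$c, cache$N)
      dx <- aperm(dx, c(1, 2, 4, 3))
      list(dx = dx, grads = list())
    },
    fc = {
      N <- cache$N
      grads <- list()
      if (ly$bn) {
        bb <- bn_relu_backward(dout, cache, ly, ly$n_out)
        dout <- bb$dx
        grads$gamma <- bb$dgamma; grads$beta <- bb$dbeta
      } else if (ly$relu) {
        dout <- dout * (cache$out > 0)
      }
      grads$b <- .colSums(dout, N, ncol(dout))
      grads$W <- crossprod(cache$x_in, dout)
      dx <- tcrossprod(dout, ly$W)
      if (!is.null(cache$drop_mask)) dx <- dx * cache$drop_mask
      list(dx = dx, grads = grads)
    },
    stop_locnet("internal", "unknown layer type '%s'", ly$type))
}

# Backward from layer `from` (default: last) down to the input.  `dtop`
# matches the post-activation output shape of layer `from` (internal
# layout for conv stages).  With need_input_grad = FALSE the input
# gradient of the first layer is skipped (training does not use it).
net_backward_layers <- function(layers, caches, dtop,
                                from = length(layers),
                                need_input_grad = TRUE) {
  grads <- vector("list", length(layers))
  dout <- dtop
  for (i in seq(from, 1L)) {
    bw <- layer_backward(layers[[i]], dout, caches[[i]],
                         want_dx = need_input_grad || i > 1L)
    grads[[i]] <- bw$grads
    dout <- bw$dx
  }
  if (length(dim(dout)) == 4L) dout <- aperm(dout, c(1, 2, 4, 3))
  list(dinput = dout, grads = grads)
}

# ---- softmax / loss --------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy and gradient wrt logits for integer labels in 1..K.
softmax_xent <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly)
    lapply(setNames(nm = ly$params), function(p) {
      list(m = 0 * ly[[p]], v = 0 * ly[[p]])
    }))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    for (p in ly$params) {
      g <- grads[[i]][[p]]
      if (is.null(g)) next
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      ly[[p]] <- ly[[p]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[p]] <- st
    }
  }
  state
}

# ---- parameter snapshots ---------------------------------------------------

net_get_params <- function(net) {
  lapply(net$layers, function(ly) {
    out <- lapply(setNames(nm = ly$params), function(p) ly[[p]])
    if (isTRUE(ly$bn)) {
      out$rmean <- ly$rmean; out$rvar <- ly$rvar
    }
    out
  })
}

net_set_params <- function(net, snap) {
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    for (p in names(snap[[i]])) ly[[p]] <- snap[[i]][[p]]
  }
  invisible(net)
}
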