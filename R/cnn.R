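# Minimal CNN engine: sequential layers with explicit forward/backward
# passes and an Adam optimizer. Matrix work is delegated to BLAS through
# im2col; spatial dims are fixed at build time so patch indices are
# precomputed once per conv layer.

# Linear indices of every kxk patch (stride 1) in a zero-padded
# [h+2p, w+2p, c] array, one row per output position, columns ordered
# (row offset, col offset, channel) to match the column-major flattening
# of a [k, k, c, f] weight array.
build_im2col_idx <- function(h, w, c, k, pad) {
  hp <- h + 2L * pad
  wp <- w + 2L * pad
  oh <- hp - k + 1L
  ow <- wp - k + 1L
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  offs <- expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L), ch = 0:(c - 1L))
  idx <- matrix(0L, oh * ow, k * k * c)
  for (col in seq_len(nrow(offs))) {
    idx[, col] <- offs$ch[col] * hp * wp + (oj + offs$dj[col] - 1L) * hp + (oi + offs$di[col])
  }
  list(idx = idx, oh = oh, ow = ow, hp = hp, wp = wp)
}

he_init <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

nn_layer_conv <- function(h, w, c_in, n_f, k = 3L, pad = 1L) {
  geom <- build_im2col_idx(h, w, c_in, k, pad)
  list(
    type = "conv", k = k, pad = pad, c_in = c_in, n_f = n_f,
    h = h, w = w, geom = geom,
    W = array(he_init(k * k * c_in, k * k * c_in * n_f), dim = c(k, k, c_in, n_f)),
    b = numeric(n_f),
    trainable = TRUE,
    out_dim = c(geom$oh, geom$ow, n_f)
  )
}

nn_layer_dense <- function(d_in, d_out, scale = NULL) {
  sd <- scale %||% sqrt(2 / d_in)
  list(type = "dense", d_in = d_in, d_out = d_out,
       W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = numeric(d_out), trainable = TRUE,
       out_dim = d_out)
}

nn_forward_layer <- function(layer, x, want_cache) {
  cache <- NULL
  out <- switch(layer$type,
    conv = {
      g <- layer$geom
      xpad <- array(0, dim = c(g$hp, g$wp, layer$c_in))
      p <- layer$pad
      xpad[(p + 1):(p + layer$h), (p + 1):(p + layer$w), ] <- x
      P <- matrix(xpad[g$idx], nrow(g$idx), ncol(g$idx))
      Wmat <- matrix(layer$W, ncol(g$idx), layer$n_f)
      Y <- P %*% Wmat
      Y <- sweep(Y, 2L, layer$b, "+")
      if (want_cache) cache <- list(P = P)
      array(Y, dim = layer$out_dim)
    },
    relu = {
      if (want_cache) cache <- list(mask = x > 0)
      x * (x > 0)
    },
    maxpool = {
      d <- dim(x)
      h2 <- d[1] %/% 2L
      w2 <- d[2] %/% 2L
      ri <- seq.int(1L, 2L * h2, 2L)
      ci <- seq.int(1L, 2L * w2, 2L)
      a <- x[ri, ci, , drop = FALSE]
      b <- x[ri + 1L, ci, , drop = FALSE]
      cc <- x[ri, ci + 1L, , drop = FALSE]
      dd <- x[ri + 1L, ci + 1L, , drop = FALSE]
      y <- pmax(a, b, cc, dd)
      if (want_cache) {
        m1 <- a == y
        m2 <- (b == y) & !m1
        m3 <- (cc == y) & !(m1 | m2)
        m4 <- (dd == y) & !(m1 | m2 | m3)
        cache <- list(in_dim = d, h2 = h2, w2 = w2, m = list(m1, m2, m3, m4))
      }
      y
    },
    gap = {
      d <- dim(x)
      if (want_cache) cache <- list(in_dim = d)
      colMeans(matrix(x, d[1] * d[2], d[3]))
    },
    flatten = {
      if (want_cache) cache <- list(in_dim = dim(x))
      as.numeric(x)
    },
    dense = {
      if (want_cache) cache <- list(x = x)
      drop(crossprod(layer$W, x)) + layer$b
    },
    l2norm = {
      n <- sqrt(sum(x^2))
      if (n == 0 && layer$eps == 0) {
        abort_bad_arg("degenerate zero-vector input to the L2-constraint layer.")
      }
      ng <- n + layer$eps
      if (want_cache) cache <- list(x = x, ng = ng)
      layer$alpha * x / ng
    },
    stop("unknown layer type ", layer$type)
  )
  list(out = out, cache = cache)
}

nn_backward_layer <- function(layer, cache, dout, need_dx) {
  switch(layer$type,
    conv = {
      g <- layer$geom
      dY <- matrix(dout, nrow(g$idx), layer$n_f)
      grads <- NULL
      if (isTRUE(layer$trainable)) {
        dW <- crossprod(cache$P, dY)
        grads <- list(W = array(dW, dim = dim(layer$W)), b = colSums(dY))
      }
      dx <- NULL
      if (need_dx) {
        Wmat <- matrix(layer$W, ncol(g$idx), layer$n_f)
        dP <- tcrossprod(dY, Wmat)
        dxpad <- numeric(g$hp * g$wp * layer$c_in)
        for (col in seq_len(ncol(g$idx))) {
          tgt <- g$idx[, col]
          dxpad[tgt] <- dxpad[tgt] + dP[, col]
        }
        dxpad <- array(dxpad, dim = c(g$hp, g$wp, layer$c_in))
        p <- layer$pad
        dx <- dxpad[(p + 1):(p + layer$h), (p + 1):(p + layer$w), , drop = FALSE]
      }
      list(dx = dx, grads = grads)
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    maxpool = {
      d <- cache$in_dim
      h2 <- cache$h2
      w2 <- cache$w2
      ri <- seq.int(1L, 2L * h2, 2L)
      ci <- seq.int(1L, 2L * w2, 2L)
      dx <- array(0, dim = d)
      dx[ri, ci, ] <- dout * cache$m[[1]]
      dx[ri + 1L, ci, ] <- dx[ri + 1L, ci, , drop = FALSE] + dout * cache$m[[2]]
      dx[ri, ci + 1L, ] <- dx[ri, ci + 1L, , drop = FALSE] + dout * cache$m[[3]]
      dx[ri + 1L, ci + 1L, ] <- dx[ri + 1L, ci + 1L, , drop = FALSE] + dout * cache$m[[4]]
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$in_dim
      per <- dout / (d[1] * d[2])
      list(dx = array(rep(per, each = d[1] * d[2]), dim = d), grads = NULL)
    },
    flatten = list(dx = array(dout, dim = cache$in_dim), grads = NULL),
    dense = {
      grads <- NULL
      if (isTRUE(layer$trainable)) {
        grads <- list(W = outer(cache$x, dout), b = dout)
      }
      dx <- if (need_dx) drop(layer$W %*% dout) else NULL
      list(dx = dx, grads = grads)
    },
    l2norm = {
      x <- cache$x
      ng <- cache$ng
      dx <- layer$alpha / ng * dout - (layer$alpha * sum(dout * x) / ng^3) * x
      list(dx = dx, grads = NULL)
    }
  )
}

# Forward pass through the whole network. Returns the logits, the feature
# descriptor (activation at model$feature_index) and, when requested, the
# per-layer caches needed for backpropagation.
nn_forward <- function(model, x, want_cache = FALSE) {
  caches <- if (want_cache) vector("list", length(model$layers)) else NULL
  feature <- NULL
  for (i in seq_along(model$layers)) {
    step <- nn_forward_layer(model$layers[[i]], x, want_cache)
    x <- step$out
    if (want_cache) caches[[i]] <- step$cache
    if (i == model$feature_index) feature <- x
  }
  list(logits = x, feature = feature, caches = caches)
}

nn_backward <- function(model, caches, dlogits) {
  n <- length(model$layers)
  grads <- vector("list", n)
  dout <- dlogits
  for (i in rev(seq_len(n))) {
    res <- nn_backward_layer(model$layers[[i]], caches[[i]], dout, need_dx = i > 1L)
    grads[i] <- list(res$grads)   # plain [[<- would drop NULL entries
    dout <- res$dx
  }
  grads
}

# Numerically stable softmax cross-entropy against a soft-label simplex
# vector; returns the loss and the gradient w.r.t. the logits.
softmax_ce <- function(logits, target) {
  zs <- logits - max(logits)
  lse <- log(sum(exp(zs)))
  p <- exp(zs - lse)
  list(loss = -sum(target * zs) + lse * sum(target), dlogits = p - target)
}

softmax_probs <- function(logits) {
  zs <- logits - max(logits)
  e <- exp(zs)
  e / sum(e)
}

nn_init_adam <- function(model) {
  lapply(model$layers, function(layer) {
    if (is.null(layer$W)) return(NULL)
    list(mW = layer$W * 0, vW = layer$W * 0,
         mb = layer$b * 0, vb = layer$b * 0)
  })
}

nn_adam_step <- function(model, state, grads, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhW <- s$mW / (1 - beta1^t)
    vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t)
    vhb <- s$vb / (1 - beta2^t)
    model$layers[[i]]$W <- model$layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

nn_snapshot_weights <- function(model) {
  lapply(model$layers, function(l) if (is.null(l$W)) NULL else list(W = l$W, b = l$b))
}

nn_restore_weights <- function(model, snapshot) {
  for (i in seq_along(snapshot)) {
    if (!is.null(snapshot[[i]])) {
      model$layers[[i]]$W <- snapshot[[i]]$W
      model$layers[[i]]$b <- snapshot[[i]]$b
    }
  }
  model
}
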