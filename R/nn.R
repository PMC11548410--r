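# Minimal neural-network engine used by the conditional GAN and the FCN
# classifier. Conventions:
#   - convolutional activations are arrays of dim (batch, length, channels)
#   - dense activations are (batch, features) matrices
# Convolutions run as im2col + BLAS matrix multiplies; every layer has an
# exact hand-derived backward pass (verified by finite differences in the
# test suite). All parameter initialization and dropout draw from R's global
# RNG so training is reproducible under set.seed().

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

nn_dense <- function(n_in, n_out) {
  list(type = "dense",
       params = list(W = glorot(n_in, n_out, c(n_in, n_out)),
                     b = matrix(0, 1, n_out)))
}

nn_conv1d <- function(c_in, c_out, kernel, stride = 1L) {
  list(type = "conv1d", kernel = as.integer(kernel),
       stride = as.integer(stride), c_in = c_in, c_out = c_out,
       params = list(W = glorot(kernel * c_in, c_out,
                                c(kernel * c_in, c_out)),
                     b = matrix(0, 1, c_out)))
}

nn_bn <- function(n_feat, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", momentum = momentum, eps = eps,
       params = list(gamma = rep(1, n_feat), beta = rep(0, n_feat)),
       state = list(rm = rep(0, n_feat), rv = rep(1, n_feat)))
}

nn_relu <- function() list(type = "relu")
nn_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nn_dropout <- function(p) list(type = "dropout", p = p)
nn_flatten <- function() list(type = "flatten")
nn_reshape <- function(len, channels) {
  list(type = "reshape", len = as.integer(len),
       channels = as.integer(channels))
}
nn_upsample2 <- function() list(type = "upsample2")
nn_maxpool2 <- function() list(type = "maxpool2")
nn_crop_pad <- function(target_len) {
  list(type = "crop_pad", target_len = as.integer(target_len))
}
nn_minibatch <- function(n_in, n_kernels = 5L, kernel_dim = 3L) {
  list(type = "minibatch", n_kernels = as.integer(n_kernels),
       kernel_dim = as.integer(kernel_dim),
       params = list(T = glorot(n_in, n_kernels * kernel_dim,
                                c(n_in, n_kernels * kernel_dim)) * 0.1))
}

# ---- conv plumbing (im2col kernels in src/conv1d.cpp) -----------------------

conv_geometry <- function(L, kernel, stride) {
  Lout <- as.integer(ceiling(L / stride))
  pad_total <- max(0L, (Lout - 1L) * stride + kernel - L)
  list(Lout = Lout, pad_left = pad_total %/% 2L,
       pad_total = as.integer(pad_total))
}

conv1d_forward <- function(layer, x) {
  d <- dim(x)
  g <- conv_geometry(d[2], layer$kernel, layer$stride)
  y <- conv1d_fwd_cpp(x, as.integer(d), layer$params$W,
                      as.numeric(layer$params$b), layer$kernel,
                      layer$stride, g$pad_left, g$Lout)
  list(out = y, cache = list(x = x, d = d, g = g))
}

conv1d_backward <- function(layer, cache, dout, compute_dx = TRUE) {
  g <- cache$g
  res <- conv1d_bwd_cpp(cache$x, as.integer(cache$d), layer$params$W,
                        dout, layer$kernel, layer$stride, g$pad_left,
                        g$Lout, compute_dx)
  list(dx = if (compute_dx) res$dx else NULL,
       grads = list(W = res$W, b = res$b))
}

# ---- batch norm -------------------------------------------------------------

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  conv_mode <- length(d) == 3L
  xm <- if (conv_mode) {
    y <- x; dim(y) <- c(d[1] * d[2], d[3]); y
  } else {
    x
  }
  n_feat <- ncol(xm)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$state$rm <- layer$momentum * layer$state$rm +
      (1 - layer$momentum) * mu
    layer$state$rv <- layer$momentum * layer$state$rv +
      (1 - layer$momentum) * v
  } else {
    mu <- layer$state$rm
    v <- layer$state$rv
  }
  ivstd <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - rep(mu, each = nrow(xm))) * rep(ivstd, each = nrow(xm))
  y <- xhat * rep(layer$params$gamma, each = nrow(xm)) +
    rep(layer$params$beta, each = nrow(xm))
  if (conv_mode) dim(y) <- d
  list(out = y, layer = layer,
       cache = list(xhat = xhat, ivstd = ivstd, d = d,
                    conv_mode = conv_mode, training = training))
}

bn_backward <- function(layer, cache, dout) {
  d <- cache$d
  dy <- dout
  if (cache$conv_mode) dim(dy) <- c(d[1] * d[2], d[3])
  N <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(layer$params$gamma, each = N)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- (dxhat - rep(s1 / N, each = N) -
             xhat * rep(s2 / N, each = N)) *
      rep(cache$ivstd, each = N)
  } else {
    dx <- dxhat * rep(cache$ivstd, each = N)
  }
  if (cache$conv_mode) dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- minibatch discrimination ----------------------------------------------

# f: (B, A); Tm: (A, n_kernels * kernel_dim) with kernel index varying
# fastest. Appends per-sample diversity features
#   o_i[b'] = sum_{j != i} exp(-||M_i[b'] - M_j[b']||_1)
minibatch_forward <- function(layer, f) {
  B <- nrow(f)
  nk <- layer$n_kernels; kd <- layer$kernel_dim
  M <- f %*% layer$params$T
  dim(M) <- c(B, nk, kd)
  E <- array(0, c(B, B, nk))
  for (b in seq_len(nk)) {
    Mb <- M[, b, , drop = TRUE]
    if (is.null(dim(Mb))) Mb <- matrix(Mb, B, kd)
    D <- matrix(0, B, B)
    for (c in seq_len(kd)) {
      D <- D + abs(outer(Mb[, c], Mb[, c], "-"))
    }
    Eb <- exp(-D)
    diag(Eb) <- 0
    E[, , b] <- Eb
  }
  o <- apply(E, c(1, 3), sum)
  if (B == 1L) o <- matrix(0, 1, nk)
  dim(o) <- c(B, nk)
  list(out = cbind(f, o), cache = list(f = f, M = M, E = E, B = B))
}

minibatch_backward <- function(layer, cache, dout) {
  B <- cache$B
  nk <- layer$n_kernels; kd <- layer$kernel_dim
  A <- ncol(cache$f)
  df_direct <- dout[, seq_len(A), drop = FALSE]
  do <- dout[, A + seq_len(nk), drop = FALSE]
  dM <- array(0, c(B, nk, kd))
  if (B > 1L) {
    for (b in seq_len(nk)) {
      G <- (matrix(do[, b], B, B) + matrix(do[, b], B, B, byrow = TRUE)) *
        cache$E[, , b]
      Mb <- cache$M[, b, , drop = TRUE]
      if (is.null(dim(Mb))) Mb <- matrix(Mb, B, kd)
      for (c in seq_len(kd)) {
        S <- sign(outer(Mb[, c], Mb[, c], "-"))
        dM[, b, c] <- -rowSums(G * S)
      }
    }
  }
  dim(dM) <- c(B, nk * kd)
  dT <- crossprod(cache$f, dM)
  df <- dM %*% t(layer$params$T) + df_direct
  list(dx = df, grads = list(T = dT))
}

#' Minibatch-discrimination features
#'
#' Measures within-batch diversity: each sample's feature row is projected by
#' a learned tensor into `n_kernels` small vectors, and the feature for
#' kernel b is `sum_{j != i} exp(-||M_i[b] - M_j[b]||_1)`. A batch of
#' near-identical samples (generator mode collapse) yields large, uniform
#' values that the discriminator learns to flag. The sum excludes `j = i`, so
#' a batch of one yields zeros.
#'
#' @param f Feature matrix, one row per sample (B x A).
#' @param proj Projection tensor, an `A x n_kernels x kernel_dim` array.
#' @return A `B x n_kernels` matrix of diversity features.
#' @examples
#' f <- matrix(rnorm(6), 2, 3)
#' proj <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
#' minibatch_features(f, proj)
#' @export
minibatch_features <- function(f, proj) {
  if (!is.matrix(f) || nrow(f) < 1L) {
    abort("f must be a matrix with at least one row.",
          class = "reachsynth_invalid_input")
  }
  dp <- dim(proj)
  if (length(dp) != 3L || dp[1] != ncol(f)) {
    abort("proj must be an A x n_kernels x kernel_dim array.",
          class = "reachsynth_invalid_input")
  }
  layer <- list(type = "minibatch", n_kernels = dp[2], kernel_dim = dp[3],
                params = list(T = matrix(proj, dp[1], dp[2] * dp[3])))
  res <- minibatch_forward(layer, f)
  res$out[, ncol(f) + seq_len(dp[2]), drop = FALSE]
}

# ---- other layers -----------------------------------------------------------

crop_pad_forward <- function(layer, x) {
  d <- dim(x); L <- d[2]; tl <- layer$target_len
  if (L == tl) return(list(out = x, cache = list(L = L)))
  if (L > tl) {
    start <- (L - tl) %/% 2L
    out <- x[, start + seq_len(tl), , drop = FALSE]
  } else {
    out <- array(0, c(d[1], tl, d[3]))
    start <- (tl - L) %/% 2L
    out[, start + seq_len(L), ] <- x
  }
  list(out = out, cache = list(L = L))
}

crop_pad_backward <- function(layer, cache, dout) {
  L <- cache$L; tl <- layer$target_len
  if (L == tl) return(list(dx = dout, grads = NULL))
  d <- dim(dout)
  if (L > tl) {
    dx <- array(0, c(d[1], L, d[3]))
    start <- (L - tl) %/% 2L
    dx[, start + seq_len(tl), ] <- dout
  } else {
    start <- (tl - L) %/% 2L
    dx <- dout[, start + seq_len(L), , drop = FALSE]
  }
  list(dx = dx, grads = NULL)
}

# ---- sequential runner ------------------------------------------------------

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    dense = {
      y <- x %*% layer$params$W + rep(layer$params$b, each = nrow(x))
      list(out = y, cache = list(x = x))
    },
    conv1d = conv1d_forward(layer, x),
    bn = bn_forward(layer, x, training),
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask))
    },
    lrelu = {
      mask <- x > 0
      scale <- layer$alpha + (1 - layer$alpha) * mask
      list(out = x * scale, cache = list(scale = scale))
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- (array(runif(length(x)), dim = dim(x)) >= layer$p) /
          (1 - layer$p)
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    flatten = {
      d <- dim(x)
      y <- x; dim(y) <- c(d[1], prod(d[-1]))
      list(out = y, cache = list(d = d))
    },
    reshape = {
      y <- x; dim(y) <- c(nrow(x), layer$len, layer$channels)
      list(out = y, cache = list(n_in = ncol(x)))
    },
    upsample2 = {
      L <- dim(x)[2]
      list(out = x[, rep(seq_len(L), each = 2), , drop = FALSE],
           cache = list(L = L))
    },
    maxpool2 = {
      L <- dim(x)[2]
      a <- x[, seq(1L, L, 2L), , drop = FALSE]
      b <- x[, seq(2L, L, 2L), , drop = FALSE]
      mask <- a >= b
      list(out = pmax(a, b), cache = list(mask = mask, L = L))
    },
    crop_pad = crop_pad_forward(layer, x),
    minibatch = minibatch_forward(layer, x),
    abort(paste0("Unknown layer type: ", layer$type))
  )
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    dense = list(
      dx = dout %*% t(layer$params$W),
      grads = list(W = crossprod(cache$x, dout),
                   b = matrix(colSums(dout), 1))
    ),
    conv1d = conv1d_backward(layer, cache, dout),
    bn = bn_backward(layer, cache, dout),
    relu = list(dx = dout * cache$mask, grads = NULL),
    lrelu = list(dx = dout * cache$scale, grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    flatten = { dx <- dout; dim(dx) <- cache$d; list(dx = dx, grads = NULL) },
    reshape = {
      dx <- dout; dim(dx) <- c(dim(dout)[1], cache$n_in)
      list(dx = dx, grads = NULL)
    },
    upsample2 = {
      L <- cache$L
      dx <- dout[, seq(1L, 2L * L, 2L), , drop = FALSE] +
        dout[, seq(2L, 2L * L, 2L), , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    maxpool2 = {
      L <- cache$L
      dx <- array(0, c(dim(dout)[1], L, dim(dout)[3]))
      dx[, seq(1L, L, 2L), ] <- dout * cache$mask
      dx[, seq(2L, L, 2L), ] <- dout * !cache$mask
      list(dx = dx, grads = NULL)
    },
    crop_pad = crop_pad_backward(layer, cache, dout),
    minibatch = minibatch_backward(layer, cache, dout),
    abort(paste0("Unknown layer type: ", layer$type))
  )
}

net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    res <- layer_forward(net$layers[[i]], x, training)
    if (!is.null(res$layer)) net$layers[[i]] <- res$layer  # bn running stats
    caches[[i]] <- res$cache
    x <- res$out
  }
  list(out = x, caches = caches, net = net)
}

net_backward <- function(net, caches, dout, need_input_grad = TRUE) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (i == 1L && !need_input_grad && l$type == "conv1d") {
      res <- conv1d_backward(l, caches[[i]], dout, compute_dx = FALSE)
    } else {
      res <- layer_backward(l, caches[[i]], dout)
    }
    grads[i] <- list(res$grads)   # keep NULLs as placeholders
    dout <- res$dx
  }
  list(dx = dout, grads = grads)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(net, lr = 3e-4, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  m <- lapply(net$layers, function(l) {
    if (is.null(l$params)) NULL else lapply(l$params, function(p) p * 0)
  })
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = m, v = m)
}

adam_step <- function(net, grads, opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(net$layers)) {
    ps <- net$layers[[i]]$params
    if (is.null(ps) || is.null(grads[[i]])) next
    for (pn in names(ps)) {
      g <- grads[[i]][[pn]]
      opt$m[[i]][[pn]] <- opt$beta1 * opt$m[[i]][[pn]] + (1 - opt$beta1) * g
      opt$v[[i]][[pn]] <- opt$beta2 * opt$v[[i]][[pn]] +
        (1 - opt$beta2) * g^2
      mhat <- opt$m[[i]][[pn]] / bc1
      vhat <- opt$v[[i]][[pn]] / bc2
      net$layers[[i]]$params[[pn]] <- ps[[pn]] -
        opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  list(net = net, opt = opt)
}

# Stable binary cross-entropy from logits; returns loss and dlogit.
bce_from_logits <- function(logits, target) {
  p <- 1 / (1 + exp(-logits))
  loss <- mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
  list(loss = loss, dlogits = (p - target) / length(logits))
}

softmax_xent <- function(logits, y_index) {
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  n <- nrow(logits)
  picked <- p[cbind(seq_len(n), y_index)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(seq_len(n), y_index)] <- dl[cbind(seq_len(n), y_index)] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}
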