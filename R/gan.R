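# Conditional GAN with FFT spectral loss and minibatch discrimination.
#
# Generator: concat(noise, label embedding) -> dense -> BN -> ReLU -> dropout
#   -> reshape to (75, C) -> two upsampling blocks (upsample x2 -> Conv1D
#   kernel 15 -> BN -> ReLU -> dropout) -> final Conv1D with 9 filters,
#   adjusted to 300 samples by centre crop/zero-pad.
# Discriminator (mirror): label embedding broadcast as extra input channels
#   -> two stride-2 Conv1D blocks (LeakyReLU 0.2, dropout) -> flatten ->
#   minibatch-discrimination features -> dense logit.
# Both trained with Adam (lr 3e-4, beta1 0.5) on binary cross-entropy; the
# generator additionally minimizes the squared difference between the
# magnitude FFT spectra of real and generated batches.

#' Generator architecture configuration
#'
#' @param noise_dim Length of the latent noise vector.
#' @param reshape_length,reshape_channels Shape the dense output is folded
#'   into before the two x2 upsampling blocks (`reshape_length * 4` should be
#'   close to `out_length`; any mismatch is fixed by centre crop/zero-pad).
#' @param block_filters Filters of the two upsampling Conv1D blocks.
#' @param kernel_size Conv1D kernel (odd).
#' @param dropout_rate Dropout after each block.
#' @param out_channels,out_length Output signal shape (9 x 300).
#' @param embed_dim Size of the learned class-label embedding concatenated to
#'   the noise vector.
#' @param n_classes Number of condition classes (30 task-by-impairment codes).
#' @return A `generator_config` list.
#' @export
generator_config <- function(noise_dim = 100L, reshape_length = 75L,
                             reshape_channels = 128L,
                             block_filters = c(256L, 128L),
                             kernel_size = 15L, dropout_rate = 0.4,
                             out_channels = 9L, out_length = 300L,
                             embed_dim = 16L, n_classes = 30L) {
  if (kernel_size %% 2L == 0L) {
    abort("kernel_size must be odd.", class = "reachsynth_config_error")
  }
  if (dropout_rate <= 0 || dropout_rate >= 1) {
    abort("dropout_rate must be in (0, 1).",
          class = "reachsynth_config_error")
  }
  if (abs(reshape_length * 4L - out_length) > kernel_size) {
    abort("reshape_length * 4 must be within one kernel of out_length.",
          class = "reachsynth_config_error")
  }
  structure(
    list(noise_dim = as.integer(noise_dim),
         reshape_length = as.integer(reshape_length),
         reshape_channels = as.integer(reshape_channels),
         block_filters = as.integer(block_filters),
         kernel_size = as.integer(kernel_size),
         dropout_rate = dropout_rate,
         out_channels = as.integer(out_channels),
         out_length = as.integer(out_length),
         embed_dim = as.integer(embed_dim),
         n_classes = as.integer(n_classes)),
    class = "generator_config"
  )
}

#' GAN training configuration
#'
#' @param learning_rate,beta1 Adam settings shared by both networks.
#' @param spectral_weight Weight of the spectral loss added to the
#'   generator's adversarial loss; 0 disables it. Raw magnitude spectra
#'   scale with signal length, so the spectral term is numerically much
#'   larger than the adversarial term; the default 0.05 balances high-band
#'   suppression against the conditioning signal (see the methods
#'   vignette).
#' @param spectral_mode `"batch_mean"` compares batch-averaged magnitude
#'   spectra; `"paired"` compares per-sample spectra pairing real and fake by
#'   batch position.
#' @param batch_size,epochs Training schedule (batches with fewer than 2
#'   samples are skipped: batch statistics need at least 2).
#' @param mismatch_weight Weight of the matching-aware discriminator term:
#'   real signals paired with shuffled (wrong) labels are scored as fake.
#'   Without it the discriminator can succeed on signal texture alone and
#'   the generator feels little pressure to respect the class label; 0
#'   disables the term.
#' @param real_label_smooth Target for real samples in the discriminator
#'   loss (one-sided label smoothing; 1 disables). Keeps the discriminator
#'   from saturating at small data scales.
#' @param d_lr_factor Discriminator learning rate as a fraction of
#'   `learning_rate`; values below 1 slow the discriminator so the
#'   generator's conditioning signal stays informative.
#' @param minibatch_kernels,minibatch_dim Minibatch-discrimination layer size.
#' @param disc_filters Filters of the two stride-2 discriminator conv blocks.
#' @param seed Integer seed controlling initialization, shuffling, noise and
#'   dropout.
#' @return A `gan_train_config` list.
#' @export
gan_train_config <- function(learning_rate = 3e-4, beta1 = 0.5,
                             spectral_weight = 0.05,
                             spectral_mode = c("batch_mean", "paired"),
                             batch_size = 32L, epochs = 500L,
                             mismatch_weight = 0.5,
                             real_label_smooth = 0.9, d_lr_factor = 0.5,
                             minibatch_kernels = 5L, minibatch_dim = 3L,
                             disc_filters = c(128L, 256L), seed = 1L) {
  if (learning_rate <= 0) {
    abort("learning_rate must be positive.",
          class = "reachsynth_config_error")
  }
  if (spectral_weight < 0) {
    abort("spectral_weight must be nonnegative.",
          class = "reachsynth_config_error")
  }
  structure(
    list(learning_rate = learning_rate, beta1 = beta1,
         spectral_weight = spectral_weight,
         spectral_mode = match.arg(spectral_mode),
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         mismatch_weight = mismatch_weight,
         real_label_smooth = real_label_smooth, d_lr_factor = d_lr_factor,
         minibatch_kernels = as.integer(minibatch_kernels),
         minibatch_dim = as.integer(minibatch_dim),
         disc_filters = as.integer(disc_filters), seed = as.integer(seed)),
    class = "gan_train_config"
  )
}

build_generator_net <- function(g) {
  rl <- g$reshape_length; rc <- g$reshape_channels
  f <- g$block_filters; k <- g$kernel_size; p <- g$dropout_rate
  list(layers = list(
    nn_dense(g$noise_dim + g$embed_dim, rl * rc),
    nn_bn(rl * rc), nn_relu(), nn_dropout(p),
    nn_reshape(rl, rc),
    nn_upsample2(), nn_conv1d(rc, f[1], k), nn_bn(f[1]), nn_relu(),
    nn_dropout(p),
    nn_upsample2(), nn_conv1d(f[1], f[2], k), nn_bn(f[2]), nn_relu(),
    nn_dropout(p),
    nn_conv1d(f[2], g$out_channels, k),
    nn_crop_pad(g$out_length)
  ))
}

build_discriminator_net <- function(g, tc) {
  d <- tc$disc_filters; k <- g$kernel_size
  c_in <- g$out_channels + g$embed_dim
  flat <- as.integer(ceiling(ceiling(g$out_length / 2) / 2)) * d[2]
  list(layers = list(
    nn_conv1d(c_in, d[1], k, stride = 2L), nn_lrelu(0.2), nn_dropout(0.4),
    nn_conv1d(d[1], d[2], k, stride = 2L), nn_lrelu(0.2), nn_dropout(0.4),
    nn_flatten(),
    nn_minibatch(flat, tc$minibatch_kernels, tc$minibatch_dim),
    nn_dense(flat + tc$minibatch_kernels, 1L)
  ))
}

# Forward pass of the generator given noise rows and integer class codes.
gen_forward_internal <- function(gen, z, labels, training) {
  x0 <- cbind(z, gen$embed[labels + 1L, , drop = FALSE])
  res <- net_forward(gen$net, x0, training)
  list(out = res$out, caches = res$caches, net = res$net, x0 = x0)
}

gen_backward_internal <- function(gen, fwd, dout, labels) {
  bk <- net_backward(gen$net, fwd$caches, dout)
  nd <- ncol(fwd$x0) - ncol(gen$embed)
  demb_rows <- bk$dx[, (nd + 1L):ncol(fwd$x0), drop = FALSE]
  dembed <- matrix(0, nrow(gen$embed), ncol(gen$embed))
  agg <- rowsum(demb_rows, group = labels)
  dembed[as.integer(rownames(agg)) + 1L, ] <- agg
  list(grads = bk$grads, dembed = dembed)
}

disc_forward_internal <- function(disc, x, labels, training) {
  d <- dim(x)
  ed <- ncol(disc$embed)
  xd <- array(0, c(d[1], d[2], d[3] + ed))
  xd[, , seq_len(d[3])] <- x
  emb <- disc$embed[labels + 1L, , drop = FALSE]
  for (j in seq_len(ed)) {
    xd[, , d[3] + j] <- matrix(emb[, j], d[1], d[2])
  }
  res <- net_forward(disc$net, xd, training)
  list(out = res$out, caches = res$caches, net = res$net, d_in = d)
}

disc_backward_internal <- function(disc, fwd, dout, labels) {
  bk <- net_backward(disc$net, fwd$caches, dout)
  d <- fwd$d_in
  ed <- ncol(disc$embed)
  dx <- bk$dx[, , seq_len(d[3]), drop = FALSE]
  demb_rows <- matrix(0, d[1], ed)
  for (j in seq_len(ed)) {
    demb_rows[, j] <- rowSums(bk$dx[, , d[3] + j, drop = TRUE])
  }
  dembed <- matrix(0, nrow(disc$embed), ed)
  agg <- rowsum(demb_rows, group = labels)
  dembed[as.integer(rownames(agg)) + 1L, ] <- agg
  list(grads = bk$grads, dembed = dembed, dx = dx)
}

# Derange labels within a batch: every sample gets a different label drawn
# from the labels present, never its own (possible whenever >1 distinct).
wrong_labels <- function(labels) {
  pool <- unique(labels)
  vapply(labels, function(l) {
    cand <- pool[pool != l]
    if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }, integer(1))
}

# ---- spectral loss ----------------------------------------------------------

# Magnitude spectra of every sample and channel: (B, L, C) -> (B, nb, C)
# with nb = floor(L/2) + 1 one-sided bins.
magnitude_spectra <- function(x) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  nb <- L %/% 2L + 1L
  out <- array(0, c(B, nb, C))
  for (c in seq_len(C)) {
    xc <- matrix(x[, , c], B, L)
    X <- stats::mvfft(t(xc))          # L x B, series in columns
    out[, , c] <- t(Mod(X[seq_len(nb), , drop = FALSE]))
  }
  out
}

as_batch_array <- function(x) {
  if (inherits(x, "trial_dataset")) return(trials_to_array(x))
  if (is.matrix(x)) return(array(x, c(1L, nrow(x), ncol(x))))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.list(x)) {
    b <- length(x)
    out <- array(0, c(b, nrow(x[[1]]), ncol(x[[1]])))
    for (i in seq_len(b)) out[i, , ] <- x[[i]]
    return(out)
  }
  abort("Expected a matrix, 3-D array, list of matrices, or trial_dataset.",
        class = "reachsynth_invalid_input")
}

#' Spectral loss between real and generated batches
#'
#' For each channel, the one-sided magnitude FFT spectrum (151 bins for
#' 300-sample trials) of every sample is computed; the spectra are averaged
#' over the batch separately for the real and the generated side, and the
#' loss is the mean squared difference between the two batch-mean spectra
#' over all channels and bins. It is zero exactly when the batch-mean
#' magnitude spectra coincide, and is blind to phase, so time-shifted copies
#' of the real data incur no penalty.
#'
#' @param real_batch,fake_batch Equal-shape `B x L x C` arrays (or lists of
#'   matrices / `trial_dataset`s).
#' @param mode `"batch_mean"` (default, the training objective) or
#'   `"paired"`, which compares spectra sample-by-sample in batch order.
#' @return Nonnegative scalar.
#' @examples
#' x <- array(rnorm(2 * 300 * 9), c(2, 300, 9))
#' spectral_loss(x, x)  # 0
#' @export
spectral_loss <- function(real_batch, fake_batch,
                          mode = c("batch_mean", "paired")) {
  mode <- match.arg(mode)
  xr <- as_batch_array(real_batch)
  xf <- as_batch_array(fake_batch)
  if (!all(dim(xr) == dim(xf))) {
    abort("Real and fake batches must have identical shape.",
          class = "reachsynth_invalid_input")
  }
  sr <- magnitude_spectra(xr)
  sf <- magnitude_spectra(xf)
  if (mode == "batch_mean") {
    mr <- apply(sr, c(2, 3), mean)
    mf <- apply(sf, c(2, 3), mean)
    mean((mf - mr)^2)
  } else {
    mean((sf - sr)^2)
  }
}

# Gradient of spectral_loss wrt the fake batch; returns the loss too.
spectral_loss_grad <- function(xr, xf, mode = "batch_mean") {
  d <- dim(xf); B <- d[1]; L <- d[2]; C <- d[3]
  nb <- L %/% 2L + 1L
  eps <- 1e-12
  sr <- magnitude_spectra(xr)
  sf <- magnitude_spectra(xf)
  dx <- array(0, d)
  if (mode == "batch_mean") {
    mr <- apply(sr, c(2, 3), mean)
    mf <- apply(sf, c(2, 3), mean)
    loss <- mean((mf - mr)^2)
    gbar <- 2 * (mf - mr) / (nb * C)          # (nb, C)
    for (c in seq_len(C)) {
      Xc <- stats::mvfft(t(matrix(xf[, , c], B, L)))  # L x B complex
      cf <- matrix(0 + 0i, L, B)
      Ak <- Mod(Xc[seq_len(nb), , drop = FALSE])
      cf[seq_len(nb), ] <- (gbar[, c] / B) * Conj(Xc[seq_len(nb), ,
                                                     drop = FALSE]) /
        pmax(Ak, eps)
      dx[, , c] <- t(Re(stats::mvfft(cf)))
    }
  } else {
    loss <- mean((sf - sr)^2)
    g <- 2 * (sf - sr) / (B * nb * C)         # (B, nb, C)
    for (c in seq_len(C)) {
      Xc <- stats::mvfft(t(matrix(xf[, , c], B, L)))
      cf <- matrix(0 + 0i, L, B)
      Ak <- Mod(Xc[seq_len(nb), , drop = FALSE])
      cf[seq_len(nb), ] <- t(matrix(g[, , c], B, nb)) *
        Conj(Xc[seq_len(nb), , drop = FALSE]) / pmax(Ak, eps)
      dx[, , c] <- t(Re(stats::mvfft(cf)))
    }
  }
  list(loss = loss, dx = dx)
}

# ---- training ---------------------------------------------------------------

#' Train the conditional GAN
#'
#' Standardizes each channel to zero mean / unit variance over the training
#' set (the mixed cm / rad scales would otherwise dominate the losses),
#' then alternates discriminator and generator Adam updates. The generator
#' loss is binary cross-entropy against the discriminator plus
#' `spectral_weight` times the [spectral_loss()] between the real and
#' generated batch. Classes absent from `dataset` are excluded from
#' conditioning with a warning. Training aborts with a diagnostic if any
#' loss becomes non-finite.
#'
#' @param dataset A `trial_dataset` with at least one trial per conditioned
#'   class.
#' @param train_config A [gan_train_config()].
#' @param gen_config A [generator_config()].
#' @return A `gan_bundle`: generator and discriminator parameters, channel
#'   standardization statistics, per-epoch loss history, and config
#'   snapshots.
#' @seealso [sample_trials()], [tidy.gan_bundle()]
#' @export
train_cgan <- function(dataset, train_config = gan_train_config(),
                       gen_config = generator_config()) {
  validate_trials(dataset)
  tc <- train_config; g <- gen_config
  present <- sort(unique(dataset$class))
  all_classes <- 0:(g$n_classes - 1L)
  missing_classes <- setdiff(all_classes, present)
  if (length(missing_classes)) {
    warn(sprintf("Classes absent from dataset and excluded from conditioning: %s",
                 paste(missing_classes, collapse = ", ")))
  }

  set.seed(tc$seed)
  x <- trials_to_array(dataset)
  n <- dim(x)[1]
  ch_mean <- apply(x, 3, mean)
  ch_sd <- pmax(apply(x, 3, sd), 1e-8)
  for (c in seq_len(dim(x)[3])) x[, , c] <- (x[, , c] - ch_mean[c]) / ch_sd[c]
  labels <- as.integer(dataset$class)

  # unit-norm-scale embeddings: the discriminator's label channels must be
  # commensurate with the (standardized) signal channels from step one, or
  # conditioning emerges too slowly at small step counts
  emb_sd <- 1 / sqrt(g$embed_dim)
  gen <- list(net = build_generator_net(g),
              embed = matrix(rnorm(g$n_classes * g$embed_dim, sd = emb_sd),
                             g$n_classes, g$embed_dim))
  disc <- list(net = build_discriminator_net(g, tc),
               embed = matrix(rnorm(g$n_classes * g$embed_dim, sd = emb_sd),
                              g$n_classes, g$embed_dim))
  opt_g <- adam_init(gen$net, tc$learning_rate, tc$beta1)
  opt_d <- adam_init(disc$net, tc$learning_rate * tc$d_lr_factor, tc$beta1)
  emb_opt <- list(
    g = list(m = gen$embed * 0, v = gen$embed * 0),
    d = list(m = disc$embed * 0, v = disc$embed * 0)
  )
  emb_update <- function(emb, grad, st, t, lr = tc$learning_rate) {
    st$m <- tc$beta1 * st$m + (1 - tc$beta1) * grad
    st$v <- 0.999 * st$v + 0.001 * grad^2
    emb <- emb - lr * (st$m / (1 - tc$beta1^t)) /
      (sqrt(st$v / (1 - 0.999^t)) + 1e-8)
    list(emb = emb, st = st)
  }

  bs <- tc$batch_size
  hist <- matrix(NA_real_, tc$epochs, 3,
                 dimnames = list(NULL, c("d_loss", "g_adv", "g_spec")))
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    ep <- c(d = 0, a = 0, s = 0); nb_done <- 0L
    for (start in seq(1L, n, by = bs)) {
      take <- ord[start:min(start + bs - 1L, n)]
      if (length(take) < 2L) next
      b <- length(take)
      xr <- x[take, , , drop = FALSE]
      lr <- labels[take]
      z <- matrix(rnorm(b * g$noise_dim), b, g$noise_dim)

      gf <- gen_forward_internal(gen, z, lr, training = TRUE)
      gen$net <- gf$net
      xf <- gf$out

      # --- discriminator update
      dr <- disc_forward_internal(disc, xr, lr, training = TRUE)
      disc$net <- dr$net
      lr_real <- bce_from_logits(dr$out, tc$real_label_smooth)
      bk_r <- disc_backward_internal(disc, dr, lr_real$dlogits, lr)
      df <- disc_forward_internal(disc, xf, lr, training = TRUE)
      disc$net <- df$net
      lr_fake <- bce_from_logits(df$out, 0)
      bk_f <- disc_backward_internal(disc, df, lr_fake$dlogits, lr)
      grads_d <- mapply(function(a, b) {
        if (is.null(a)) NULL else mapply(`+`, a, b, SIMPLIFY = FALSE)
      }, bk_r$grads, bk_f$grads, SIMPLIFY = FALSE)
      demb_d <- bk_r$dembed + bk_f$dembed
      # matching-aware term: real signals with shuffled labels are "fake",
      # forcing the discriminator to check label-signal consistency
      if (tc$mismatch_weight > 0 && length(unique(lr)) > 1L) {
        lw <- wrong_labels(lr)
        dm <- disc_forward_internal(disc, xr, lw, training = TRUE)
        disc$net <- dm$net
        lr_mis <- bce_from_logits(dm$out, 0)
        bk_m <- disc_backward_internal(
          disc, dm, tc$mismatch_weight * lr_mis$dlogits, lw)
        grads_d <- mapply(function(a, b) {
          if (is.null(a)) NULL else mapply(`+`, a, b, SIMPLIFY = FALSE)
        }, grads_d, bk_m$grads, SIMPLIFY = FALSE)
        demb_d <- demb_d + bk_m$dembed
      }
      st <- adam_step(disc$net, grads_d, opt_d)
      disc$net <- st$net; opt_d <- st$opt
      eu <- emb_update(disc$embed, demb_d, emb_opt$d, opt_d$t,
                       tc$learning_rate * tc$d_lr_factor)
      disc$embed <- eu$emb; emb_opt$d <- eu$st

      # --- generator update (through the updated discriminator)
      dg <- disc_forward_internal(disc, xf, lr, training = TRUE)
      disc$net <- dg$net
      adv <- bce_from_logits(dg$out, 1)
      bk_g <- disc_backward_internal(disc, dg, adv$dlogits, lr)
      dxf <- bk_g$dx
      sp <- list(loss = 0)
      if (tc$spectral_weight > 0) {
        sp <- spectral_loss_grad(xr, xf, tc$spectral_mode)
        dxf <- dxf + tc$spectral_weight * sp$dx
      }
      gb <- gen_backward_internal(gen, gf, dxf, lr)
      st <- adam_step(gen$net, gb$grads, opt_g)
      gen$net <- st$net; opt_g <- st$opt
      eu <- emb_update(gen$embed, gb$dembed, emb_opt$g, opt_g$t)
      gen$embed <- eu$emb; emb_opt$g <- eu$st

      d_loss <- (lr_real$loss + lr_fake$loss) / 2
      if (!is.finite(d_loss) || !is.finite(adv$loss) ||
          !is.finite(sp$loss)) {
        abort(sprintf(
          "GAN training diverged at epoch %d (d=%.3g, adv=%.3g, spec=%.3g).",
          epoch, d_loss, adv$loss, sp$loss),
          class = "reachsynth_divergence")
      }
      ep <- ep + c(d_loss, adv$loss, sp$loss)
      nb_done <- nb_done + 1L
    }
    hist[epoch, ] <- ep / max(nb_done, 1L)
  }

  structure(
    list(generator = gen, discriminator = disc,
         channel_means = ch_mean, channel_sds = ch_sd,
         history = as_tibble(cbind(epoch = seq_len(tc$epochs), hist)),
         train_config = tc, gen_config = g,
         trained_classes = present, n_train = n),
    class = "gan_bundle"
  )
}

#' Run the trained generator on explicit noise
#'
#' Deterministic inference-mode pass (batch-norm uses running statistics,
#' dropout off) mapping one noise vector and class label to a standardized
#' 300 x 9 signal.
#'
#' @param bundle A `gan_bundle` from [train_cgan()].
#' @param z Numeric noise vector of length `noise_dim`.
#' @param label Integer class code.
#' @return A 300 x 9 matrix in standardized units.
#' @export
generator_forward <- function(bundle, z, label) {
  g <- bundle$gen_config
  if (length(z) != g$noise_dim) {
    abort(sprintf("z must have %d entries.", g$noise_dim),
          class = "reachsynth_config_error")
  }
  fwd <- gen_forward_internal(bundle$generator, matrix(z, 1),
                              as.integer(label), training = FALSE)
  out <- fwd$out[1, , ]
  colnames(out) <- .CHANNEL_NAMES
  out
}

#' Sample synthetic trials from a trained bundle
#'
#' Draws noise, runs the generator in inference mode, and de-standardizes the
#' outputs back to physical units (cm / rad) with the channel statistics
#' stored in the bundle. Apply [lowpass_2hz()] afterwards to obtain the
#' filtered trials used for augmentation.
#'
#' @param bundle A `gan_bundle`.
#' @param class Integer class code(s) in 0-29; recycled against `n`.
#' @param n Number of trials to generate.
#' @param seed Integer seed for the noise draws.
#' @return A `trial_dataset` of `n` synthetic trials.
#' @export
sample_trials <- function(bundle, class, n = length(class), seed = 1) {
  g <- bundle$gen_config
  class <- rep_len(as.integer(class), n)
  bad <- setdiff(unique(class), bundle$trained_classes)
  if (length(bad)) {
    abort(paste0("Class(es) not covered by the trained bundle: ",
                 paste(bad, collapse = ", ")),
          class = "reachsynth_invalid_input")
  }
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n * g$noise_dim), n, g$noise_dim)
  fwd <- gen_forward_internal(bundle$generator, z, class, training = FALSE)
  x <- fwd$out
  for (c in seq_len(dim(x)[3])) {
    x[, , c] <- x[, , c] * bundle$channel_sds[c] + bundle$channel_means[c]
  }
  dc <- decode_class(class)
  as_trial_dataset(tibble(
    subject_id = "cgan",
    task = dc$task,
    group = dc$group,
    fmma = NA_integer_,
    provenance = "synthetic",
    signal = array_to_signals(x)
  ))
}
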