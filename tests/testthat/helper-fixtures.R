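# Shared fixtures: desk-scale model configurations and constructed datasets.

# Small GAN used in experiment-scale runs (full recipe, reduced widths).
small_gen_config <- function() {
  generator_config(noise_dim = 32L, reshape_channels = 12L,
                   block_filters = c(20L, 12L), kernel_size = 9L,
                   embed_dim = 8L)
}

small_train_config <- function(epochs = 6L, seed = 1L,
                               spectral_weight = 1) {
  gan_train_config(epochs = epochs, batch_size = 32L, seed = seed,
                   spectral_weight = spectral_weight,
                   minibatch_kernels = 5L, minibatch_dim = 3L,
                   disc_filters = c(12L, 20L))
}

# Even smaller GAN for the 2-class sinusoid recovery runs.
toy_gen_config <- function() {
  generator_config(noise_dim = 16L, reshape_channels = 8L,
                   block_filters = c(12L, 8L), kernel_size = 9L,
                   embed_dim = 4L)
}

toy_train_config <- function(epochs, seed = 1L, spectral_weight = 0.05) {
  gan_train_config(epochs = epochs, batch_size = 32L, seed = seed,
                   spectral_weight = spectral_weight,
                   learning_rate = 1e-3,
                   minibatch_kernels = 4L, minibatch_dim = 3L,
                   disc_filters = c(8L, 12L))
}

small_fcn_config <- function(epochs = 5L, seed = 1L) {
  fcn_config(conv_filters = c(16L, 32L), epochs = epochs,
             batch_size = 32L, seed = seed)
}

# Two-class toy dataset: every channel carries a sinusoid at the class
# frequency (0.5 Hz for class code 0, 1 Hz for class code 3), with amplitude
# and small phase jitter plus mild wideband noise.
toy_sine_dataset <- function(n_per_class = 32L, freqs = c(0.5, 1),
                             seed = 1L, noise_sd = 0.05) {
  set.seed(seed)
  t <- (0:299) / 60
  rows <- list()
  for (cl in seq_along(freqs)) {
    for (i in seq_len(n_per_class)) {
      amp <- rnorm(1, 1, 0.1)
      ph <- runif(1, -0.3, 0.3)
      base <- amp * sin(2 * pi * freqs[cl] * t + ph)
      sig <- matrix(rep(base, 9), 300, 9) +
        matrix(rnorm(300 * 9, sd = noise_sd), 300, 9)
      colnames(sig) <- channel_spec()$name
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sprintf("toy_%d", cl),
        task = task_ids()[cl], group = "control",
        provenance = "real", signal = list(sig)
      )
    }
  }
  as_trial_dataset(dplyr::bind_rows(rows))
}

# 0-based dominant non-DC bin of the batch-mean magnitude spectrum of the
# trials with the given class code.
dominant_bin <- function(dataset, code) {
  sig <- dataset$signal[dataset$class == code]
  spec <- rowMeans(vapply(sig, function(s) {
    Mod(stats::fft(s[, 1]))[2:151]
  }, numeric(150)))
  which.max(spec)  # bin index, 1 = 0.2 Hz
}

# Mean silhouette width of a labeled 2-D embedding (O(N^2) direct form).
mean_silhouette <- function(coords, labels) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]; same[i] <- FALSE
    if (!any(same)) { s[i] <- 0; next }
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
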