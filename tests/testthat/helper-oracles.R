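# Independent reference implementations used to cross-check the package's
# fast paths. These deliberately avoid fft(), vectorized ROM, and t.test().

# Brute-force O(n^2) DFT spectral loss (batch-mean magnitude spectra).
naive_spectral_loss <- function(xr, xf) {
  d <- dim(xr); B <- d[1]; L <- d[2]; C <- d[3]
  nb <- L %/% 2 + 1
  mag <- function(v) {
    vapply(0:(nb - 1), function(k) {
      re <- sum(v * cos(-2 * pi * k * (0:(L - 1)) / L))
      im <- sum(v * sin(-2 * pi * k * (0:(L - 1)) / L))
      sqrt(re^2 + im^2)
    }, numeric(1))
  }
  tot <- 0
  for (c in seq_len(C)) {
    sr <- rowMeans(vapply(seq_len(B), function(i) mag(xr[i, , c]),
                          numeric(nb)))
    sf <- rowMeans(vapply(seq_len(B), function(i) mag(xf[i, , c]),
                          numeric(nb)))
    tot <- tot + sum((sf - sr)^2)
  }
  tot / (nb * C)
}

# Triple-loop minibatch-discrimination reference.
naive_minibatch_features <- function(f, proj) {
  B <- nrow(f); nk <- dim(proj)[2]
  ref <- matrix(0, B, nk)
  for (i in seq_len(B)) {
    for (b in seq_len(nk)) {
      Mi <- as.numeric(f[i, ] %*% proj[, b, ])
      for (j in seq_len(B)) {
        if (j == i) next
        Mj <- as.numeric(f[j, ] %*% proj[, b, ])
        ref[i, b] <- ref[i, b] + exp(-sum(abs(Mi - Mj)))
      }
    }
  }
  ref
}

# Explicit per-column scan for range of motion.
naive_rom <- function(m) {
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    mx <- m[1, j]; mn <- m[1, j]
    for (i in seq_len(nrow(m))[-1]) {
      if (m[i, j] > mx) mx <- m[i, j]
      if (m[i, j] < mn) mn <- m[i, j]
    }
    out[j] <- mx - mn
  }
  out
}

# Closed-form Welch statistic with Welch-Satterthwaite df.
naive_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}
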