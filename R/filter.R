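# Zero-phase Butterworth lowpass filtering.
#
# Coefficients come from signal::butter; the forward-backward pass is applied
# with odd-reflection edge padding so that short (300-sample) windows are not
# distorted at their ends.

butter_lowpass <- function(cutoff_hz, fs, order = 4) {
  if (fs <= 2 * cutoff_hz) {
    abort("Sampling rate must exceed twice the cutoff.",
          class = "reachsynth_invalid_input")
  }
  signal::butter(order, cutoff_hz / (fs / 2), type = "low")
}

# One directional IIR pass initialized at steady state for the first sample
# (suppresses the start-up transient, as scipy-style filtfilt does).
iir_steady <- function(bf, x) {
  nb <- length(bf$b); na <- length(bf$a)
  h0 <- sum(bf$b) / sum(bf$a)
  as.numeric(signal::filter(bf$b, bf$a, x,
                            init.x = rep(x[1], nb - 1L),
                            init.y = rep(x[1] * h0, na - 1L)))
}

# Zero-phase filter of one vector: odd-reflect ~3 filter lengths at each end,
# filter forward and backward with steady-state initialization, trim.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  flen <- max(length(bf$b), length(bf$a)) - 1L
  if (n <= 3L * flen) {
    abort(sprintf("Signal of length %d is shorter than the %d-sample filter pad.",
                  n, 3L * flen),
          class = "reachsynth_invalid_input")
  }
  # 12 filter lengths where possible: long enough for the reflection kink's
  # transient to die out before it reaches the retained window
  p <- min(n - 1L, 12L * flen)
  left <- 2 * x[1] - x[(p + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - p)]
  xe <- c(left, x, right)
  y <- iir_steady(bf, xe)
  y <- rev(iir_steady(bf, rev(y)))
  y[(p + 1L):(p + n)]
}

#' Zero-phase 2 Hz lowpass filter
#'
#' Applies a 4th-order Butterworth lowpass forward and backward (zero phase,
#' squared magnitude response) to every channel. Generated trials carry
#' excess energy above 2 Hz, which this post-filter removes; reaching
#' movements themselves live almost entirely below 2 Hz.
#'
#' @param x A 300 x 9 matrix, a B x 300 x 9 array, or a `trial_dataset`
#'   (filtered signal list-column returned).
#' @param cutoff_hz Cutoff frequency in Hz (default 2).
#' @param fs Sampling rate in Hz (default 60).
#' @param order Butterworth order for a single pass (default 4).
#' @return Same shape as the input.
#' @examples
#' t <- seq(0, 5, length.out = 300)
#' x <- matrix(sin(2 * pi * 0.5 * t), 300, 9)
#' y <- lowpass_2hz(x)        # passband: essentially unchanged
#' @export
lowpass_2hz <- function(x, cutoff_hz = 2, fs = .SAMPLE_RATE, order = 4) {
  bf <- butter_lowpass(cutoff_hz, fs, order)
  if (inherits(x, "trial_dataset")) {
    x$signal <- lapply(x$signal, function(s) {
      out <- apply(s, 2, function(col) filtfilt_padded(bf, col))
      colnames(out) <- colnames(s)
      out
    })
    return(x)
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) filtfilt_padded(bf, col))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    out <- x
    for (i in seq_len(dim(x)[1])) {
      for (c in seq_len(dim(x)[3])) {
        out[i, , c] <- filtfilt_padded(bf, x[i, , c])
      }
    }
    return(out)
  }
  abort("x must be a matrix, 3-D array, or trial_dataset.",
        class = "reachsynth_invalid_input")
}
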