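# Quantitative realism statistics: range of motion, Welch t-test grids,
# and spectral band power.

#' Range of motion per channel
#'
#' ROM is max minus min of each channel over the 5 s window — the kinematic
#' feature used to compare real and synthetic trials quantitatively (and a
#' standard summary of stroke-related motor impairment).
#'
#' @param x A 300 x 9 matrix or a `trial_dataset`.
#' @return For a matrix, a named length-9 vector. For a dataset, a long
#'   tibble with one row per trial x channel: `trial`, `subject_id`, `task`,
#'   `group`, `provenance`, `channel`, `rom`.
#' @examples
#' rom <- range_of_motion(simulate_dataset(1, seed = 1))
#' head(rom)
#' @export
range_of_motion <- function(x) {
  if (is.matrix(x)) {
    rom <- apply(x, 2, max) - apply(x, 2, min)
    names(rom) <- if (!is.null(colnames(x))) colnames(x) else .CHANNEL_NAMES
    return(rom)
  }
  if (!inherits(x, "trial_dataset")) {
    abort("x must be a matrix or trial_dataset.",
          class = "reachsynth_invalid_input")
  }
  roms <- t(vapply(x$signal, function(s) {
    apply(s, 2, max) - apply(s, 2, min)
  }, numeric(9)))
  colnames(roms) <- .CHANNEL_NAMES
  out <- as_tibble(roms)
  out$trial <- seq_len(nrow(x))
  out$subject_id <- x$subject_id
  out$task <- x$task
  out$group <- x$group
  out$provenance <- x$provenance
  tidyr::pivot_longer(out, cols = dplyr::all_of(.CHANNEL_NAMES),
                      names_to = "channel", values_to = "rom")
}

#' Two-sided t-test on two ROM samples
#'
#' Welch's unequal-variance t-test by default (real and synthetic ROM spreads
#' are not expected to match). Degenerate inputs with zero variance on both
#' sides give p = 1 when the means agree; fewer than 2 observations on
#' either side returns `NA` with a warning.
#'
#' @param real_roms,synth_roms Numeric vectors of per-trial ROM values.
#' @param var_equal Use the pooled-variance Student test instead.
#' @return Two-sided p-value.
#' @export
rom_ttest <- function(real_roms, synth_roms, var_equal = FALSE) {
  x <- real_roms[is.finite(real_roms)]
  y <- synth_roms[is.finite(synth_roms)]
  if (length(x) < 2L || length(y) < 2L) {
    warn("Fewer than 2 observations on one side; returning NA.")
    return(NA_real_)
  }
  if (var(x) < 1e-300 && var(y) < 1e-300) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Range-of-motion comparison grid
#'
#' One Welch t-test per (task, channel, impairment group) cell comparing the
#' per-trial ROM distribution of real versus synthetic trials — the full
#' 10 x 9 x 3 grid of raw (uncorrected) p-values. Cells with fewer than 2
#' trials on either side are flagged `insufficient` and carry `NA`.
#'
#' @param real,synth `trial_dataset`s (provenance is not checked; the two
#'   arguments define the comparison).
#' @param var_equal Passed to [rom_ttest()].
#' @return A `rom_table` tibble with columns `task`, `channel`, `group`,
#'   `n_real`, `n_synth`, `p_value`, `insufficient` (270 rows).
#' @export
rom_table <- function(real, synth, var_equal = FALSE) {
  rr <- range_of_motion(real)
  rs <- range_of_motion(synth)
  grid <- tidyr::expand_grid(
    task = .TASK_IDS, channel = .CHANNEL_NAMES, group = .GROUPS
  )
  res <- purrr::pmap(grid, function(task, channel, group) {
    x <- rr$rom[rr$task == task & rr$channel == channel & rr$group == group]
    y <- rs$rom[rs$task == task & rs$channel == channel & rs$group == group]
    insufficient <- length(x) < 2L || length(y) < 2L
    p <- if (insufficient) {
      NA_real_
    } else {
      suppressWarnings(rom_ttest(x, y, var_equal))
    }
    tibble(n_real = length(x), n_synth = length(y), p_value = p,
           insufficient = insufficient)
  })
  out <- dplyr::bind_cols(grid, bind_rows(res))
  out$channel <- factor(out$channel, levels = .CHANNEL_NAMES)
  out$group <- factor(out$group, levels = .GROUPS)
  class(out) <- c("rom_table", class(out))
  out
}

#' Fraction of signal power above a cutoff frequency
#'
#' Per sample and channel, the Parseval-consistent one-sided periodogram is
#' split at `cutoff_hz` (strictly above counts as high band) and the
#' high-band share of total non-DC power is averaged over all samples and
#' channels with nonzero power. Generated trials before 2 Hz filtering show
#' elevated values; real reaching movements sit near zero.
#'
#' @param x Matrix, `B x L x C` array, or `trial_dataset`.
#' @param cutoff_hz Band split in Hz.
#' @param fs Sampling rate in Hz.
#' @return Scalar in `[0, 1]`.
#' @examples
#' t <- seq(0, 5 - 1/60, by = 1/60)
#' highband_power_ratio(cbind(sin(2 * pi * 5 * t)))  # ~1: all power at 5 Hz
#' @export
highband_power_ratio <- function(x, cutoff_hz = 2, fs = .SAMPLE_RATE) {
  xa <- as_batch_array(x)
  d <- dim(xa); L <- d[2]
  nb <- L %/% 2L + 1L
  freqs <- (seq_len(nb) - 1L) * fs / L
  w <- rep(2, nb); w[1] <- 1
  if (L %% 2L == 0L) w[nb] <- 1
  sp <- magnitude_spectra(xa)^2            # (B, nb, C)
  hi_bins <- freqs > cutoff_hz
  ratios <- c()
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[3])) {
      p <- sp[i, , c] * w
      tot <- sum(p[-1])                    # exclude DC
      if (tot > 0) ratios <- c(ratios, sum(p[hi_bins]) / tot)
    }
  }
  if (!length(ratios)) return(0)
  mean(ratios)
}
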