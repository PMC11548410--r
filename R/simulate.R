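# Parametric simulator of reach-and-return kinematic trials with
# impairment-dependent structure: stroke groups show larger trunk (T8)
# excursions (compensation) and smaller shoulder/elbow ranges, scaled by
# group-level gains.

# Peak excursions per task (rows, task_ids() order) and channel (columns,
# channel_spec() order); cm for T8 position, rad for angles. Values are
# chosen so the 10 tasks are distinct (linearly separable) in range-of-motion
# space at control level.
.TASK_TEMPLATES <- matrix(c(
  # T8x  T8y  T8z  T8rz  Sx    Sy    Sz    Ex    Ey
   2.0,  1.0, 0.5, 0.05, 0.60, 0.20, 0.10, 0.80, 0.90,  # T02 thumb down
   3.5,  1.5, 2.5, 0.08, 1.50, 0.40, 0.30, 1.20, 0.20,  # T03 overhead
   2.5,  3.0, 0.8, 0.20, 0.50, 1.20, 0.25, 0.60, 0.30,  # T04 lateral
   2.0,  1.2, 0.6, 0.06, 0.55, 0.25, 0.15, 0.85, 1.10,  # T06 palm up
   1.5,  0.8, 1.2, 0.04, 1.00, 0.30, 0.50, 0.40, 0.15,  # T08 stop gesture
   1.8,  0.9, 1.0, 0.10, 0.70, 0.15, 0.35, 1.40, 0.60,  # T10 hand to mouth
   2.8,  1.1, 1.4, 0.12, 0.90, 0.35, 0.40, 1.30, 0.75,  # T16 bite apple
   3.0,  2.0, 0.7, 0.15, 0.65, 0.60, 0.20, 0.70, 0.40,  # T18 move cup
   4.0,  2.5, 1.0, 0.25, 0.75, 0.80, 0.45, 0.55, 0.25,  # T19 move tray
   2.2,  1.8, 0.9, 0.09, 0.45, 0.50, 0.60, 0.95, 0.50   # T28 tennis ball
), nrow = 10, byrow = TRUE, dimnames = list(.TASK_IDS, .CHANNEL_NAMES))

#' Simulator parameters
#'
#' Defaults encode the qualitative structure of post-stroke reaching: trunk
#' gains increase and arm gains decrease with impairment, movements last
#' about 3 s inside the 5 s window, and each trial carries smooth (4 Hz
#' lowpassed) measurement noise plus trial-to-trial amplitude variability.
#'
#' @param task_templates 10 x 9 matrix of peak excursions (cm / rad).
#' @param trunk_gain Named multipliers (>= 1 ordering) on the four T8
#'   channels per group; must be nondecreasing control -> mild -> modsev.
#' @param arm_gain Named multipliers on the five shoulder/elbow channels;
#'   must be nonincreasing control -> mild -> modsev.
#' @param duration_mean_s,duration_sd_s Mean and jitter SD of movement
#'   duration in seconds (truncated to fit the 5 s window).
#' @param noise_sd Length-9 vector of smooth-noise SDs per channel (cm / rad).
#' @param noise_cutoff_hz Lowpass cutoff shaping the noise; 4 Hz by default
#'   so raw simulated trials retain some energy above the 2 Hz band that the
#'   GAN post-filter targets.
#' @param amp_sd Trial-level multiplicative amplitude jitter SD.
#' @return A `sim_params` list, validated against the gain-ordering
#'   invariants.
#' @export
sim_params <- function(task_templates = .TASK_TEMPLATES,
                       trunk_gain = c(control = 1.0, mild = 1.5, modsev = 2.2),
                       arm_gain = c(control = 1.0, mild = 0.8, modsev = 0.55),
                       duration_mean_s = 3.0,
                       duration_sd_s = 0.4,
                       noise_sd = c(rep(0.25, 3), 0.01, rep(0.03, 5)),
                       noise_cutoff_hz = 4,
                       amp_sd = 0.10) {
  stopifnot(
    is.matrix(task_templates), all(dim(task_templates) == c(10, 9)),
    length(noise_sd) == 9, all(noise_sd >= 0)
  )
  if (any(trunk_gain <= 0) || any(arm_gain <= 0)) {
    abort("Gains must be positive.", class = "reachsynth_invalid_input")
  }
  if (is.unsorted(trunk_gain[.GROUPS]) ||
      is.unsorted(rev(arm_gain[.GROUPS]))) {
    abort("trunk_gain must be nondecreasing and arm_gain nonincreasing with impairment.",
          class = "reachsynth_invalid_input")
  }
  structure(
    list(task_templates = task_templates, trunk_gain = trunk_gain,
         arm_gain = arm_gain, duration_mean_s = duration_mean_s,
         duration_sd_s = duration_sd_s, noise_sd = noise_sd,
         noise_cutoff_hz = noise_cutoff_hz, amp_sd = amp_sd),
    class = "sim_params"
  )
}

#' Minimum-jerk position profile
#'
#' The classic smooth point-to-point reach profile
#' `10 t^3 - 15 t^4 + 6 t^5`, monotone from 0 to 1 on the unit interval.
#'
#' @param t Numeric value(s) in `[0, 1]`.
#' @return Profile value(s) in `[0, 1]`.
#' @examples
#' minimum_jerk_profile(c(0, 0.5, 1))
#' @export
minimum_jerk_profile <- function(t) {
  if (any(t < 0 | t > 1)) {
    abort("t must lie in [0, 1].", class = "reachsynth_invalid_input")
  }
  10 * t^3 - 15 * t^4 + 6 * t^5
}

# Reach-and-return envelope over the 300-sample window: minimum-jerk out for
# the first half of the movement, minimum-jerk back for the second, zero after.
reach_return_envelope <- function(duration_s, n = .TRIAL_LEN,
                                  fs = .SAMPLE_RATE) {
  time <- (seq_len(n) - 1) / fs
  half <- duration_s / 2
  out <- numeric(n)
  up <- time <= half
  down <- time > half & time <= duration_s
  out[up] <- minimum_jerk_profile(time[up] / half)
  out[down] <- minimum_jerk_profile((duration_s - time[down]) / half)
  out
}

#' Simulate one reach-and-return trial
#'
#' Builds `envelope x (template * group gains * amplitude jitter)` plus
#' smooth lowpassed Gaussian noise. Movement onset is at the start of the
#' 5 s window and the limb returns to baseline before it ends.
#'
#' @param task_index Integer 0-9.
#' @param group `"control"`, `"mild"`, or `"modsev"`.
#' @param params A [sim_params()] object.
#' @param subject_id Metadata string.
#' @param seed Optional integer seed for this trial.
#' @return A one-row `trial_dataset` tibble.
#' @export
simulate_trial <- function(task_index, group, params = sim_params(),
                           subject_id = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (task_index < 0 || task_index > 9 || !group %in% .GROUPS) {
    abort("Invalid task_index or group.", class = "reachsynth_invalid_input")
  }
  template <- params$task_templates[task_index + 1L, ]
  gains <- numeric(9)
  gains[.TRUNK_CHANNELS] <- params$trunk_gain[[group]]
  gains[.ARM_CHANNELS] <- params$arm_gain[[group]]

  dur <- rnorm(1, params$duration_mean_s, params$duration_sd_s)
  dur <- min(max(dur, 1.0), 4.8)
  env <- reach_return_envelope(dur)

  amp <- max(rnorm(1, 1, params$amp_sd), 0.4) *
    pmax(rnorm(9, 1, params$amp_sd / 2), 0.4)
  sig <- env %o% (template * gains * amp)

  bf <- butter_lowpass(params$noise_cutoff_hz, .SAMPLE_RATE)
  noise <- matrix(rnorm(.TRIAL_LEN * 9), .TRIAL_LEN, 9)
  noise <- apply(noise, 2, function(col) {
    f <- filtfilt_padded(bf, col)
    f / max(sd(f), 1e-12)
  })
  sig <- sig + noise %*% diag(params$noise_sd)
  colnames(sig) <- .CHANNEL_NAMES

  as_trial_dataset(tibble(
    subject_id = subject_id,
    task = .TASK_IDS[task_index + 1L],
    group = group,
    fmma = NA_integer_,
    provenance = "synthetic",
    signal = list(sig)
  ))
}

#' Simulate a balanced labeled dataset
#'
#' Generates `n_per_class` trials for each of the 30 task-by-impairment
#' classes. Each trial draws from its own RNG substream derived from `seed`
#' and a trial counter, so the dataset is reproducible and insensitive to
#' generation order.
#'
#' @param n_per_class Trials per class (>= 1).
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param provenance Provenance tag to record; simulator output stands in for
#'   real recordings in the no-download pipeline, so `"real"` is the default.
#' @return A `trial_dataset` of `30 * n_per_class` trials.
#' @examples
#' ds <- simulate_dataset(1, seed = 7)
#' nrow(ds)  # 30
#' @export
simulate_dataset <- function(n_per_class, params = sim_params(), seed = 1,
                             provenance = "real") {
  if (n_per_class < 1) {
    abort("n_per_class must be >= 1.", class = "reachsynth_invalid_input")
  }
  base <- as.integer(seed)
  rows <- vector("list", 30L * n_per_class)
  counter <- 0L
  for (ti in 0:9) {
    for (gi in 0:2) {
      for (rep in seq_len(n_per_class)) {
        counter <- counter + 1L
        trial_seed <- (abs(base) %% 100000L * 7919 + counter * 104729) %%
          2147483647
        grp <- .GROUPS[gi + 1L]
        tr <- simulate_trial(
          ti, grp, params,
          subject_id = sprintf("sim_%s_%02d", grp, (rep - 1L) %% 5L + 1L),
          seed = trial_seed
        )
        rows[[counter]] <- as_tibble(tr)
      }
    }
  }
  out <- as_trial_dataset(bind_rows(rows))
  out$provenance <- provenance
  out
}
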