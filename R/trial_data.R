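# Preprocessing and labeling of kinematic trials.

#' Crop or pad a trial to a fixed length
#'
#' Trials vary in duration; the models require a fixed 300-sample (5 s at
#' 60 Hz) window. Longer recordings are cropped to their first `target_len`
#' samples (movement onset is at trial start); shorter recordings are extended
#' by repeating the final sample.
#'
#' @param signal Numeric matrix, one row per time sample, one column per
#'   channel.
#' @param target_len Target number of rows (default 300).
#' @return A matrix with exactly `target_len` rows and the input's columns.
#' @examples
#' x <- matrix(rnorm(250 * 9), 250, 9)
#' dim(pad_or_crop(x))  # 300 x 9
#' @export
pad_or_crop <- function(signal, target_len = .TRIAL_LEN) {
  if (!is.matrix(signal) || nrow(signal) < 1L) {
    abort("`signal` must be a matrix with at least one row.",
          class = "reachsynth_invalid_input")
  }
  target_len <- as.integer(target_len)
  n <- nrow(signal)
  if (n >= target_len) {
    signal[seq_len(target_len), , drop = FALSE]
  } else {
    pad <- signal[rep(n, target_len - n), , drop = FALSE]
    rbind(signal, pad)
  }
}

#' Convert raw channel units to canonical units
#'
#' Canonical units are centimeters for the three T8 position channels and
#' radians for all six angle channels (including T8 axial rotation). Motion
#' capture exports typically arrive in meters and degrees.
#'
#' @param signal Numeric matrix with 9 columns in [channel_spec()] order.
#' @param position_unit Unit of the incoming position channels: `"m"`, `"mm"`,
#'   or `"cm"`.
#' @param angle_unit Unit of the incoming angle channels: `"deg"` or `"rad"`.
#' @return The matrix rescaled to cm / rad.
#' @examples
#' x <- matrix(1, 2, 9)
#' normalize_units(x, "m", "deg")[1, c(1, 5)]  # 100 cm, pi/180 rad
#' @export
normalize_units <- function(signal, position_unit = "m", angle_unit = "deg") {
  if (!is.matrix(signal) || ncol(signal) != 9L) {
    abort("`signal` must be a matrix with 9 columns.",
          class = "reachsynth_invalid_input")
  }
  pos_scale <- switch(position_unit,
    m = 100, mm = 0.1, cm = 1,
    abort(paste0("Unknown position unit: ", position_unit),
          class = "reachsynth_config_error")
  )
  ang_scale <- switch(angle_unit,
    deg = pi / 180, rad = 1,
    abort(paste0("Unknown angle unit: ", angle_unit),
          class = "reachsynth_config_error")
  )
  signal[, .POSITION_CHANNELS] <- signal[, .POSITION_CHANNELS] * pos_scale
  signal[, .ANGLE_CHANNELS] <- signal[, .ANGLE_CHANNELS] * ang_scale
  signal
}

#' Assign the impairment group used for class conditioning
#'
#' Stroke trials are split into two groups at a Fugl-Meyer upper-extremity
#' (FMMA-UE, 0-66) threshold of 42: scores strictly above 42 are `"mild"`,
#' scores of 42 or below are `"modsev"` (moderate + severe pooled). Controls
#' form the third group regardless of score.
#'
#' @param fm_score Integer FMMA-UE score(s) in 0-66, or `NA` for controls.
#' @param is_control Logical, same length (or length 1): is the trial from a
#'   healthy control?
#' @return Character vector of group labels among [impairment_groups()].
#' @examples
#' assign_impairment_group(c(NA, 55, 42, 21), c(TRUE, FALSE, FALSE, FALSE))
#' @export
assign_impairment_group <- function(fm_score, is_control) {
  n <- max(length(fm_score), length(is_control))
  fm_score <- rep_len(fm_score, n)
  is_control <- rep_len(is_control, n)
  stroke <- !is_control
  if (any(stroke & is.na(fm_score))) {
    abort("Stroke trials require an FMMA-UE score.",
          class = "reachsynth_invalid_metadata")
  }
  sc <- fm_score[stroke]
  if (any(sc < 0 | sc > 66)) {
    abort("FMMA-UE scores must lie in [0, 66].",
          class = "reachsynth_invalid_metadata")
  }
  out <- character(n)
  out[is_control] <- "control"
  out[stroke] <- ifelse(fm_score[stroke] > 42, "mild", "modsev")
  out
}

#' Clinical severity band of an FMMA-UE score
#'
#' Three-way banding of the 0-66 Fugl-Meyer upper-extremity score: below 25 is
#' `"severe"`, 25 through 53 is `"moderate"`, above 53 is `"mild"`. This is
#' the clinical stratification; the coarser two-way split used for class
#' conditioning is [assign_impairment_group()].
#'
#' @param fm_score Integer score(s) in 0-66.
#' @return Character vector among `"severe"`, `"moderate"`, `"mild"`.
#' @examples
#' severity_band(c(21, 42, 54))
#' @export
severity_band <- function(fm_score) {
  if (any(is.na(fm_score)) || any(fm_score < 0 | fm_score > 66)) {
    abort("FMMA-UE scores must lie in [0, 66].",
          class = "reachsynth_invalid_metadata")
  }
  ifelse(fm_score < 25, "severe", ifelse(fm_score <= 53, "moderate", "mild"))
}

#' Encode and decode the 30-way task-by-impairment class label
#'
#' The conditional GAN and the 30-class classifier operate on a composite
#' label: `code = task_index * 3 + group_index`, a bijection between the
#' 10 tasks x 3 groups grid and the integers 0..29.
#'
#' @param task_index Integer(s) in 0-9, position in [task_ids()].
#' @param group_index Integer(s) in 0-2, position in [impairment_groups()].
#' @return `encode_class()`: integer code(s) in 0-29. `decode_class()`: a
#'   tibble with columns `code`, `task_index`, `group_index`, `task`, `group`.
#' @examples
#' encode_class(9, 2)          # 29
#' decode_class(encode_class(4, 1))
#' @export
encode_class <- function(task_index, group_index) {
  n <- max(length(task_index), length(group_index))
  task_index <- rep_len(as.integer(task_index), n)
  group_index <- rep_len(as.integer(group_index), n)
  if (any(task_index < 0 | task_index > 9) ||
      any(group_index < 0 | group_index > 2)) {
    abort("task_index must be in 0-9 and group_index in 0-2.",
          class = "reachsynth_invalid_input")
  }
  task_index * 3L + group_index
}

#' @param code Integer class code(s) in 0-29.
#' @rdname encode_class
#' @export
decode_class <- function(code) {
  code <- as.integer(code)
  if (any(code < 0 | code > 29)) {
    abort("Class codes must lie in 0-29.",
          class = "reachsynth_invalid_input")
  }
  ti <- code %/% 3L
  gi <- code %% 3L
  tibble(
    code = code,
    task_index = ti,
    group_index = gi,
    task = .TASK_IDS[ti + 1L],
    group = .GROUPS[gi + 1L]
  )
}

# ---- trial datasets ---------------------------------------------------------

#' Construct a trial dataset
#'
#' A trial dataset is a tibble with one row per trial and a `signal`
#' list-column of 300 x 9 numeric matrices in canonical units, plus metadata
#' columns `subject_id`, `task`, `group`, `provenance`, and the derived
#' integer `class` code. All downstream functions (GAN training, realism
#' statistics, the classifier, the augmentation experiment) consume this
#' shape.
#'
#' @param df A data frame with columns `subject_id`, `task`, `group`,
#'   `provenance`, and a `signal` list-column; `class` is recomputed.
#' @return A validated `trial_dataset` tibble.
#' @seealso [simulate_dataset()], [read_trials()], [validate_trials()]
#' @export
as_trial_dataset <- function(df) {
  needed <- c("subject_id", "task", "group", "provenance", "signal")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "reachsynth_invalid_input")
  }
  out <- as_tibble(df)
  out$class <- encode_class(
    match(out$task, .TASK_IDS) - 1L,
    match(out$group, .GROUPS) - 1L
  )
  class(out) <- c("trial_dataset", class(out))
  validate_trials(out)
}

#' Validate trial dataset invariants
#'
#' Checks that every signal is a finite 300 x 9 matrix, that task, group and
#' provenance labels are legal, and that class codes agree with task/group.
#'
#' @param dataset A `trial_dataset`.
#' @return The dataset, invisibly unchanged, or an error.
#' @export
validate_trials <- function(dataset) {
  ok_dims <- vapply(
    dataset$signal,
    function(s) is.matrix(s) && all(dim(s) == c(.TRIAL_LEN, 9L)) &&
      all(is.finite(s)),
    logical(1)
  )
  if (!all(ok_dims)) {
    abort(sprintf("%d trial(s) violate the 300x9 finite-signal invariant.",
                  sum(!ok_dims)),
          class = "reachsynth_invalid_input")
  }
  if (!all(dataset$task %in% .TASK_IDS)) {
    abort("Unknown task ID.", class = "reachsynth_invalid_input")
  }
  if (!all(dataset$group %in% .GROUPS)) {
    abort("Unknown impairment group.", class = "reachsynth_invalid_input")
  }
  if (!all(dataset$provenance %in% c("real", "synthetic"))) {
    abort("Provenance must be 'real' or 'synthetic'.",
          class = "reachsynth_invalid_input")
  }
  expected <- encode_class(match(dataset$task, .TASK_IDS) - 1L,
                           match(dataset$group, .GROUPS) - 1L)
  if (!identical(as.integer(dataset$class), as.integer(expected))) {
    abort("Class codes are inconsistent with task/group.",
          class = "reachsynth_invalid_input")
  }
  invisible(dataset)
}

#' Per-class trial counts
#'
#' @param dataset A `trial_dataset`.
#' @return A tibble with `class`, `task`, `group`, and `n`, covering all 30
#'   classes (zero counts included).
#' @export
class_counts <- function(dataset) {
  grid <- decode_class(0:29)
  names(grid)[names(grid) == "code"] <- "class"
  counts <- dplyr::count(as_tibble(dataset)[c("class")], .data$class)
  out <- left_join(grid, counts, by = "class")
  out$n[is.na(out$n)] <- 0L
  out[c("class", "task", "group", "n")]
}

# Stack the signal list-column into a B x 300 x 9 array.
trials_to_array <- function(dataset) {
  b <- nrow(dataset)
  x <- array(0, dim = c(b, .TRIAL_LEN, 9L))
  for (i in seq_len(b)) x[i, , ] <- dataset$signal[[i]]
  x
}

array_to_signals <- function(x) {
  lapply(seq_len(dim(x)[1]), function(i) {
    m <- x[i, , ]
    colnames(m) <- .CHANNEL_NAMES
    m
  })
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "<trial_dataset: %d trials (%d real, %d synthetic), %d of 30 classes>\n",
    nrow(x), sum(x$provenance == "real"), sum(x$provenance == "synthetic"),
    length(unique(x$class))
  ))
  NextMethod()
}
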