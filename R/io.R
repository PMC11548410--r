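# Plain-text trial I/O: one wide CSV per trial plus a metadata sidecar.

#' Describe a CSV trial-file dialect
#'
#' Readers for tabular motion-capture exports need to know the source units
#' and layout. The default dialect matches common Xsens-style exports: one
#' wide CSV per trial with a header naming the 9 channels, positions in
#' meters and angles in degrees. [write_trials()] always writes canonical
#' units (cm / rad) and records that in the metadata sidecar, which overrides
#' these defaults on read.
#'
#' @param position_unit `"m"`, `"mm"`, or `"cm"`.
#' @param angle_unit `"deg"` or `"rad"`.
#' @param layout `"wide"` (one column per channel) or `"long"` (columns
#'   `time`, `channel`, `value`).
#' @return A `trial_dialect` list.
#' @export
trial_dialect <- function(position_unit = "m", angle_unit = "deg",
                          layout = "wide") {
  if (!layout %in% c("wide", "long")) {
    abort("layout must be 'wide' or 'long'.",
          class = "reachsynth_config_error")
  }
  structure(
    list(position_unit = position_unit, angle_unit = angle_unit,
         layout = layout),
    class = "trial_dialect"
  )
}

#' Write a trial dataset to a directory of CSV files
#'
#' Writes one wide CSV per trial (`trial_00001.csv`, ...) with the 9 channel
#' columns at full double precision, and a `metadata.csv` sidecar with
#' `trial_file`, `subject_id`, `task`, `fmma_ue`, `is_control`, `group`,
#' `provenance`, `position_unit`, `angle_unit`.
#'
#' @param dataset A `trial_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trials <- function(dataset, dir) {
  validate_trials(dataset)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("trial_%05d.csv", seq_len(nrow(dataset)))
  for (i in seq_len(nrow(dataset))) {
    m <- dataset$signal[[i]]
    # 17 significant digits: doubles survive the text round trip bit-exactly
    txt <- apply(m, 2, function(col) sprintf("%.17g", col))
    colnames(txt) <- .CHANNEL_NAMES
    readr::write_csv(as_tibble(txt), file.path(dir, files[i]),
                     quote = "none")
  }
  fmma <- if ("fmma" %in% names(dataset)) dataset$fmma else NA_integer_
  meta <- tibble(
    trial_file = files,
    subject_id = dataset$subject_id,
    task = dataset$task,
    fmma_ue = fmma,
    is_control = dataset$group == "control",
    group = dataset$group,
    provenance = dataset$provenance,
    position_unit = "cm",
    angle_unit = "rad"
  )
  readr::write_csv(meta, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Read a directory of trial CSV files
#'
#' Loads every trial listed in `metadata.csv`, converts units to canonical
#' cm / rad via [normalize_units()], fixes the length to 300 samples via
#' [pad_or_crop()], and recomputes the impairment group from the FMMA-UE
#' score when the sidecar does not carry one. Trials with a missing channel,
#' non-finite values, or an unknown task ID are rejected individually with a
#' warning; the reasons are attached as the `"rejected"` attribute.
#'
#' @param dir Directory containing trial CSVs and `metadata.csv`.
#' @param dialect A [trial_dialect()] giving source units and layout;
#'   per-trial units in the sidecar take precedence.
#' @return A `trial_dataset` of the accepted trials.
#' @export
read_trials <- function(dir, dialect = trial_dialect()) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    abort(paste0("No metadata.csv in ", dir),
          class = "reachsynth_invalid_input")
  }
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  rows <- list()
  rejected <- list()
  for (i in seq_len(nrow(meta))) {
    res <- read_one_trial(dir, meta[i, ], dialect)
    if (is.character(res)) {
      rejected[[length(rejected) + 1L]] <-
        tibble(trial_file = meta$trial_file[i], reason = res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rejected)) {
    rej <- bind_rows(rejected)
    warn(sprintf("Rejected %d trial(s): %s", nrow(rej),
                 paste(unique(rej$reason), collapse = "; ")))
  } else {
    rej <- tibble(trial_file = character(), reason = character())
  }
  if (!length(rows)) {
    abort("No valid trials found.", class = "reachsynth_invalid_input")
  }
  out <- as_trial_dataset(bind_rows(rows))
  attr(out, "rejected") <- rej
  out
}

read_one_trial <- function(dir, m, dialect) {
  if (!m$task %in% .TASK_IDS) return("unknown task ID")
  path <- file.path(dir, m$trial_file)
  if (!file.exists(path)) return("trial file missing")
  # parse numbers with base R (correctly rounded) for a bit-exact round trip
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  num_cols <- setdiff(names(raw), "channel")
  raw[num_cols] <- lapply(raw[num_cols], as.numeric)
  if (dialect$layout == "long") {
    if (!all(c("time", "channel", "value") %in% names(raw))) {
      return("long layout requires time/channel/value columns")
    }
    raw <- tidyr::pivot_wider(raw, id_cols = "time",
                              names_from = "channel",
                              values_from = "value")
    raw <- raw[order(raw$time), setdiff(names(raw), "time")]
  }
  if (!all(.CHANNEL_NAMES %in% names(raw))) return("missing channel")
  sig <- as.matrix(raw[.CHANNEL_NAMES])
  if (nrow(sig) < 1L) return("empty trial")
  if (!all(is.finite(sig))) return("non-finite value")
  has <- function(col) col %in% names(m) && !is.na(m[[col]])
  pu <- if (has("position_unit")) m$position_unit else dialect$position_unit
  au <- if (has("angle_unit")) m$angle_unit else dialect$angle_unit
  sig <- pad_or_crop(normalize_units(sig, pu, au))
  colnames(sig) <- .CHANNEL_NAMES
  grp <- if (has("group") && m$group %in% .GROUPS) {
    m$group
  } else {
    assign_impairment_group(m$fmma_ue, isTRUE(m$is_control))
  }
  prov <- if (has("provenance")) m$provenance else "real"
  tibble(
    subject_id = as.character(m$subject_id),
    task = m$task,
    group = grp,
    fmma = if (has("fmma_ue")) as.integer(m$fmma_ue) else NA_integer_,
    provenance = prov,
    signal = list(sig)
  )
}
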