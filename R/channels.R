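# Fixed 9-channel layout shared by every stage of the pipeline.
# Order matters: trunk (T8) position x/y/z and axial rotation first,
# then shoulder angles x/y/z, then elbow angles x/y.

.CHANNEL_NAMES <- c(
  "T8x", "T8y", "T8z", "T8rz",
  "shoulder_x", "shoulder_y", "shoulder_z",
  "elbow_x", "elbow_y"
)
.CHANNEL_UNITS <- c(rep("cm", 3), rep("rad", 6))
.POSITION_CHANNELS <- 1:3
.ANGLE_CHANNELS <- 4:9
.TRUNK_CHANNELS <- 1:4
.ARM_CHANNELS <- 5:9

.TASK_IDS <- c("T02", "T03", "T04", "T06", "T08", "T10",
               "T16", "T18", "T19", "T28")
.TASK_LABELS <- c(
  T02 = "Distal Thumb Down", T03 = "Overhead", T04 = "Lateral",
  T06 = "Distal Palm Up", T08 = "Stop Gesture", T10 = "Hand to Mouth",
  T16 = "Grab and Bite Apple", T18 = "Move Cup", T19 = "Move Tray",
  T28 = "Move Tennis Ball"
)

.GROUPS <- c("control", "mild", "modsev")

.TRIAL_LEN <- 300L
.SAMPLE_RATE <- 60

#' Channel specification for kinematic trials
#'
#' Every trial in this package is a 300-sample x 9-channel matrix sampled at
#' 60 Hz: trunk (T8 marker) position x/y/z in centimeters and axial rotation
#' in radians, followed by shoulder (x, y, z) and elbow (x, y) joint angles in
#' radians. This function returns that fixed layout.
#'
#' @return A tibble with columns `index` (0-based), `name`, and `unit`.
#' @examples
#' channel_spec()
#' @export
channel_spec <- function() {
  tibble(
    index = 0:8,
    name = .CHANNEL_NAMES,
    unit = .CHANNEL_UNITS
  )
}

#' Task identifiers covered by the pipeline
#'
#' The ten short reach-and-return tasks, in the fixed order used for class
#' encoding (task index 0 to 9).
#'
#' @param labels If `TRUE`, return a named character vector of human-readable
#'   task descriptions instead of the bare IDs.
#' @return Character vector of 10 task IDs (or labeled descriptions).
#' @examples
#' task_ids()
#' task_ids(labels = TRUE)[["T16"]]
#' @export
task_ids <- function(labels = FALSE) {
  if (labels) .TASK_LABELS else .TASK_IDS
}

#' Impairment group levels
#'
#' @return Character vector `c("control", "mild", "modsev")` in class-encoding
#'   order (group index 0 to 2). `"modsev"` pools moderate and severe
#'   impairment, which are combined because severe impairment is rare in the
#'   source cohort.
#' @export
impairment_groups <- function() .GROUPS
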