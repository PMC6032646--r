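#' IMU trial recordings
#'
#' An `imu_recording` is a tibble with one row per sample and columns
#' `time` (seconds, uniform grid), `acc_x`, `acc_y`, `acc_z` (linear
#' acceleration, m/s^2) and `gyr_x`, `gyr_y`, `gyr_z` (angular velocity,
#' deg/s), carrying the sampling rate and trial metadata as attributes.
#' All user-facing functions accept and return this tabular form so
#' recordings compose with dplyr verbs.
#'
#' @param data data frame with columns `time`, `acc_x`, `acc_y`, `acc_z`,
#'   `gyr_x`, `gyr_y`, `gyr_z`.
#' @param fs sampling rate in Hz. Defaults to 51.2, the rate of the wireless
#'   sensors this package targets. If `NULL`, inferred from the `time`
#'   column.
#' @param meta optional [trial_metadata()] row describing the trial.
#'
#' @details Invariants enforced: sample spacing uniform to 1e-6 relative
#' tolerance, all samples finite, and at least `2 * fs` samples (2 s) so
#' that downstream spectral and entropy features are defined.
#'
#' @return A tibble of class `imu_recording` with attributes `fs` and `meta`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1 / 51.2)
#' rec <- imu_recording(data.frame(
#'   time = t,
#'   acc_x = sin(2 * pi * 5 * t), acc_y = 0, acc_z = 9.80665,
#'   gyr_x = 0, gyr_y = 0, gyr_z = 0
#' ))
#' rec_fs(rec)
imu_recording <- function(data, fs = NULL, meta = NULL) {
  data <- as_tibble(data)
  missing_cols <- setdiff(imu_channels(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("recording is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tremorkit_format_error")
  }
  data <- data[, imu_channels()]
  vals <- as.matrix(data)
  if (!all(is.finite(vals))) {
    abort("recording contains non-finite samples (NaN/Inf/NA)",
          class = "tremorkit_data_error")
  }
  dt <- diff(data$time)
  if (length(dt) < 1 || any(dt <= 0)) {
    abort("time column must be strictly increasing",
          class = "tremorkit_sampling_error")
  }
  dt0 <- mean(dt)
  if (max(abs(dt - dt0)) > 1e-6 * dt0) {
    abort("non-uniform sample spacing (beyond 1e-6 relative tolerance)",
          class = "tremorkit_sampling_error")
  }
  fs_time <- 1 / dt0
  if (is.null(fs)) {
    fs <- fs_time
  } else {
    stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
    # The observed time grid is authoritative over a declared rate.
    if (abs(fs_time - fs) > 1e-3 * fs) {
      warn(sprintf(
        "declared fs = %.4g Hz disagrees with time column (%.4g Hz) by >0.1%%; using the time column",
        fs, fs_time))
      fs <- fs_time
    }
  }
  if (nrow(data) < 2 * fs) {
    abort("recording shorter than 2 s; too short for feature extraction",
          class = "tremorkit_too_short_error")
  }
  if (!is.null(meta)) meta <- validate_metadata(meta)
  new_imu_recording(data, fs = fs, meta = meta)
}

new_imu_recording <- function(data, fs, meta = NULL, transient_sec = NULL) {
  structure(data,
            fs = fs, meta = meta, transient_sec = transient_sec,
            class = c("imu_recording", class(as_tibble(data))))
}

imu_channels <- function() {
  c("time", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
}

#' @rdname imu_recording
#' @param x an `imu_recording`.
#' @export
rec_fs <- function(x) attr(x, "fs")

#' @rdname imu_recording
#' @export
rec_meta <- function(x) attr(x, "meta")

#' @export
print.imu_recording <- function(x, ...) {
  fs <- rec_fs(x)
  cat(sprintf("<imu_recording: %d samples at %.4g Hz (%.1f s)>\n",
              nrow(x), fs, nrow(x) / fs))
  m <- rec_meta(x)
  if (!is.null(m)) {
    cat(sprintf("  %s | %s | %s | %s | %s | trial %d\n",
                m$subject_id, m$group, m$side, m$segment, m$task, m$trial))
  }
  NextMethod()
}

#' Trial metadata
#'
#' One row describing a recorded trial: subject, diagnostic group (`PD`
#' patients vs `CO` healthy controls), body side, arm segment carrying the
#' sensor, motor task (`kinetic` = finger-to-nose, `postural` = outstretched
#' arm), trial repetition 1--3, and the per-side clinical tremor score
#' (UPDRS item 21, 0--4; recorded for PD subjects only).
#'
#' @param subject_id character subject label.
#' @param group `"PD"` or `"CO"`.
#' @param side `"left"` or `"right"`.
#' @param segment `"upper_arm"`, `"forearm"` or `"hand"`.
#' @param task `"kinetic"` or `"postural"`.
#' @param trial integer in 1:3; each motor task is performed three times.
#' @param updrs21 integer 0--4, or `NA` (must be `NA` for controls).
#'
#' @return A one-row tibble of class `trial_metadata`.
#' @export
trial_metadata <- function(subject_id, group, side, segment, task, trial,
                           updrs21 = NA_integer_) {
  meta <- tibble(
    subject_id = as.character(subject_id),
    group = as.character(group), side = as.character(side),
    segment = as.character(segment), task = as.character(task),
    trial = as.integer(trial), updrs21 = as.integer(updrs21)
  )
  meta <- validate_metadata(meta)
  if (meta$group == "CO" && !is.na(meta$updrs21)) {
    abort("updrs21 must be absent (NA) for control (CO) subjects",
          class = "tremorkit_format_error")
  }
  meta
}

validate_metadata <- function(meta) {
  meta <- as_tibble(meta)
  req <- c("subject_id", "group", "side", "segment", "task", "trial", "updrs21")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata missing field(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tremorkit_format_error")
  }
  chk <- function(field, allowed) {
    bad <- !meta[[field]] %in% allowed
    if (any(bad)) {
      abort(sprintf("invalid %s: %s (allowed: %s)", field,
                    paste(unique(meta[[field]][bad]), collapse = ", "),
                    paste(allowed, collapse = ", ")),
            class = "tremorkit_format_error")
    }
  }
  chk("group", c("PD", "CO"))
  chk("side", c("left", "right"))
  chk("segment", c("upper_arm", "forearm", "hand"))
  chk("task", c("kinetic", "postural"))
  chk("trial", 1:3)
  bad_updrs <- !is.na(meta$updrs21) & !meta$updrs21 %in% 0:4
  if (any(bad_updrs)) {
    abort("updrs21 must be an integer 0-4 or NA",
          class = "tremorkit_format_error")
  }
  class(meta) <- unique(c("trial_metadata", class(as_tibble(meta))))
  meta
}
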