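#' Read and write single-trial IMU recordings
#'
#' Recordings are stored one trial per CSV file: `#`-prefixed `key=value`
#' header lines carry the sampling rate, acceleration units and trial
#' metadata, followed by a standard comma-delimited table with columns
#' `time, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`. Acceleration is held
#' internally in m/s^2; files declaring `units_acc=g` are converted
#' (x 9.80665) on read.
#'
#' @param path file path.
#' @return `read_imu_csv()` returns a validated [imu_recording()];
#'   `write_imu_csv()` returns `path` invisibly.
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tremorkit_io_error")
  }
  hdr <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  kv <- parse_header(hdr)
  body <- utils::read.csv(textConnection(c(line, readLines(con))),
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(imu_channels(), names(body))
  if (length(missing_cols) > 0) {
    abort(paste0("recording file missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tremorkit_format_error")
  }
  units_acc <- kv[["units_acc"]] %||% "m/s2"
  if (identical(units_acc, "g")) {
    for (ch in c("acc_x", "acc_y", "acc_z")) {
      body[[ch]] <- body[[ch]] * STANDARD_GRAVITY
    }
  } else if (!identical(units_acc, "m/s2")) {
    abort(paste0("unknown acceleration units: ", units_acc),
          class = "tremorkit_format_error")
  }
  fs <- if (!is.null(kv[["fs"]])) as.numeric(kv[["fs"]]) else NULL
  meta <- header_metadata(kv)
  imu_recording(body, fs = fs, meta = meta)
}

#' @rdname read_imu_csv
#' @param rec an [imu_recording()].
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  m <- rec_meta(rec)
  hdr <- c(sprintf("# fs=%.10g", rec_fs(rec)), "# units_acc=m/s2")
  if (!is.null(m)) {
    for (field in c("subject_id", "group", "side", "segment", "task",
                    "trial", "updrs21")) {
      val <- m[[field]]
      if (length(val) == 1 && !is.na(val)) {
        hdr <- c(hdr, sprintf("# %s=%s", field, as.character(val)))
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(rec)[, imu_channels()], con,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_header <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  lines <- lines[nzchar(lines) & grepl("=", lines, fixed = TRUE)]
  keys <- sub("=.*$", "", lines)
  vals <- sub("^[^=]*=", "", lines)
  setNames(as.list(trimws(vals)), trimws(keys))
}

header_metadata <- function(kv) {
  req <- c("subject_id", "group", "side", "segment", "task", "trial")
  if (!all(req %in% names(kv))) return(NULL)
  validate_metadata(tibble(
    subject_id = kv$subject_id, group = kv$group, side = kv$side,
    segment = kv$segment, task = kv$task, trial = as.integer(kv$trial),
    updrs21 = if (is.null(kv$updrs21)) NA_integer_ else as.integer(kv$updrs21)
  ))
}

#' Write and read per-subject feature tables
#'
#' A feature table has one row per (subject, side, segment) and twelve
#' metric columns: dominant frequency (`f_`), root mean square (`rms_`) and
#' approximate entropy (`apen_`) for each of the kinetic and postural tasks
#' and each of the acceleration (`acc`) and angular-velocity (`gyr`)
#' signals. Values round-trip through text at full double precision.
#'
#' @param features tibble as produced by [extract_features()].
#' @param path file path for the CSV table.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(features, path) {
  if (is.null(features) || nrow(as_tibble(features)) == 0) {
    abort("feature table is empty", class = "tremorkit_usage_error")
  }
  features <- as_tibble(features)
  key <- c("subject_id", "side", "segment")
  if (!all(key %in% names(features))) {
    abort("feature table must contain subject_id, side, segment columns",
          class = "tremorkit_usage_error")
  }
  dup <- duplicated(features[, key])
  if (any(dup)) {
    abort(paste0("duplicate (subject_id, side, segment) key(s): ",
                 paste(unique(sprintf("%s/%s/%s",
                                      features$subject_id[dup],
                                      features$side[dup],
                                      features$segment[dup])),
                       collapse = "; ")),
          class = "tremorkit_duplicate_key_error")
  }
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' The twelve tremor metric names
#'
#' @return Character vector of the metric column names, in conventional
#'   order: dominant frequency, RMS, ApEn, each for kinetic/postural task
#'   and acceleration/gyroscope signal.
#' @export
feature_metrics <- function() {
  as.vector(outer(c("f", "rms", "apen"),
                  c("kin_acc", "pos_acc", "kin_gyr", "pos_gyr"),
                  paste, sep = "_"))
}

#' Validate a cohort's completeness and metadata consistency
#'
#' Report-only validation of a cohort metadata table (one row per
#' recording). A complete subject contributes 3 trials x 2 tasks x 6 sensor
#' placements (2 sides x 3 segments) = 36 recordings. PD subjects must carry
#' a per-side clinical score (UPDRS item 21); controls must not.
#'
#' @param metadata tibble with columns `subject_id`, `group`, `side`,
#'   `segment`, `task`, `trial`, `updrs21`.
#' @return A tibble of issues with columns `subject_id`, `type`, `detail`;
#'   zero rows when the cohort is complete and consistent.
#' @export
validate_cohort <- function(metadata) {
  metadata <- as_tibble(metadata)
  expected <- tidyr::expand_grid(
    side = c("left", "right"),
    segment = c("upper_arm", "forearm", "hand"),
    task = c("kinetic", "postural"),
    trial = 1:3
  )
  issues <- purrr::map_dfr(split(metadata, metadata$subject_id), function(md) {
    sid <- md$subject_id[1]
    have <- md %>% distinct(.data$side, .data$segment, .data$task, .data$trial)
    miss <- dplyr::anti_join(expected, have,
                             by = c("side", "segment", "task", "trial"))
    out <- tibble(subject_id = character(), type = character(),
                  detail = character())
    if (nrow(miss) > 0) {
      out <- bind_rows(out, tibble(
        subject_id = sid, type = "missing_trial",
        detail = sprintf("%s/%s/%s trial %d", miss$side, miss$segment,
                         miss$task, miss$trial)))
    }
    grp <- md$group[1]
    by_side <- md %>% group_by(.data$side) %>%
      summarise(scored = any(!is.na(.data$updrs21)), .groups = "drop")
    if (grp == "PD" && any(!by_side$scored)) {
      out <- bind_rows(out, tibble(
        subject_id = sid, type = "missing_updrs21",
        detail = sprintf("PD subject lacks updrs21 on side: %s",
                         paste(by_side$side[!by_side$scored], collapse = ", "))))
    }
    if (grp == "CO" && any(by_side$scored)) {
      out <- bind_rows(out, tibble(
        subject_id = sid, type = "metadata",
        detail = "control (CO) subject carries an updrs21 score"))
    }
    out
  })
  as_tibble(issues)
}
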