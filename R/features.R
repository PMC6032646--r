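#' Periodogram power spectral density
#'
#' One-sided rectangular-window periodogram of a single-axis signal:
#' `P(f) = |DFT(x)|^2 / (L * fs)`, with interior bins doubled so that
#' `sum(psd) * df` equals the mean square of the input (Parseval). No
#' zero-padding, segment averaging, tapering or detrending is applied;
#' preprocessing is expected to have removed DC and trend.
#'
#' @param x numeric signal (length >= 8, finite).
#' @param fs sampling rate, Hz.
#' @return A tibble of class `spectral_estimate` with columns `freq` (Hz,
#'   grid `0..fs/2` spaced `fs/L`) and `psd` ((signal units)^2 / Hz), and
#'   attribute `fs`.
#' @export
#' @examples
#' t <- (0:511) / 51.2
#' p <- periodogram_psd(2 * sin(2 * pi * 5 * t), fs = 51.2)
#' sum(p$psd) * (51.2 / 512)  # = amplitude^2 / 2 = 2
periodogram_psd <- function(x, fs) {
  L <- length(x)
  if (L < 8) {
    abort("signal too short for a periodogram (need length >= 8)",
          class = "tremorkit_too_short_error")
  }
  if (!all(is.finite(x))) {
    abort("signal contains non-finite values", class = "tremorkit_data_error")
  }
  X <- fft(x)
  nf <- L %/% 2 + 1
  psd <- (Mod(X[seq_len(nf)])^2) / (L * fs)
  interior <- seq(2, nf - if (L %% 2 == 0) 1 else 0)
  psd[interior] <- 2 * psd[interior]
  structure(tibble(freq = (seq_len(nf) - 1) * fs / L, psd = psd),
            fs = fs,
            class = c("spectral_estimate", class(tibble())))
}

spectra_3axis <- function(mat, fs, axes = colnames(mat)) {
  purrr::map2_dfr(seq_len(ncol(mat)), axes, function(i, nm) {
    periodogram_psd(mat[, i], fs) %>% mutate(axis = nm, .before = 1)
  })
}

#' Dominant tremor frequency across axes
#'
#' Finds, per axis, the periodogram bin of maximum power inside the search
#' band, then takes the dominant frequency from the axis whose peak power is
#' largest — so when axes disagree, the strongest oscillation wins. Ties are
#' broken towards the lower frequency, then the lower axis index.
#'
#' @param spectra a long tibble of per-axis spectra with columns `axis`,
#'   `freq`, `psd` (as from stacking [periodogram_psd()] results), or a
#'   single-axis `spectral_estimate`.
#' @param band numeric length-2 search band in Hz, or `NULL` (default) for
#'   1 Hz (the high-pass cut-off) up to the Nyquist frequency.
#' @return A one-row tibble: `f_dom` (Hz), `axis`, `peak_power`.
#' @export
dominant_frequency <- function(spectra, band = NULL) {
  if (inherits(spectra, "spectral_estimate") && !"axis" %in% names(spectra)) {
    spectra <- mutate(spectra, axis = "x", .before = 1)
  }
  if (is.null(band)) band <- c(1, max(spectra$freq))
  stopifnot(band[1] < band[2], band[1] >= 0)
  axes <- unique(spectra$axis)
  inband <- spectra %>%
    filter(.data$freq >= band[1], .data$freq <= band[2])
  if (nrow(inband) == 0 || all(inband$psd <= 0)) {
    abort("no positive spectral power inside the search band",
          class = "tremorkit_no_peak_error")
  }
  peaks <- inband %>%
    group_by(.data$axis) %>%
    # within an axis: maximum power, ties towards the lower frequency
    arrange(dplyr::desc(.data$psd), .data$freq, .by_group = TRUE) %>%
    summarise(f_dom = first(.data$freq), peak_power = first(.data$psd),
              .groups = "drop") %>%
    # across axes: ties towards lower frequency, then lower axis index
    mutate(axis_index = match(.data$axis, axes)) %>%
    arrange(dplyr::desc(.data$peak_power), .data$f_dom, .data$axis_index)
  peaks %>%
    dplyr::slice(1) %>%
    select("f_dom", "axis", "peak_power")
}

#' Approximate entropy parameters
#'
#' @param m embedding (template) length; default 2.
#' @param r_coeff similarity tolerance as a multiple of the series standard
#'   deviation; default 0.45, the recommended setting for short
#'   physiological series with m = 2.
#' @return A list of class `apen_params`.
#' @export
apen_params <- function(m = 2, r_coeff = 0.45) {
  if (m < 1) abort("m must be >= 1", class = "tremorkit_spec_error")
  if (!(r_coeff > 0)) {
    abort("r_coeff must be > 0", class = "tremorkit_spec_error")
  }
  structure(list(m = as.integer(m), r_coeff = r_coeff),
            class = "apen_params")
}

#' Approximate entropy of a time series
#'
#' Regularity statistic: low values indicate predictable, regular series;
#' high values indicate irregular ones. Standard formulation with
#' self-matches: `ApEn = Phi_m(r) - Phi_{m+1}(r)`, where `Phi_m` is the
#' average log-fraction of length-`m` templates lying within Chebyshev
#' distance `r` (inclusive). The tolerance is `r_coeff` times the population
#' standard deviation (divisor N) of the series; an absolute tolerance can
#' be supplied instead via `r_abs`.
#'
#' @param x numeric series, length >= 50, non-constant.
#' @param params an [apen_params()].
#' @param r_abs optional absolute tolerance overriding `r_coeff * sd(x)`.
#' @return Non-negative scalar (dimensionless).
#' @export
approx_entropy <- function(x, params = apen_params(), r_abs = NULL) {
  n <- length(x)
  if (n < 50) {
    abort("series too short for approximate entropy (need N >= 50)",
          class = "tremorkit_too_short_error")
  }
  if (!all(is.finite(x))) {
    abort("series contains non-finite values", class = "tremorkit_data_error")
  }
  if (is.null(r_abs)) {
    s <- sqrt(mean((x - mean(x))^2))  # population SD, divisor N
    if (s == 0) {
      abort("constant series: approximate entropy undefined (SD = 0)",
            class = "tremorkit_degenerate_error")
    }
    r_abs <- params$r_coeff * s
  }
  apen_cpp(as.numeric(x), params$m, r_abs)
}

#' Root mean square
#'
#' @param x numeric vector (non-empty, finite).
#' @return `sqrt(mean(x^2))`, the tremor-intensity measure in signal units.
#' @export
rms <- function(x) {
  if (length(x) == 0) {
    abort("rms of an empty series is undefined",
          class = "tremorkit_usage_error")
  }
  if (!all(is.finite(x))) {
    abort("series contains non-finite values", class = "tremorkit_data_error")
  }
  sqrt(mean(x^2))
}

resultant_magnitude <- function(mat) sqrt(rowSums(mat^2))

# Matrix fast path used by trial_features(): one-sided periodograms of the
# three axes via mvfft, then the cross-axis peak rule (max power in band;
# ties to lower frequency, then lower axis index). Matches
# periodogram_psd() + dominant_frequency() exactly; the agreement is pinned
# by tests.
dom_freq_mat <- function(mat, fs, band = NULL) {
  L <- nrow(mat)
  X <- stats::mvfft(mat)
  nf <- L %/% 2 + 1
  psd <- (Mod(X[seq_len(nf), , drop = FALSE])^2) / (L * fs)
  interior <- seq(2, nf - if (L %% 2 == 0) 1 else 0)
  psd[interior, ] <- 2 * psd[interior, ]
  freq <- (seq_len(nf) - 1) * fs / L
  if (is.null(band)) band <- c(1, fs / 2)
  sel <- which(freq >= band[1] & freq <= band[2])
  if (length(sel) == 0 || all(psd[sel, ] <= 0)) {
    abort("no positive spectral power inside the search band",
          class = "tremorkit_no_peak_error")
  }
  peak_idx <- integer(3); peak_val <- numeric(3)
  for (ax in 1:3) {
    p <- psd[sel, ax]
    peak_idx[ax] <- sel[which.max(p)]   # which.max takes the first (lowest
    peak_val[ax] <- max(p)              # frequency) of tied maxima
  }
  ord <- order(-peak_val, freq[peak_idx], seq_len(3))
  win <- ord[1]
  list(f_dom = freq[peak_idx[win]], axis = c("x", "y", "z")[win],
       peak_power = peak_val[win])
}

#' Per-trial tremor features
#'
#' Computes, for each preprocessed recording in a trials table, the dominant
#' frequency (per signal, cross-axis rule on the per-axis periodograms) and
#' the RMS and approximate entropy of the resultant magnitude series
#' `sqrt(x^2 + y^2 + z^2)`, separately for acceleration and angular
#' velocity. Only post-transient samples enter the computation.
#'
#' @param trials tibble with metadata columns and a `recording` list-column
#'   of preprocessed [imu_recording()]s (or an `imu_cohort`).
#' @param params an [apen_params()].
#' @param band dominant-frequency search band, Hz.
#' @param per_axis if `TRUE`, RMS and ApEn are computed on the axis selected
#'   by the dominant-frequency rule instead of the resultant magnitude
#'   (sensitivity-analysis mode; the magnitude default is rotation
#'   invariant).
#' @return A tibble, one row per (trial, signal in acc/gyr): metadata
#'   columns plus `signal`, `f_dom`, `axis`, `rms`, `apen`, `n_samples`.
#' @export
trial_features <- function(trials, params = apen_params(), band = NULL,
                           per_axis = FALSE) {
  if (inherits(trials, "imu_cohort")) trials <- trials$trials
  stopifnot(is_tibble(trials), "recording" %in% names(trials))
  meta_cols <- intersect(
    c("subject_id", "group", "side", "segment", "task", "trial", "updrs21"),
    names(trials))
  rows <- vector("list", 2 * nrow(trials))
  for (i in seq_len(nrow(trials))) {
    rec <- trials$recording[[i]]
    win <- analysis_window(rec)
    fs <- rec_fs(rec)
    for (k in 1:2) {
      sig <- c("acc", "gyr")[k]
      mat <- cbind(win[[paste0(sig, "_x")]], win[[paste0(sig, "_y")]],
                   win[[paste0(sig, "_z")]])
      dom <- dom_freq_mat(mat, fs, band = band)
      series <- if (per_axis) {
        mat[, match(dom$axis, c("x", "y", "z"))]
      } else {
        resultant_magnitude(mat)
      }
      rows[[2 * (i - 1) + k]] <- c(
        as.list(trials[i, meta_cols]),
        list(signal = sig, f_dom = dom$f_dom, axis = dom$axis,
             rms = rms(series),
             apen = approx_entropy(series, params = params),
             n_samples = nrow(win)))
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-subject feature table
#'
#' Aggregates per-trial features by arithmetic mean over the available
#' repetitions (up to three per task) and pivots to the wide twelve-metric
#' layout: `f`, `rms`, `apen` for each (task in kinetic/postural) x (signal
#' in acc/gyr), one row per (subject, side, segment). Group and clinical
#' score columns are carried through when present.
#'
#' @inheritParams trial_features
#' @return A tibble with key columns `subject_id`, (`group`,) `side`,
#'   `segment`, (`updrs21`,) `n_trials`, and the metric columns named
#'   `f_kin_acc` ... `apen_pos_gyr` (see [feature_metrics()]).
#' @export
extract_features <- function(trials, params = apen_params(), band = NULL,
                             per_axis = FALSE) {
  per_trial <- if (is_tibble(trials) && all(c("signal", "f_dom") %in% names(trials))) {
    trials  # already trial-level features
  } else {
    trial_features(trials, params = params, band = band, per_axis = per_axis)
  }
  if (nrow(per_trial) == 0) {
    abort("no trials available for feature extraction",
          class = "tremorkit_missing_data_error")
  }
  carry <- intersect(c("group", "updrs21"), names(per_trial))
  long <- per_trial %>%
    group_by(across(all_of(c("subject_id", carry, "side", "segment", "task",
                             "signal")))) %>%
    summarise(f = mean(.data$f_dom), rms = mean(.data$rms),
              apen = mean(.data$apen), n_trials = dplyr::n_distinct(.data$trial),
              .groups = "drop")
  wide <- long %>%
    mutate(task3 = ifelse(.data$task == "kinetic", "kin", "pos")) %>%
    tidyr::pivot_wider(
      id_cols = all_of(c("subject_id", carry, "side", "segment")),
      names_from = c("task3", "signal"),
      values_from = c("f", "rms", "apen"),
      names_glue = "{.value}_{task3}_{signal}") %>%
    left_join(long %>%
                group_by(across(all_of(c("subject_id", "side", "segment")))) %>%
                summarise(n_trials = max(.data$n_trials), .groups = "drop"),
              by = c("subject_id", "side", "segment"))
  metric_order <- intersect(feature_metrics(), names(wide))
  wide %>% select(all_of(c("subject_id", carry, "side", "segment",
                           "n_trials", metric_order)))
}
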