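#' High-pass filter design for tremor isolation
#'
#' Designs the digital first-order Butterworth high-pass (cut-off 1 Hz by
#' default) applied to every channel before feature extraction. Design is by
#' bilinear transform with frequency prewarping, so the magnitude response
#' at the cut-off is exactly 1/sqrt(2) and the DC gain is exactly zero.
#'
#' @param fs sampling rate, Hz.
#' @param cutoff cut-off frequency, Hz (must satisfy 0 < cutoff < fs/2).
#' @param order filter order; the default, 1, matches the intended
#'   single-pole tremor preprocessing.
#' @return A list of class `highpass_spec` with elements `b`, `a`
#'   (transfer-function coefficients), `fs`, `cutoff`, `order`.
#' @export
#' @examples
#' hp <- highpass_design(51.2)
#' highpass_gain(hp, c(0, 1, 10))  # 0, 1/sqrt(2), ~0.996
highpass_design <- function(fs, cutoff = 1, order = 1) {
  if (!(cutoff > 0 && cutoff < fs / 2)) {
    abort(sprintf("cutoff must lie in (0, fs/2) = (0, %g)", fs / 2),
          class = "tremorkit_design_error")
  }
  bt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  structure(list(b = as.numeric(bt$b), a = as.numeric(bt$a), fs = fs,
                 cutoff = cutoff, order = order),
            class = "highpass_spec")
}

#' @rdname highpass_design
#' @param filt a `highpass_spec`.
#' @param f frequencies (Hz) at which to evaluate the magnitude response.
#' @export
highpass_gain <- function(filt, f) {
  z <- exp(-2i * pi * f / filt$fs)
  num <- outer(z, seq_along(filt$b) - 1, `^`) %*% filt$b
  den <- outer(z, seq_along(filt$a) - 1, `^`) %*% filt$a
  as.numeric(Mod(num / den))
}

# Causal IIR filtering with the internal state initialised to steady state
# for a constant input equal to the first sample, suppressing the start-up
# transient on signals with a DC offset. First-order transfer function only.
filter_causal1 <- function(x, b, a) {
  stopifnot(length(b) == 2, length(a) == 2, a[1] == 1)
  # v[n] = b0 x[n] + b1 x[n-1], with x[0] extended backwards as x[1]
  v <- b[1] * x + b[2] * c(x[1], x[-length(x)])
  # steady-state output for constant input x[1] is x[1] * H(z = 1)
  y0 <- x[1] * sum(b) / sum(a)
  as.numeric(stats::filter(v, filter = -a[2], method = "recursive",
                           init = y0))
}

#' Preprocess a recording for feature extraction
#'
#' Applies, causally (forward-only), the first-order high-pass to every
#' acceleration and angular-velocity channel. Acceleration channels first
#' have their mean subtracted (gravity / DC removal); the high-pass then
#' eliminates any residual sub-cut-off content such as slow voluntary
#' movement. The first `transient_sec` seconds are flagged in a logical
#' `transient` column and excluded from all downstream features.
#'
#' @param rec an [imu_recording()].
#' @param filt a `highpass_spec` from [highpass_design()]; defaults to the
#'   1 Hz first-order design at the recording's sampling rate.
#' @param transient_sec seconds to flag as filter start-up transient
#'   (default 2; generous against the ~0.16 s time constant of the 1 Hz
#'   single pole).
#' @return An `imu_recording` with filtered channels, an added logical
#'   `transient` column and attribute `transient_sec`.
#' @export
preprocess_recording <- function(rec, filt = NULL, transient_sec = 2) {
  stopifnot(inherits(rec, "imu_recording"))
  fs <- rec_fs(rec)
  if (is.null(filt)) filt <- highpass_design(fs)
  if (!isTRUE(all.equal(filt$fs, fs))) {
    abort("filter was designed for a different sampling rate",
          class = "tremorkit_design_error")
  }
  n <- nrow(rec)
  if (n < 2 * transient_sec * fs) {
    abort(sprintf("recording (%.2f s) shorter than twice the transient window (%g s)",
                  n / fs, transient_sec),
          class = "tremorkit_too_short_error")
  }
  out <- as_tibble(rec)
  for (ch in c("acc_x", "acc_y", "acc_z")) {
    out[[ch]] <- filter_causal1(out[[ch]] - mean(out[[ch]]), filt$b, filt$a)
  }
  for (ch in c("gyr_x", "gyr_y", "gyr_z")) {
    out[[ch]] <- filter_causal1(out[[ch]], filt$b, filt$a)
  }
  out$transient <- seq_len(n) <= round(transient_sec * fs)
  new_imu_recording(out, fs = fs, meta = rec_meta(rec),
                    transient_sec = transient_sec)
}

#' Post-transient analysis window of a preprocessed recording
#'
#' @param rec a preprocessed [imu_recording()] (with a `transient` column).
#' @return The recording restricted to post-transient samples, as a tibble.
#' @export
analysis_window <- function(rec) {
  if (!"transient" %in% names(rec)) {
    abort("recording has no transient mask; run preprocess_recording() first",
          class = "tremorkit_usage_error")
  }
  as_tibble(rec)[!rec$transient, ]
}
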