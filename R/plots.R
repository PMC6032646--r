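#' Diagnostic plots
#'
#' `autoplot()` methods for the package's result types, built on ggplot2:
#' raw or preprocessed recordings (channels over time), per-axis power
#' spectra (log-power against frequency), and group comparisons (group
#' means with SD error bars, faceted by metric and segment).
#'
#' @param object an `imu_recording`, `spectral_estimate` or
#'   `tremor_comparison`.
#' @param ... unused.
#' @return A ggplot object.
#' @name tremorkit-autoplot
NULL

#' @rdname tremorkit-autoplot
#' @export
autoplot.imu_recording <- function(object, ...) {
  long <- as_tibble(object) %>%
    select(-dplyr::any_of("transient")) %>%
    tidyr::pivot_longer(-"time", names_to = "channel", values_to = "value") %>%
    tidyr::separate("channel", into = c("signal", "axis"), sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(acc = "acceleration (m/s²)",
                            gyr = "angular velocity (°/s)"))) +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @rdname tremorkit-autoplot
#' @export
autoplot.spectral_estimate <- function(object, ...) {
  dat <- as_tibble(object)
  if (!"axis" %in% names(dat)) dat$axis <- "x"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$freq, y = .data$psd,
                                    colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power spectral density")
}

#' @rdname tremorkit-autoplot
#' @export
autoplot.tremor_comparison <- function(object, ...) {
  lab <- attr(object, "group_labels")
  long <- tidy(object) %>%
    tidyr::pivot_longer(cols = c("mean1", "mean2"), names_to = "which",
                        values_to = "mean") %>%
    mutate(sd = ifelse(.data$which == "mean1", .data$sd1, .data$sd2),
           group = ifelse(.data$which == "mean1", lab[1], lab[2]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$segment, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::facet_wrap(~ .data$metric + .data$side, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean ± SD")
}

#' Plot per-trial power spectra for a recording
#'
#' Convenience wrapper: computes per-axis periodograms of the post-transient
#' window of a preprocessed recording and plots them.
#'
#' @param rec preprocessed [imu_recording()].
#' @param signal `"acc"` or `"gyr"`.
#' @return A ggplot object.
#' @export
plot_psd <- function(rec, signal = c("acc", "gyr")) {
  signal <- match.arg(signal)
  win <- analysis_window(rec)
  mat <- as.matrix(win[, paste0(signal, "_", c("x", "y", "z"))])
  sp <- spectra_3axis(mat, rec_fs(rec), axes = c("x", "y", "z"))
  class(sp) <- c("spectral_estimate", class(tibble()))
  autoplot.spectral_estimate(sp)
}
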