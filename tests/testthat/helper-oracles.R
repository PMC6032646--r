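# Independent oracles, deliberately naive: used to pin the package's
# implementations, never the other way round.

# Brute-force approximate entropy: explicit double loop over templates,
# Chebyshev distance, inclusive tolerance, self-matches included.
# Phi_m = mean_i log(count_i / (N - m + 1)); ApEn = Phi_m - Phi_{m+1}.
apen_bruteforce <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n_templates <- N - mm + 1
    logs <- numeric(n_templates)
    for (i in seq_len(n_templates)) {
      count <- 0L
      for (j in seq_len(n_templates)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) {
          count <- count + 1L
        }
      }
      logs[i] <- log(count / n_templates)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Direct-DFT one-sided periodogram: O(L^2) sum, no fft().
pgram_dft <- function(x, fs) {
  L <- length(x)
  nf <- L %/% 2 + 1
  psd <- numeric(nf)
  n <- 0:(L - 1)
  for (k in seq_len(nf)) {
    f <- (k - 1) * fs / L
    X <- sum(x * exp(-2i * pi * f * n / fs))
    psd[k] <- Mod(X)^2 / (L * fs)
  }
  interior <- seq(2, nf - if (L %% 2 == 0) 1 else 0)
  psd[interior] <- 2 * psd[interior]
  psd
}

# Exact magnitude response of the bilinear-transform first-order high-pass
# with prewarped analog cutoff fc at rate fs (closed form, independent of
# signal::butter).
hp1_gain_exact <- function(f, fc, fs) {
  wc <- 2 * fs * tan(pi * fc / fs)    # prewarped analog cutoff (rad/s)
  K <- 2 * fs
  b0 <- K / (K + wc); b1 <- -b0; a1 <- (wc - K) / (K + wc)
  z <- exp(-2i * pi * f / fs)
  Mod((b0 + b1 * z) / (1 + a1 * z))
}

# A recording holding a single-axis sinusoid (postural-style, no noise).
sine_recording <- function(freq, amp = 1, fs = 51.2, duration = 10,
                           axis = "acc_x", gravity_z = 0) {
  t <- (0:(round(duration * fs) - 1)) / fs
  cols <- setNames(rep(list(rep(0, length(t))),
                       length(imu_channels()) - 1), imu_channels()[-1])
  cols[[axis]] <- amp * sin(2 * pi * freq * t)
  if (gravity_z != 0) cols[["acc_z"]] <- cols[["acc_z"]] + gravity_z
  imu_recording(tibble::tibble(time = t, !!!cols), fs = fs)
}

# Degenerate jitter-free, noise-free synthetic trial with tremor pinned to
# one axis.
pure_tremor_spec <- function(freq, amp_acc = 1, amp_gyr = 40, duration = 30,
                             seed = 1) {
  signal_spec(tremor_freq = freq, tremor_amp_acc = amp_acc,
              tremor_amp_gyr = amp_gyr, freq_jitter_sd = 0, amp_mod_sd = 0,
              voluntary_amp = 0, voluntary_amp_gyr = 0,
              noise_sd_acc = 0, noise_sd_gyr = 0, duration = duration,
              seed = seed)
}

axis_geometry <- list(dir_acc = c(1, 0, 0), dir_gyr = c(0, 1, 0),
                      phi_acc = c(0, 0, 0), phi_gyr = c(0, 0, 0))
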