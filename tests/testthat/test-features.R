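test_that("periodogram matches a direct DFT oracle on random signals", {
  set.seed(1)
  for (L in c(16, 64, 257)) {
    x <- rnorm(L)
    p <- periodogram_psd(x, fs = 51.2)
    expect_equal(nrow(p), L %/% 2 + 1)
    expect_equal(p$psd, pgram_dft(x, 51.2), tolerance = 1e-9)
  }
})

test_that("periodogram satisfies Parseval and closed forms", {
  fs <- 51.2
  # zero signal
  expect_true(all(periodogram_psd(rep(0, 64), fs)$psd == 0))
  # on-bin sinusoid: all power at one bin, total = A^2 / 2
  t <- (0:511) / fs
  p <- periodogram_psd(2 * sin(2 * pi * 5 * t), fs)
  df <- fs / 512
  expect_equal(sum(p$psd) * df, 2, tolerance = 1e-9)
  expect_equal(sum(p$psd > 1e-12), 1)
  expect_equal(p$freq[which.max(p$psd)], 5)
  # unit impulse: flat spectrum, total power = 1/L
  imp <- c(1, rep(0, 63))
  pi_ <- periodogram_psd(imp, fs)
  expect_equal(sum(pi_$psd) * (fs / 64), 1 / 64, tolerance = 1e-12)
  interior <- pi_$psd[2:32]
  expect_lt(diff(range(interior)) / mean(interior), 1e-9)
  # Parseval on random signals, odd and even lengths
  set.seed(2)
  for (L in c(100, 101, 256)) {
    x <- rnorm(L)
    p <- periodogram_psd(x, fs)
    expect_equal(sum(p$psd) * fs / L, mean(x^2), tolerance = 1e-6)
  }
  expect_error(periodogram_psd(rnorm(7), fs),
               class = "tremorkit_too_short_error")
})

test_that("periodogram agrees with spec.pgram as an independent route", {
  set.seed(3)
  x <- rnorm(256)
  p <- periodogram_psd(x, 51.2)
  ref <- stats::spec.pgram(ts(x, frequency = 51.2), taper = 0, detrend = FALSE,
                           demean = FALSE, fast = FALSE, plot = FALSE)
  # spec.pgram drops DC and scales the two-sided density by 1/2
  expect_equal(p$psd[2:128], 2 * ref$spec[1:127], tolerance = 1e-9)
})

test_that("the cross-axis rule picks the strongest axis and breaks ties low", {
  fs <- 51.2
  t <- (0:511) / fs
  spec_of <- function(x) periodogram_psd(x, fs)
  stack <- dplyr::bind_rows(
    dplyr::mutate(spec_of(1 * sin(2 * pi * 3 * t)), axis = "x"),
    dplyr::mutate(spec_of(2 * sin(2 * pi * 6 * t)), axis = "y"),
    dplyr::mutate(spec_of(rep(0, 512)), axis = "z"))
  dom <- dominant_frequency(stack)
  expect_equal(dom$f_dom, 6)
  expect_equal(dom$axis, "y")

  # single active axis
  one <- dplyr::mutate(spec_of(sin(2 * pi * 5 * t)), axis = "x")
  expect_equal(dominant_frequency(one)$f_dom, 5)

  # identical spectra on two axes: first axis wins
  twin <- dplyr::bind_rows(
    dplyr::mutate(spec_of(sin(2 * pi * 4 * t)), axis = "x"),
    dplyr::mutate(spec_of(sin(2 * pi * 4 * t)), axis = "y"))
  expect_equal(dominant_frequency(twin)$axis, "x")

  # band restriction and the no-peak error
  expect_equal(dominant_frequency(stack, band = c(1, 4))$f_dom, 3)
  expect_error(dominant_frequency(dplyr::mutate(stack, psd = 0)),
               class = "tremorkit_no_peak_error")
})

test_that("matrix fast path reproduces the tibble route exactly", {
  set.seed(4)
  fs <- 51.2
  for (i in 1:5) {
    mat <- matrix(rnorm(3 * 300), ncol = 3)
    stack <- dplyr::bind_rows(lapply(1:3, function(ax)
      dplyr::mutate(periodogram_psd(mat[, ax], fs),
                    axis = c("x", "y", "z")[ax])))
    slow <- dominant_frequency(stack)
    fast <- tremorkit:::dom_freq_mat(mat, fs)
    expect_equal(fast$f_dom, slow$f_dom)
    expect_equal(fast$axis, slow$axis)
    expect_equal(fast$peak_power, slow$peak_power, tolerance = 1e-12)
  }
})

test_that("approximate entropy equals the brute-force oracle", {
  set.seed(5)
  params <- apen_params(m = 2, r_coeff = 0.45)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    x <- switch(1 + i %% 3,
                rnorm(n),
                sin(0.3 * seq_len(n)) + rnorm(n, sd = 0.2),
                cumsum(rnorm(n)))
    r <- 0.45 * sqrt(mean((x - mean(x))^2))
    expect_equal(approx_entropy(x, params), apen_bruteforce(x, 2, r),
                 tolerance = 1e-12)
  }
  # repeating pattern: near-zero ApEn, equal to the oracle absolutely
  x <- rep(c(1, 2, 3), 20)
  r <- 0.45 * sqrt(mean((x - mean(x))^2))
  expect_lt(abs(approx_entropy(x) - apen_bruteforce(x, 2, r)), 1e-12)
})

test_that("approximate entropy handles the degenerate regimes", {
  # tolerance wider than the range: every template matches, ApEn = 0
  set.seed(6)
  x <- rnorm(100)
  expect_equal(approx_entropy(x, r_abs = diff(range(x)) + 1), 0)
  expect_error(approx_entropy(rep(1, 100)),
               class = "tremorkit_degenerate_error")
  expect_error(approx_entropy(rnorm(30)), class = "tremorkit_too_short_error")
  expect_gte(approx_entropy(rnorm(200)), 0)
})

test_that("ApEn orders signals by irregularity", {
  n <- 400
  t <- seq_len(n) / 51.2
  vals <- sapply(1:20, function(s) {
    set.seed(s)
    noise <- rnorm(n)
    sine <- sin(2 * pi * 3 * t)
    c(pure = approx_entropy(sine),
      mixed = approx_entropy(sine + 0.2 * sqrt(0.5) * rnorm(n)),
      noise = approx_entropy(noise))
  })
  med <- apply(vals, 1, median)
  expect_gt(med["mixed"] - med["pure"], 0.05)
  expect_gt(med["noise"] - med["mixed"], 0.05)
})

test_that("rms obeys its closed forms and scale equivariance", {
  t <- (0:511) / 51.2
  expect_equal(rms(2 * sin(2 * pi * 4 * t)), sqrt(2), tolerance = 1e-6)
  expect_equal(rms(c(3, 4)), sqrt(12.5), tolerance = 1e-12)
  expect_equal(rms(rep(0, 10)), 0)
  set.seed(8)
  x <- rnorm(100)
  for (c_ in c(-2.5, 0.3)) {
    expect_equal(rms(c_ * x), abs(c_) * rms(x), tolerance = 1e-12)
  }
  expect_error(rms(numeric(0)), class = "tremorkit_usage_error")
})

test_that("feature extraction recovers ground truth and averages trials", {
  # jitter-free tremor: dominant frequency within one bin; single-axis gyr
  # sinusoid: magnitude RMS = A / sqrt(2)
  fs <- 51.2
  rows <- lapply(1:3, function(tr) {
    rec <- simulate_trial(pure_tremor_spec(5, amp_gyr = 40, seed = tr),
                          task = "kinetic", geometry = axis_geometry,
                          meta = trial_metadata("S1", "PD", "right", "hand",
                                                "kinetic", tr, updrs21 = 1))
    preprocess_recording(rec)
  })
  trials <- dplyr::tibble(
    subject_id = "S1", group = "PD", side = "right", segment = "hand",
    task = "kinetic", trial = 1:3, updrs21 = 1L, recording = rows)
  tf <- trial_features(trials)
  expect_equal(nrow(tf), 6)  # 3 trials x {acc, gyr}
  L <- sum(!rows[[1]]$transient)
  expect_lt(max(abs(tf$f_dom - 5)), fs / L + 1e-9)
  gyr <- dplyr::filter(tf, signal == "gyr")
  # the high-pass passes 5 Hz with gain |H(5)|, so the magnitude RMS is
  # |H(5)| * A / sqrt(2) exactly; the unfiltered closed form holds to ~2%
  g5 <- highpass_gain(highpass_design(fs), 5)
  expect_equal(gyr$rms, rep(g5 * 40 / sqrt(2), 3), tolerance = 1e-3)
  expect_equal(gyr$rms, rep(40 / sqrt(2), 3), tolerance = 0.02)

  feats <- extract_features(tf)
  expect_equal(nrow(feats), 1)
  expect_equal(feats$n_trials, 3)
  # identical trials (same seed) average to the single-trial value
  same <- trials; same$recording <- rep(rows[1], 3)
  f_same <- extract_features(same)
  one <- extract_features(dplyr::slice(same, 1))
  expect_equal(f_same$rms_kin_gyr, one$rms_kin_gyr, tolerance = 1e-12)
  expect_equal(f_same$apen_kin_acc, one$apen_kin_acc, tolerance = 1e-12)
})

test_that("jitter-free tremor frequency is recovered across the band", {
  fs <- 51.2
  for (f0 in c(3, 5, 7)) {
    rec <- simulate_trial(pure_tremor_spec(f0, seed = 10 + f0), "postural",
                          geometry = axis_geometry)
    win <- analysis_window(preprocess_recording(rec))
    mat <- cbind(win$acc_x, win$acc_y, win$acc_z)
    dom <- tremorkit:::dom_freq_mat(mat, fs)
    expect_lt(abs(dom$f_dom - f0), fs / nrow(win) + 1e-9)
  }
})

test_that("per-axis mode analyses the dominant axis instead of the magnitude", {
  rec <- simulate_trial(pure_tremor_spec(5, amp_gyr = 40, seed = 3),
                        "postural", geometry = axis_geometry,
                        meta = trial_metadata("S1", "PD", "right", "hand",
                                              "postural", 1, updrs21 = 0))
  trials <- dplyr::tibble(subject_id = "S1", group = "PD", side = "right",
                          segment = "hand", task = "postural", trial = 1L,
                          updrs21 = 0L,
                          recording = list(preprocess_recording(rec)))
  tf <- trial_features(trials, per_axis = TRUE)
  gyr <- dplyr::filter(tf, signal == "gyr")
  expect_equal(gyr$axis, "y")
  # on a single-axis sinusoid the magnitude is the rectified axis: same RMS
  tf_mag <- trial_features(trials)
  expect_equal(gyr$rms, dplyr::filter(tf_mag, signal == "gyr")$rms,
               tolerance = 1e-9)
})
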