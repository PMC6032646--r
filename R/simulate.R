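#' Specification of one synthetic tremor signal
#'
#' Parameters of the generative model for a single trial. Each trial is the
#' sum of (i) a narrow-band tremor oscillation whose instantaneous frequency
#' performs a bounded random walk around `tremor_freq` and whose envelope is
#' smoothly modulated, (ii) for the kinetic (finger-to-nose) task a slow
#' voluntary-movement sinusoid below 1 Hz, (iii) on acceleration channels a
#' constant gravity vector, and (iv) white Gaussian sensor noise. The tremor
#' and voluntary components are distributed over the three axes by direction
#' cosines drawn once per trial.
#'
#' @param tremor_freq tremor centre frequency, Hz (must lie in (0, fs/2)).
#' @param tremor_amp_acc,tremor_amp_gyr tremor amplitude on the acceleration
#'   (m/s^2) and angular-velocity (deg/s) channels.
#' @param freq_jitter_sd standard deviation of the instantaneous-frequency
#'   random walk, Hz per sqrt(second); the walk is reflected at +/- 1.5 Hz
#'   around `tremor_freq`.
#' @param amp_mod_sd relative amplitude modulation depth (the envelope is
#'   `1 + amp_mod_sd * smooth noise`, floored at 0).
#' @param voluntary_freq voluntary-movement frequency, Hz (< 1 Hz so the
#'   1 Hz high-pass removes most of it).
#' @param voluntary_amp,voluntary_amp_gyr voluntary-movement amplitude on
#'   acceleration (m/s^2) and angular-velocity (deg/s) channels; applied in
#'   the kinetic task only.
#' @param gravity_vec length-3 gravity vector in m/s^2 (norm 9.80665).
#' @param noise_sd_acc,noise_sd_gyr white-noise standard deviations.
#' @param duration trial length in seconds.
#' @param seed integer seed; a trial is a pure function of its spec.
#'
#' @return A list of class `signal_spec`.
#' @export
signal_spec <- function(tremor_freq = 5, tremor_amp_acc = 1,
                        tremor_amp_gyr = 30, freq_jitter_sd = 0.3,
                        amp_mod_sd = 0.2, voluntary_freq = 0.4,
                        voluntary_amp = 2, voluntary_amp_gyr = 40,
                        gravity_vec = c(0, 0, STANDARD_GRAVITY),
                        noise_sd_acc = 0.05, noise_sd_gyr = 1.5,
                        duration = 30, seed = 1L) {
  spec <- list(
    tremor_freq = tremor_freq, tremor_amp_acc = tremor_amp_acc,
    tremor_amp_gyr = tremor_amp_gyr, freq_jitter_sd = freq_jitter_sd,
    amp_mod_sd = amp_mod_sd, voluntary_freq = voluntary_freq,
    voluntary_amp = voluntary_amp, voluntary_amp_gyr = voluntary_amp_gyr,
    gravity_vec = gravity_vec, noise_sd_acc = noise_sd_acc,
    noise_sd_gyr = noise_sd_gyr, duration = duration, seed = as.integer(seed)
  )
  validate_signal_spec(spec)
}

validate_signal_spec <- function(spec) {
  with(spec, {
    stopifnot(tremor_freq > 0, voluntary_freq > 0, duration > 0)
    if (voluntary_freq >= 1) {
      abort("voluntary_freq must be < 1 Hz (below the high-pass cut-off)",
            class = "tremorkit_spec_error")
    }
    amps <- c(tremor_amp_acc, tremor_amp_gyr, freq_jitter_sd, amp_mod_sd,
              voluntary_amp, voluntary_amp_gyr, noise_sd_acc, noise_sd_gyr)
    if (any(amps < 0)) {
      abort("amplitudes and standard deviations must be >= 0",
            class = "tremorkit_spec_error")
    }
    stopifnot(length(gravity_vec) == 3, all(is.finite(gravity_vec)))
  })
  structure(spec, class = "signal_spec")
}

#' Simulate one IMU trial
#'
#' Generates a fully reproducible [imu_recording()] from a [signal_spec()].
#' Acceleration channel i is
#' `gravity[i] + a_i * A(t) * sin(phase(t) + phi_i) + v_i * V(t) + noise`,
#' where `A(t)` is the smooth amplitude envelope, `phase(t)` integrates the
#' jittered instantaneous frequency, and the voluntary term `V(t)` is present
#' in the kinetic task only. Angular-velocity channels are analogous without
#' gravity. Direction cosines and per-axis phases are drawn once per trial.
#'
#' @param spec a [signal_spec()].
#' @param task `"kinetic"` or `"postural"`.
#' @param fs sampling rate, Hz.
#' @param meta optional [trial_metadata()] to attach.
#' @param geometry optional list overriding the per-trial random geometry,
#'   with any of `dir_acc`, `dir_gyr`, `dir_vol_acc`, `dir_vol_gyr`
#'   (length-3 direction vectors), `phi_acc`, `phi_gyr` (length-3 phases,
#'   rad) and `phi_vol` (scalar phase). Useful for constructing exactly
#'   known signals in tests and documentation.
#' @return An [imu_recording()].
#' @export
simulate_trial <- function(spec, task = c("kinetic", "postural"), fs = 51.2,
                           meta = NULL, geometry = NULL) {
  spec <- validate_signal_spec(spec)
  task <- match.arg(task)
  if (spec$tremor_freq >= fs / 2) {
    abort(sprintf("tremor_freq = %g Hz is at or above Nyquist (%g Hz)",
                  spec$tremor_freq, fs / 2),
          class = "tremorkit_aliasing_error")
  }
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  dt <- 1 / fs

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
    code
  }

  withr_seed({
    # per-trial geometry: unit direction vectors and per-axis phases
    geo <- list(dir_acc = unit_vec(rnorm(3)), dir_gyr = unit_vec(rnorm(3)),
                dir_vol_acc = unit_vec(rnorm(3)),
                dir_vol_gyr = unit_vec(rnorm(3)),
                phi_acc = runif(3, 0, 2 * pi), phi_gyr = runif(3, 0, 2 * pi),
                phi_vol = runif(1, 0, 2 * pi))
    if (!is.null(geometry)) geo <- modifyList(geo, geometry)
    dir_acc <- geo$dir_acc; dir_gyr <- geo$dir_gyr
    dir_vol_acc <- geo$dir_vol_acc; dir_vol_gyr <- geo$dir_vol_gyr
    phi_acc <- geo$phi_acc; phi_gyr <- geo$phi_gyr; phi_vol <- geo$phi_vol

    # instantaneous frequency: reflected random walk around tremor_freq
    devn <- reflected_walk(n, sd_step = spec$freq_jitter_sd * sqrt(dt),
                           bound = 1.5)
    f_inst <- spec$tremor_freq + devn
    phase <- 2 * pi * dt * (cumsum(f_inst) - f_inst[1])  # phase(0) = 0

    # smooth multiplicative envelope, unit-SD low-frequency noise
    env <- 1 + spec$amp_mod_sd * smooth_noise(n, fs)
    env <- pmax(env, 0)

    trem <- env * sin(outer(phase, phi_acc, "+"))      # n x 3, acc phases
    trem_g <- env * sin(outer(phase, phi_gyr, "+"))
    vol <- if (task == "kinetic") {
      sin(2 * pi * spec$voluntary_freq * t + phi_vol)
    } else rep(0, n)

    acc <- matrix(spec$gravity_vec, n, 3, byrow = TRUE) +
      spec$tremor_amp_acc * trem * matrix(dir_acc, n, 3, byrow = TRUE) +
      spec$voluntary_amp * vol * matrix(dir_vol_acc, n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, sd = spec$noise_sd_acc), n, 3)
    gyr <- spec$tremor_amp_gyr * trem_g * matrix(dir_gyr, n, 3, byrow = TRUE) +
      spec$voluntary_amp_gyr * vol * matrix(dir_vol_gyr, n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, sd = spec$noise_sd_gyr), n, 3)

    new_imu_recording(
      tibble(time = t, acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
             gyr_x = gyr[, 1], gyr_y = gyr[, 2], gyr_z = gyr[, 3]),
      fs = fs, meta = meta)
  })
}

unit_vec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) c(1, 0, 0) else v / nv
}

reflected_walk <- function(n, sd_step, bound) {
  if (sd_step == 0) return(rep(0, n))
  w <- cumsum(rnorm(n, sd = sd_step))
  # reflect into [-bound, bound] (fold the line at the boundaries)
  w <- abs((w + bound) %% (4 * bound) - 2 * bound) - bound
  w
}

smooth_noise <- function(n, fs, tau = 1) {
  # white noise smoothed by a ~tau-second moving average, rescaled to SD 1
  if (n < 4) return(rep(0, n))
  k <- max(3, round(tau * fs))
  z <- rnorm(n + k)
  sm <- as.numeric(stats::filter(z, rep(1 / k, k), sides = 1))
  sm <- sm[(k + 1):(k + n)]
  s <- sd(sm)
  if (!is.finite(s) || s == 0) rep(0, n) else (sm - mean(sm)) / s
}

# Deterministic seed derivation: Lehmer step on the parent seed plus a
# stream index, kept inside [1, 2^31 - 2].
child_seed <- function(parent, index) {
  m <- 2147483647
  as.integer((as.numeric(parent) %% m * 48271 + as.numeric(index) * 8191) %% m + 1)
}

#' Group presets and cohort specification
#'
#' `preset_signal()` returns the package's default generative parameters for
#' a patient (`"pd"`) or control (`"co"`) subject side. Both groups share
#' the slow voluntary movement of the finger-to-nose task; patients differ
#' by a much larger tremor amplitude and by more irregular oscillation
#' (larger frequency jitter, amplitude modulation and broadband motor
#' noise). Controls' recordings are dominated by the smooth voluntary
#' component plus a small fast tremor, so their magnitude series are
#' regular (low ApEn) and of low intensity (low RMS); patients' strong
#' irregular tremor raises both. `cohort_spec()` bundles group
#' sizes and between-subject variability into a reproducible cohort recipe;
#' per-(subject, side) parameters are drawn from Gaussians centred on the
#' preset values, truncated at zero where negative values are meaningless.
#'
#' @param group `"pd"` or `"co"`.
#' @return `preset_signal()`: a [signal_spec()]; `cohort_spec()`: a list of
#'   class `cohort_spec`.
#' @export
preset_signal <- function(group = c("pd", "co")) {
  group <- match.arg(group)
  if (group == "pd") {
    signal_spec(tremor_freq = 5, tremor_amp_acc = 1.0, tremor_amp_gyr = 30,
                freq_jitter_sd = 0.6, amp_mod_sd = 0.35,
                noise_sd_acc = 0.12, noise_sd_gyr = 2.5)
  } else {
    signal_spec(tremor_freq = 5.5, tremor_amp_acc = 0.15, tremor_amp_gyr = 4,
                freq_jitter_sd = 0.15, amp_mod_sd = 0.10,
                noise_sd_acc = 0.04, noise_sd_gyr = 0.8)
  }
}

#' @rdname preset_signal
#' @param n_pd,n_co subject counts (each >= 2); defaults mirror a typical
#'   clinic cohort of 19 patients and 12 controls.
#' @param pd,co [signal_spec()] presets giving each group's parameter means.
#' @param between_sd relative between-subject (and between-side) SD applied
#'   to the amplitude and irregularity parameters.
#' @param freq_sd absolute between-subject SD of the tremor frequency, Hz.
#' @param updrs_threshold angular-velocity tremor amplitude (deg/s) above
#'   which a PD side is scored 1 on UPDRS item 21, else 0.
#' @param duration trial length, seconds.
#' @param master_seed integer master seed; the whole cohort (parameters and
#'   recordings) is a pure function of it.
#' @export
cohort_spec <- function(n_pd = 19, n_co = 12, pd = preset_signal("pd"),
                        co = preset_signal("co"), between_sd = 0.25,
                        freq_sd = 1, updrs_threshold = 36,
                        duration = 30, master_seed = 1L) {
  if (n_pd < 2 || n_co < 2) {
    abort("n_pd and n_co must each be >= 2", class = "tremorkit_spec_error")
  }
  # PD means must not be smaller than CO (equality permitted so that
  # identical presets can serve as a pure-null calibration cohort)
  if (pd$tremor_amp_gyr < co$tremor_amp_gyr ||
      pd$tremor_amp_acc < co$tremor_amp_acc ||
      pd$freq_jitter_sd < co$freq_jitter_sd ||
      pd$amp_mod_sd < co$amp_mod_sd) {
    abort("PD preset must have at least as large tremor amplitude and irregularity as CO",
          class = "tremorkit_spec_error")
  }
  structure(list(n_pd = as.integer(n_pd), n_co = as.integer(n_co),
                 pd = pd, co = co, between_sd = between_sd, freq_sd = freq_sd,
                 updrs_threshold = updrs_threshold, duration = duration,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

draw_subject_params <- function(base, between_sd, freq_sd, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  jit <- function(x) max(x * (1 + rnorm(1, sd = between_sd)), 0.05 * x)
  base$tremor_freq <- min(max(base$tremor_freq + rnorm(1, sd = freq_sd), 1.5), 12)
  base$tremor_amp_acc <- jit(base$tremor_amp_acc)
  base$tremor_amp_gyr <- jit(base$tremor_amp_gyr)
  base$freq_jitter_sd <- jit(base$freq_jitter_sd)
  base$amp_mod_sd <- jit(base$amp_mod_sd)
  base
}

#' Simulate a full cohort of IMU trials
#'
#' Draws per-(subject, side) generative parameters from the group presets,
#' assigns the per-side clinical score by amplitude threshold, and simulates
#' every requested trial. Parameter draws are seeded per (subject, side)
#' independently of which tasks/segments/sides are simulated, so a subset
#' cohort shares its ground truth with the full factorial.
#'
#' @param cohort a [cohort_spec()].
#' @param fs sampling rate, Hz.
#' @param sides,segments,tasks,trials factors to simulate; defaults give the
#'   full design (2 sides x 3 segments x 2 tasks x 3 trials per subject).
#' @return A list of class `imu_cohort` with elements `trials` (tibble, one
#'   row per recording: metadata columns plus a `recording` list-column) and
#'   `truth` (tibble of the drawn per-(subject, side) parameters).
#' @export
simulate_cohort <- function(cohort, fs = 51.2,
                            sides = c("left", "right"),
                            segments = c("upper_arm", "forearm", "hand"),
                            tasks = c("kinetic", "postural"),
                            trials = 1:3) {
  stopifnot(inherits(cohort, "cohort_spec"))
  subjects <- tibble(
    subject_id = c(sprintf("PD%02d", seq_len(cohort$n_pd)),
                   sprintf("CO%02d", seq_len(cohort$n_co))),
    group = rep(c("PD", "CO"), c(cohort$n_pd, cohort$n_co)),
    subj_index = seq_len(cohort$n_pd + cohort$n_co)
  )

  # ground truth: one parameter draw per (subject, side)
  truth <- purrr::pmap_dfr(subjects, function(subject_id, group, subj_index) {
    purrr::map_dfr(c("left", "right"), function(side) {
      side_index <- if (side == "left") 1L else 2L
      seed <- child_seed(cohort$master_seed, subj_index * 64L + side_index)
      base <- if (group == "PD") cohort$pd else cohort$co
      p <- draw_subject_params(base, cohort$between_sd, cohort$freq_sd, seed)
      tibble(subject_id = subject_id, group = group, side = side,
             tremor_freq = p$tremor_freq,
             tremor_amp_acc = p$tremor_amp_acc,
             tremor_amp_gyr = p$tremor_amp_gyr,
             freq_jitter_sd = p$freq_jitter_sd, amp_mod_sd = p$amp_mod_sd,
             updrs21 = if (group == "PD") {
               as.integer(p$tremor_amp_gyr > cohort$updrs_threshold)
             } else NA_integer_,
             param_seed = seed)
    })
  })

  design <- tidyr::expand_grid(
    subjects, side = sides, segment = segments, task = tasks, trial = trials
  ) %>%
    left_join(truth %>% select("subject_id", "side", "tremor_freq",
                               "tremor_amp_acc", "tremor_amp_gyr",
                               "freq_jitter_sd", "amp_mod_sd", "updrs21"),
              by = c("subject_id", "side"))

  # distal segments tremble more; fixed attenuation towards the shoulder
  seg_scale <- c(upper_arm = 0.45, forearm = 0.7, hand = 1)

  rows <- purrr::pmap(design, function(subject_id, group, subj_index, side,
                                       segment, task, trial, tremor_freq,
                                       tremor_amp_acc, tremor_amp_gyr,
                                       freq_jitter_sd, amp_mod_sd, updrs21) {
    side_index <- if (side == "left") 1L else 2L
    seg_index <- match(segment, names(seg_scale))
    task_index <- if (task == "kinetic") 1L else 2L
    stream <- (((subj_index * 2L + side_index) * 4L + seg_index) * 3L +
                 task_index) * 4L + trial
    spec <- if (group == "PD") cohort$pd else cohort$co
    spec$tremor_freq <- tremor_freq
    spec$tremor_amp_acc <- tremor_amp_acc * seg_scale[[segment]]
    spec$tremor_amp_gyr <- tremor_amp_gyr * seg_scale[[segment]]
    spec$freq_jitter_sd <- freq_jitter_sd
    spec$amp_mod_sd <- amp_mod_sd
    spec$duration <- cohort$duration
    spec$seed <- child_seed(cohort$master_seed, stream)
    meta <- trial_metadata(subject_id, group, side, segment, task, trial,
                           updrs21 = updrs21)
    simulate_trial(spec, task = task, fs = fs, meta = meta)
  })

  trials_tbl <- design %>%
    select("subject_id", "group", "side", "segment", "task", "trial",
           "updrs21") %>%
    mutate(recording = rows)
  structure(list(trials = trials_tbl, truth = truth, fs = fs, spec = cohort),
            class = "imu_cohort")
}

#' @export
print.imu_cohort <- function(x, ...) {
  cat(sprintf("<imu_cohort: %d recordings, %d subjects (%d PD / %d CO), fs = %g Hz>\n",
              nrow(x$trials), length(unique(x$trials$subject_id)),
              x$spec$n_pd, x$spec$n_co, x$fs))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one recording CSV per trial plus `metadata.csv` and
#' `ground_truth.csv` into `dir`.
#'
#' @param cohort an `imu_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "imu_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- cohort$trials
  paths <- sprintf("%s/%s_%s_%s_%s_t%d.csv", dir, tr$subject_id, tr$side,
                   tr$segment, tr$task, tr$trial)
  purrr::walk2(tr$recording, paths, write_imu_csv)
  readr::write_csv(tr %>% select(-"recording"), file.path(dir, "metadata.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing recording CSVs and `metadata.csv`.
#' @return An `imu_cohort` list (with `truth = NULL` if no ground-truth file
#'   is present).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) {
    abort(paste0("cohort directory not found: ", dir),
          class = "tremorkit_io_error")
  }
  files <- sort(setdiff(list.files(dir, pattern = "\\.csv$", full.names = TRUE),
                        file.path(dir, c("metadata.csv", "ground_truth.csv"))))
  if (length(files) == 0) {
    abort("no recording files in cohort directory",
          class = "tremorkit_io_error")
  }
  recs <- purrr::map(files, read_imu_csv)
  meta <- purrr::map_dfr(recs, rec_meta)
  trials_tbl <- meta %>% mutate(recording = recs)
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  fs <- rec_fs(recs[[1]])
  n_pd <- length(unique(meta$subject_id[meta$group == "PD"]))
  n_co <- length(unique(meta$subject_id[meta$group == "CO"]))
  structure(list(trials = trials_tbl, truth = truth, fs = fs,
                 spec = list(n_pd = n_pd, n_co = n_co)),
            class = "imu_cohort")
}
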