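#' Configuration for the synthetic EMG+ECG mixture simulator
#'
#' The simulator emulates the three recording conditions the detector is
#' meant to operate under: quiet standing (`rest`, low sustained muscle
#' noise), a held contraction (`static`, moderate sustained noise with slow
#' amplitude drift), and repetitive exercise (`dynamic`, bursts of high
#' muscle noise at the repetition rate). A QRS-like biphasic template train
#' with respiratory rate modulation supplies the cardiac component and the
#' ground-truth apex indices.
#'
#' Default muscle-noise levels (`emg_rms`, relative to the default R-wave
#' amplitude `qrs_amp = 1`) are 0.1 / 0.5 / 1.0 for rest / static / dynamic.
#' These are calibration conventions of the simulator — chosen so that rest
#' is near-clean, static is a moderate sustained contamination, and dynamic
#' bursts rival the R-wave in amplitude — not measurements of any particular
#' hardware.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param rr_mean_s,rr_sd_s Mean and SD of the R-R interval (seconds).
#' @param resp_mod_depth Fractional respiratory modulation of the R-R
#'   interval (0.25 Hz carrier), in `[0, 1)`.
#' @param qrs_width_s Total width of the QRS-like template (seconds).
#' @param qrs_amp Apex amplitude of the template (arbitrary units).
#' @param emg_band_hz Length-2 passband (Hz) of the muscle noise. Upper edge
#'   must stay below `fs / 2`.
#' @param emg_rms Target RMS of the muscle noise before the condition
#'   envelope is applied. `NULL` picks the per-condition default.
#' @param condition `"rest"`, `"static"` or `"dynamic"`.
#' @param burst_rate_hz Exercise repetition rate for `dynamic` bursts.
#' @param ectopic_prob Per-beat probability of a premature (ectopic) beat:
#'   the interval is shortened to 0.6 of its drawn value and followed by a
#'   1.3x compensatory interval. Must lie in `[0, 0.5)`.
#' @param subject_id Label stamped on simulated recordings.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration_s = 40, fs = 500,
                       rr_mean_s = 0.8, rr_sd_s = 0.05,
                       resp_mod_depth = 0.05,
                       qrs_width_s = 0.08, qrs_amp = 1,
                       emg_band_hz = c(20, 150), emg_rms = NULL,
                       condition = c("rest", "static", "dynamic"),
                       burst_rate_hz = 0.5, ectopic_prob = 0,
                       subject_id = "S1", seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(emg_rms)) {
    emg_rms <- c(rest = 0.1, static = 0.5, dynamic = 1.0)[[condition]]
  }
  cfg <- list(
    duration_s = duration_s, fs = fs, rr_mean_s = rr_mean_s,
    rr_sd_s = rr_sd_s, resp_mod_depth = resp_mod_depth,
    qrs_width_s = qrs_width_s, qrs_amp = qrs_amp,
    emg_band_hz = as.numeric(emg_band_hz), emg_rms = emg_rms,
    condition = condition, burst_rate_hz = burst_rate_hz,
    ectopic_prob = ectopic_prob, subject_id = subject_id,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$fs <= 0 || cfg$duration_s <= 0) {
    stop("`fs` and `duration_s` must be positive.", call. = FALSE)
  }
  if (cfg$rr_mean_s <= 3 * cfg$rr_sd_s) {
    stop("`rr_mean_s` must exceed 3 * `rr_sd_s` (intervals must stay positive).",
         call. = FALSE)
  }
  if (cfg$qrs_width_s * cfg$fs < 5) {
    stop("`qrs_width_s` must span at least 5 samples at `fs`.", call. = FALSE)
  }
  if (cfg$emg_rms < 0) stop("`emg_rms` must be >= 0.", call. = FALSE)
  if (cfg$ectopic_prob < 0 || cfg$ectopic_prob >= 0.5) {
    stop("`ectopic_prob` must lie in [0, 0.5).", call. = FALSE)
  }
  if (cfg$resp_mod_depth < 0 || cfg$resp_mod_depth >= 1) {
    stop("`resp_mod_depth` must lie in [0, 1).", call. = FALSE)
  }
  if (length(cfg$emg_band_hz) != 2 || cfg$emg_band_hz[1] <= 0 ||
      cfg$emg_band_hz[2] <= cfg$emg_band_hz[1]) {
    stop("`emg_band_hz` must be an increasing positive pair.", call. = FALSE)
  }
  if (cfg$emg_band_hz[2] >= cfg$fs / 2) {
    stop("`emg_band_hz` upper edge must be below fs/2 (Nyquist).",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a beat-time train with respiratory modulation and ectopy
#'
#' Beat times start one interval after t = 0. Each interval is drawn as
#' `rr_mean_s * (1 + resp_mod_depth * sin(2 * pi * 0.25 * t)) + N(0, rr_sd_s)`;
#' with probability `ectopic_prob` an interval is shortened to 0.6x its drawn
#' value and the following interval lengthened 1.3x (compensatory pause).
#' Intervals are floored at `0.25 * rr_mean_s` so beat times stay strictly
#' increasing. Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of beat times (seconds), possibly empty.
#' @export
simulate_rr_train <- function(config) {
  validate_sim_config(config)
  withr_seed(derive_seed(config$seed, "rr"))
  t <- 0
  beats <- numeric(0)
  pending_comp <- FALSE
  repeat {
    base <- config$rr_mean_s *
      (1 + config$resp_mod_depth * sin(2 * pi * 0.25 * t))
    interval <- base + rnorm(1, 0, config$rr_sd_s)
    if (config$ectopic_prob > 0 && runif(1) < config$ectopic_prob) {
      # premature beat; the compensatory pause is applied to the next
      # non-ectopic interval
      interval <- interval * 0.6
      pending_comp <- TRUE
    } else if (pending_comp) {
      interval <- interval * 1.3
      pending_comp <- FALSE
    }
    interval <- max(interval, 0.25 * config$rr_mean_s)
    if (t + interval >= config$duration_s) break
    t <- t + interval
    beats <- c(beats, t)
  }
  beats
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
withr_seed <- function(seed) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    restore <- substitute(assign(".Random.seed", o, envir = globalenv()),
                          list(o = old))
    do.call(on.exit, list(restore, add = TRUE), envir = parent.frame())
  }
  set.seed(seed)
  invisible(NULL)
}

# Biphasic QRS-like template: negated second derivative of a Gaussian
# (Ricker wavelet), apex-normalized. Total support = width_s.
qrs_template <- function(width_s, fs, amp) {
  half <- round(width_s * fs / 2)
  tt <- seq(-half, half) / fs
  sigma <- width_s / 6
  shape <- (1 - (tt / sigma)^2) * exp(-tt^2 / (2 * sigma^2))
  amp * shape / max(shape)
}

#' Render the cardiac component of a recording
#'
#' Each beat contributes one QRS-like biphasic template (negated second
#' derivative of a Gaussian, total width `qrs_width_s`, apex `qrs_amp`)
#' centered at the beat time. Overlapping templates (R-R shorter than the
#' template width) are summed with a warning.
#'
#' @param beat_times Beat times in seconds, within `[0, duration_s)`.
#' @param config A [sim_config()].
#' @return List with `samples` (length `round(duration_s * fs)`) and `peaks`
#'   (0-based apex indices, one per rendered beat).
#' @export
render_ecg <- function(beat_times, config) {
  validate_sim_config(config)
  n <- round(config$duration_s * config$fs)
  sig <- numeric(n)
  tmpl <- qrs_template(config$qrs_width_s, config$fs, config$qrs_amp)
  half <- (length(tmpl) - 1) / 2
  apexes <- integer(0)
  if (length(beat_times) >= 2 &&
      any(diff(beat_times) < config$qrs_width_s)) {
    warning("R-R interval shorter than the QRS template width; templates overlap.")
  }
  for (bt in beat_times) {
    center <- round(bt * config$fs)        # 0-based apex index
    if (center < 0 || center >= n) next
    lo <- center - half
    hi <- center + half
    t_lo <- max(lo, 0)
    t_hi <- min(hi, n - 1)
    sig[(t_lo + 1):(t_hi + 1)] <- sig[(t_lo + 1):(t_hi + 1)] +
      tmpl[(t_lo - lo + 1):(t_hi - lo + 1)]
    apexes <- c(apexes, center)
  }
  list(samples = sig, peaks = as.integer(apexes))
}

#' Render the skeletal-muscle noise component
#'
#' Gaussian white noise band-pass filtered to `emg_band_hz` (4th-order
#' Butterworth, zero-phase), scaled to RMS `emg_rms`, then shaped by the
#' condition envelope: constant for `rest`; slow (0.5 Hz, +/-20%) sinusoidal
#' modulation for `static`; raised-cosine bursts at `burst_rate_hz` with 50%
#' duty cycle for `dynamic`. Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @export
render_emg <- function(config) {
  validate_sim_config(config)
  n <- round(config$duration_s * config$fs)
  if (config$emg_rms == 0) return(numeric(n))
  withr_seed(derive_seed(config$seed, "emg"))
  noise <- rnorm(n)
  bf <- signal::butter(4, config$emg_band_hz / (config$fs / 2),
                       type = "pass")
  noise <- signal::filtfilt(bf, noise)
  noise <- noise * config$emg_rms / sqrt(mean(noise^2))
  tt <- (seq_len(n) - 1) / config$fs
  env <- switch(config$condition,
    rest = rep(1, n),
    static = 1 + 0.2 * sin(2 * pi * 0.5 * tt),
    dynamic = {
      phase <- (tt * config$burst_rate_hz) %% 1
      ifelse(phase < 0.5, 0.5 * (1 - cos(2 * pi * phase / 0.5)), 0)
    }
  )
  noise * env
}

#' Simulate one annotated EMG+ECG recording
#'
#' Sum of [render_ecg()] over a [simulate_rr_train()] beat train and
#' [render_emg()] muscle noise, with the ECG apex indices as ground-truth
#' peaks. Bit-reproducible given the config (including seed).
#'
#' @param config A [sim_config()].
#' @return An annotated [recording()].
#' @export
simulate_recording <- function(config) {
  validate_sim_config(config)
  beats <- simulate_rr_train(config)
  ecg <- render_ecg(beats, config)
  emg <- render_emg(config)
  recording(ecg$samples + emg, fs = config$fs,
            subject_id = config$subject_id, condition = config$condition,
            peaks = ecg$peaks)
}

#' Simulate a multi-subject cohort across recording conditions
#'
#' Per subject, one random draw perturbs the R-wave amplitude and the
#' muscle-noise RMS by up to +/-20% (uniform), so that leave-one-subject-out
#' evaluation is a meaningful generalization test: held-out subjects differ
#' from the training subjects in signal scale. Every recording carries its
#' `subject_id` and `condition`.
#'
#' @param n_subjects Number of subjects (>= 2; leave-one-subject-out is
#'   undefined otherwise).
#' @param per_condition_recordings Recordings per subject and condition.
#' @param base_config A [sim_config()]; its `emg_rms` is ignored in favour of
#'   the per-condition defaults unless `emg_rms_by_condition` is supplied.
#' @param conditions Conditions to simulate for each subject.
#' @param emg_rms_by_condition Optional named numeric vector overriding the
#'   per-condition muscle-noise RMS.
#' @return A tibble with columns `subject_id`, `condition`, `recording`
#'   (list-column of annotated [recording()] objects).
#' @export
simulate_cohort <- function(n_subjects = 6, per_condition_recordings = 1,
                            base_config = sim_config(),
                            conditions = c("rest", "static", "dynamic"),
                            emg_rms_by_condition = NULL) {
  if (n_subjects < 2) {
    stop("`n_subjects` must be >= 2 (leave-one-subject-out is undefined for one subject).",
         call. = FALSE)
  }
  conditions <- match.arg(conditions, several.ok = TRUE)
  default_rms <- c(rest = 0.1, static = 0.5, dynamic = 1.0)
  if (!is.null(emg_rms_by_condition)) {
    default_rms[names(emg_rms_by_condition)] <- emg_rms_by_condition
  }
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%d", s)
    withr_seed(derive_seed(base_config$seed, "subject", s))
    amp_scale <- runif(1, 0.8, 1.2)
    rms_scale <- runif(1, 0.8, 1.2)
    for (cond in conditions) {
      for (r in seq_len(per_condition_recordings)) {
        cfg <- base_config
        cfg$subject_id <- sid
        cfg$condition <- cond
        cfg$qrs_amp <- base_config$qrs_amp * amp_scale
        cfg$emg_rms <- default_rms[[cond]] * rms_scale
        cfg$seed <- derive_seed(base_config$seed, sid, cond, r)
        class(cfg) <- "sim_config"
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = sid, condition = cond,
          recording = list(simulate_recording(cfg)),
          qrs_amp = cfg$qrs_amp, emg_rms = cfg$emg_rms
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
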