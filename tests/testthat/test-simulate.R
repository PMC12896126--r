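test_that("noise-free beat train is exactly periodic", {
  cfg <- sim_config(duration_s = 4, rr_mean_s = 0.8, rr_sd_s = 0,
                    resp_mod_depth = 0, ectopic_prob = 0)
  beats <- simulate_rr_train(cfg)
  expect_equal(beats, c(0.8, 1.6, 2.4, 3.2), tolerance = 1e-9)
})

test_that("mean R-R interval converges to rr_mean_s", {
  cfg <- sim_config(duration_s = 60, seed = 5)
  rr <- diff(simulate_rr_train(cfg))
  se <- sd(rr) / sqrt(length(rr))
  expect_lt(abs(mean(rr) - 0.8), 3 * se + 1e-6)
})

test_that("ectopic beats appear at the configured rate", {
  cfg <- sim_config(duration_s = 300, ectopic_prob = 0.2, seed = 17)
  rr <- diff(simulate_rr_train(cfg))
  short <- sum(rr < 0.7 * cfg$rr_mean_s)
  ci <- stats::qbinom(c(0.005, 0.995), length(rr), 0.2)
  expect_gte(short, ci[1])
  expect_lte(short, ci[2])
})

test_that("beat trains are deterministic and too-short durations give no beats", {
  cfg <- sim_config(duration_s = 20, seed = 33)
  expect_identical(simulate_rr_train(cfg), simulate_rr_train(cfg))
  expect_length(simulate_rr_train(sim_config(duration_s = 0.5)), 0)
})

test_that("rendered ECG places one apex-normalized template per beat", {
  cfg <- sim_config(duration_s = 3, emg_rms = 0)
  ecg <- render_ecg(1.0, cfg)
  expect_identical(ecg$peaks, 500L)
  expect_equal(which.max(ecg$samples) - 1L, 500L)
  expect_equal(max(ecg$samples), cfg$qrs_amp, tolerance = 1e-9)
  # zero beats -> silence
  silent <- render_ecg(numeric(0), cfg)
  expect_identical(silent$samples, numeric(1500))
  expect_length(silent$peaks, 0)
})

test_that("non-overlapping beats give exactly N supra-half-amplitude maxima", {
  cfg <- sim_config(duration_s = 10, emg_rms = 0)
  beats <- seq(0.5, 9.5, by = 0.75)
  ecg <- render_ecg(beats, cfg)
  x <- ecg$samples
  n <- length(x)
  is_max <- x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
    x[2:(n - 1)] > cfg$qrs_amp / 2
  expect_equal(sum(is_max), length(beats))
  # every emitted peak is a local maximum of the pure cardiac component
  for (p in ecg$peaks) {
    expect_equal(which.max(x[p:(p + 2)]), 2)  # 0-based p-1 .. p+1
  }
})

test_that("overlapping templates warn", {
  cfg <- sim_config(duration_s = 2, emg_rms = 0)
  expect_warning(render_ecg(c(1.0, 1.05), cfg), "overlap")
})

test_that("muscle noise hits its target RMS and respects the condition envelope", {
  expect_identical(render_emg(sim_config(duration_s = 2, emg_rms = 0)),
                   numeric(1000))
  cfg <- sim_config(duration_s = 60, emg_rms = 0.1, seed = 9)
  x <- render_emg(cfg)
  expect_gt(sqrt(mean(x^2)), 0.09)
  expect_lt(sqrt(mean(x^2)), 0.11)
  # dynamic bursts: in-burst RMS dwarfs between-burst RMS
  dcfg <- sim_config(duration_s = 20, condition = "dynamic", seed = 9)
  xd <- render_emg(dcfg)
  phase <- (((seq_along(xd) - 1) / dcfg$fs) * dcfg$burst_rate_hz) %% 1
  rms_in <- sqrt(mean(xd[phase >= 0.1 & phase < 0.4]^2))
  rms_out <- sqrt(mean(xd[phase >= 0.6 & phase < 0.9]^2))
  expect_gt(rms_in, 2 * rms_out)
  expect_error(render_emg(sim_config(emg_band_hz = c(20, 300))), "Nyquist")
})

test_that("simulated recordings are reproducible and peaks recoverable", {
  cfg <- sim_config(duration_s = 20, emg_rms = 0, rr_sd_s = 0, seed = 3)
  rec <- simulate_recording(cfg)
  rec2 <- simulate_recording(cfg)
  expect_identical(rec$samples, rec2$samples)
  expect_identical(rec$peaks, rec2$peaks)
  # noise-free: argmax in each window around a peak is the peak itself
  for (p in rec$peaks) {
    lo <- max(p - 10, 0); hi <- min(p + 10, length(rec$samples) - 1)
    expect_equal(lo + which.max(rec$samples[(lo + 1):(hi + 1)]) - 1L, p)
  }
  # different seed, same invariants, different values (in the stochastic
  # parts: muscle noise and interval jitter)
  noisy3 <- simulate_recording(sim_config(duration_s = 20, seed = 3))
  noisy4 <- simulate_recording(sim_config(duration_s = 20, seed = 4))
  expect_false(identical(noisy3$samples, noisy4$samples))
  expect_true(all(diff(noisy4$peaks) > 0))
})

test_that("a naive threshold detector recovers nearly all rest-condition peaks", {
  rec <- simulate_recording(sim_config(duration_s = 60, seed = 8))
  # 5-sample moving average suppresses apex jitter from in-band noise
  x <- as.vector(stats::filter(rec$samples, rep(1 / 5, 5), sides = 2))
  x[is.na(x)] <- 0
  above <- x > 0.5
  runs <- rle(above)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  detected <- integer(0)
  for (k in which(runs$values)) {
    seg <- starts[k]:ends[k]
    detected <- c(detected, seg[which.max(x[seg])] - 1L)
  }
  hits <- vapply(rec$peaks, function(p) any(abs(detected - p) <= 2),
                 logical(1))
  expect_gte(mean(hits), 0.99)
  expect_lte(length(detected), length(rec$peaks) * 1.05)
})

test_that("cohort structure matches the requested design", {
  cohort <- cached("small_cohort",
                   simulate_cohort(6, 1, sim_config(duration_s = 8,
                                                    seed = 13)))
  expect_equal(nrow(cohort), 18)
  expect_length(unique(cohort$subject_id), 6)
  expect_equal(as.integer(table(cohort$condition)), rep(6L, 3))
  # subject-level amplitude perturbations stay within +/-20%
  expect_true(all(cohort$qrs_amp >= 0.8 & cohort$qrs_amp <= 1.2))
  rest <- dplyr::filter(cohort, condition == "rest")
  expect_true(all(rest$emg_rms >= 0.08 & rest$emg_rms <= 0.12))
  # deterministic under the same base seed
  again <- simulate_cohort(6, 1, sim_config(duration_s = 8, seed = 13))
  expect_identical(cohort$recording[[7]]$samples,
                   again$recording[[7]]$samples)
  expect_error(simulate_cohort(1, 1, sim_config()), "at least|>= 2|undefined")
})

test_that("default condition noise levels are ordered rest < static <= dynamic bursts", {
  rms_of <- function(cond) {
    x <- render_emg(sim_config(duration_s = 30, condition = cond,
                               seed = 2))
    x
  }
  rest <- rms_of("rest"); static <- rms_of("static"); dyn <- rms_of("dynamic")
  fs <- 500
  phase <- (((seq_along(dyn) - 1) / fs) * 0.5) %% 1
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(rest), rms(static))
  expect_lte(rms(static), rms(dyn[phase < 0.5]))
})
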