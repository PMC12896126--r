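#' Build a rhythmogram (R-R interval series) from detected events
#'
#' Converts per-window detection events to global apex times and takes
#' successive differences. Apexes closer than the refractory `merge_window_s`
#' (default 0.2 s, a 300-bpm physiological ceiling) are treated as duplicate
#' detections of one beat and merged, keeping the apex with the higher
#' response.
#'
#' @param events A tibble of events with 0-based `apex` indices — either
#'   global (then `window_offsets` is ignored) or window-local with a
#'   `window` column and `window_offsets[window]` giving each window's
#'   0-based start sample. An optional `response` column (apex height)
#'   breaks merge conflicts.
#' @param window_offsets Integer vector of window start offsets, or `NULL`
#'   when `events$apex` is already global.
#' @param fs Sampling rate in Hz.
#' @param merge_window_s Refractory merge window in seconds.
#' @return A `rhythmogram`: list with `apex_times_s`, `rr_intervals_s`,
#'   `hr_bpm` and `fs`. Fewer than two apexes give an empty interval series
#'   with a warning.
#' @export
build_rhythmogram <- function(events, window_offsets = NULL, fs = 500,
                              merge_window_s = 0.2) {
  stopifnot(fs > 0)
  if (nrow(events) == 0) {
    warning("No detection events: empty rhythmogram.")
    return(new_rhythmogram(numeric(0), fs))
  }
  apex <- events$apex
  if (!is.null(window_offsets)) {
    stopifnot("window" %in% names(events))
    apex <- apex + window_offsets[events$window]
  }
  response <- events[["response"]] %||% rep(0, length(apex))
  ord <- order(apex)
  apex <- apex[ord]; response <- response[ord]
  times <- apex / fs
  # refractory merge: scan left to right, keep the stronger of any pair
  # closer than merge_window_s
  keep_t <- numeric(0); keep_r <- numeric(0)
  for (i in seq_along(times)) {
    if (length(keep_t) > 0 &&
        times[i] - keep_t[length(keep_t)] < merge_window_s) {
      if (response[i] > keep_r[length(keep_r)]) {
        keep_t[length(keep_t)] <- times[i]
        keep_r[length(keep_r)] <- response[i]
      }
    } else {
      keep_t <- c(keep_t, times[i])
      keep_r <- c(keep_r, response[i])
    }
  }
  if (length(keep_t) < 2) {
    warning("Fewer than two beats detected: empty R-R interval series.")
  }
  new_rhythmogram(keep_t, fs)
}

new_rhythmogram <- function(apex_times_s, fs) {
  rr <- diff(apex_times_s)
  structure(
    list(apex_times_s = apex_times_s, rr_intervals_s = rr,
         hr_bpm = if (length(rr)) 60 / rr else numeric(0), fs = fs),
    class = "rhythmogram"
  )
}

#' @export
print.rhythmogram <- function(x, ...) {
  cat(sprintf(
    "<rhythmogram> %d beats, %d R-R intervals%s\n",
    length(x$apex_times_s), length(x$rr_intervals_s),
    if (length(x$rr_intervals_s))
      sprintf(", mean RR %.3f s (%.1f bpm)", mean(x$rr_intervals_s),
              60 / mean(x$rr_intervals_s))
    else ""
  ))
  invisible(x)
}

#' @method tidy rhythmogram
#' @export
tidy.rhythmogram <- function(x, ...) {
  n <- length(x$rr_intervals_s)
  tibble::tibble(
    beat = seq_len(n),
    t_start_s = x$apex_times_s[seq_len(n)],
    t_end_s = x$apex_times_s[seq_len(n) + 1],
    rr_s = x$rr_intervals_s,
    hr_bpm = x$hr_bpm
  )
}

#' Heart-rate-variability summary with tachycardia/bradycardia flags
#'
#' Computes the standard time-domain statistics — mean R-R, SDNN (standard
#' deviation of intervals), RMSSD (root mean square of successive interval
#' differences), mean heart rate — and flags every maximal run of at least
#' `min_run` consecutive intervals whose instantaneous heart rate exceeds
#' `tachy_bpm` (tachycardia) or falls below `brady_bpm` (bradycardia).
#' Thresholds default to the conventional clinical cutoffs of 100 and
#' 60 bpm. Dispersion statistics require at least two intervals; with
#' fewer, the summary carries `NA` statistics and no flags.
#'
#' @param r A [build_rhythmogram()] result.
#' @param tachy_bpm,brady_bpm Episode thresholds in beats per minute.
#' @param min_run Minimum number of consecutive intervals for a flag.
#' @return An `hrv_summary`: list with the statistics and a `flags` tibble
#'   (`start_s`, `end_s`, `type`). [tidy()] returns a one-row tibble.
#' @export
hrv_summary <- function(r, tachy_bpm = 100, brady_bpm = 60, min_run = 3) {
  stopifnot(inherits(r, "rhythmogram"))
  rr <- r$rr_intervals_s
  flags <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                          type = character())
  if (length(rr) < 2) {
    return(structure(
      list(mean_rr_s = NA_real_, sdnn_s = NA_real_, rmssd_s = NA_real_,
           mean_hr_bpm = NA_real_, n_intervals = length(rr),
           flags = flags),
      class = "hrv_summary"
    ))
  }
  for (type in c("tachycardia", "bradycardia")) {
    hit <- if (type == "tachycardia") r$hr_bpm > tachy_bpm else
      r$hr_bpm < brady_bpm
    runs <- rle(hit)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in which(runs$values & runs$lengths >= min_run)) {
      flags <- dplyr::bind_rows(flags, tibble::tibble(
        start_s = r$apex_times_s[starts[k]],
        end_s = r$apex_times_s[ends[k] + 1],
        type = type
      ))
    }
  }
  flags <- dplyr::arrange(flags, .data$start_s)
  structure(
    list(mean_rr_s = mean(rr), sdnn_s = sd(rr),
         rmssd_s = sqrt(mean(diff(rr)^2)), mean_hr_bpm = 60 / mean(rr),
         n_intervals = length(rr), flags = flags),
    class = "hrv_summary"
  )
}

#' @export
print.hrv_summary <- function(x, ...) {
  if (is.na(x$mean_rr_s)) {
    cat("<hrv_summary> insufficient intervals for statistics\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<hrv_summary> mean RR %.3f s (%.1f bpm), SDNN %.1f ms, RMSSD %.1f ms, %d flag(s)\n",
    x$mean_rr_s, x$mean_hr_bpm, 1000 * x$sdnn_s, 1000 * x$rmssd_s,
    nrow(x$flags)
  ))
  invisible(x)
}

#' @method tidy hrv_summary
#' @export
tidy.hrv_summary <- function(x, ...) {
  tibble::tibble(
    mean_rr_s = x$mean_rr_s, sdnn_s = x$sdnn_s, rmssd_s = x$rmssd_s,
    mean_hr_bpm = x$mean_hr_bpm, n_intervals = x$n_intervals,
    n_flags = nrow(x$flags)
  )
}

#' Detect R-peaks in a recording with a trained detector
#'
#' Fragments the recording, runs the model, binarizes, extracts events and
#' returns them with global apex indices (0-based) and apex responses.
#' The trailing remainder shorter than one window is not scanned.
#'
#' @param detector A trained detector.
#' @param rec A [recording()].
#' @param threshold Binarization threshold.
#' @param allow_untrained Permit an untrained model (see
#'   [predict.trained_detector()]).
#' @return Tibble with `window`, `start`, `end`, `apex` (global, 0-based),
#'   `response`.
#' @export
detect_peaks <- function(detector, rec, threshold = 0.5,
                         allow_untrained = FALSE) {
  ws <- fragment(rec, window_len = detector$window_len)
  preds <- predict(detector, ws, allow_untrained = allow_untrained)
  out <- list()
  for (w in seq_len(n_windows(ws))) {
    ev <- extract_events(binarize(preds[w, ], threshold), preds[w, ])
    if (nrow(ev) == 0) next
    off <- ws$meta$offset[w]
    out[[length(out) + 1]] <- tibble::tibble(
      window = w, start = ev$start + off, end = ev$end + off,
      apex = ev$apex + off,
      response = preds[w, ev$apex + 1]
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(window = integer(), start = integer(),
                          end = integer(), apex = integer(),
                          response = numeric()))
  }
  dplyr::bind_rows(out)
}

#' End-to-end R-R recovery against a recording's ground truth
#'
#' Runs the detector over an annotated recording, matches detected apexes
#' to true apexes one-to-one within `tol_samples`, and reports the matched
#' fraction and the R-R interval errors — the parameter-recovery harness
#' for the synthetic simulator. Only ground-truth peaks within the scanned
#' region (complete windows) are considered.
#'
#' @param detector A detector (may be untrained; recovery is then poor but
#'   reported, not an error).
#' @param rec An annotated [recording()].
#' @param threshold Binarization threshold.
#' @param tol_samples Apex matching tolerance in samples (default 5).
#' @return List with `n_true`, `n_detected`, `n_matched`,
#'   `matched_fraction`, `apex_errors_samples`, `rr_true_s`,
#'   `rr_detected_s`, and `rhythmogram`.
#' @export
recover_rr <- function(detector, rec, threshold = 0.5, tol_samples = 5) {
  stopifnot(!is.null(rec$peaks))
  events <- detect_peaks(detector, rec, threshold,
                         allow_untrained = !detector$trained)
  n_scanned <- (length(rec$samples) %/% detector$window_len) *
    detector$window_len
  truth <- rec$peaks[rec$peaks < n_scanned]
  rhythm <- suppressWarnings(build_rhythmogram(events, fs = rec$fs))
  det_apex <- round(rhythm$apex_times_s * rec$fs)
  # one-to-one nearest matching within tolerance; both sequences sorted so
  # the alignment DP on point "intervals" is exact
  pred_iv <- tibble::tibble(start = det_apex - tol_samples,
                            end = det_apex + tol_samples + 1)
  true_iv <- tibble::tibble(start = truth, end = truth + 1L)
  m <- match_events_dp(pred_iv, true_iv, min_overlap = 1)
  errors <- integer(0)
  if (length(det_apex) > 0 && length(truth) > 0) {
    nearest <- vapply(det_apex, function(a) truth[which.min(abs(truth - a))],
                      numeric(1))
    ok <- abs(det_apex - nearest) <= tol_samples
    errors <- (det_apex - nearest)[ok]
  }
  list(
    n_true = length(truth), n_detected = length(det_apex),
    n_matched = m$tp,
    matched_fraction = if (length(truth)) m$tp / length(truth) else
      NA_real_,
    apex_errors_samples = errors,
    rr_true_s = diff(truth) / rec$fs,
    rr_detected_s = rhythm$rr_intervals_s,
    rhythmogram = rhythm
  )
}
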