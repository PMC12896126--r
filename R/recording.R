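#' Single-channel EMG recording with optional R-peak ground truth
#'
#' The core container for one subject/condition signal trace. `samples` is a
#' numeric vector in arbitrary units; `peaks`, when present, holds the sample
#' indices of R-wave apexes. **All sample indices in this package are
#' 0-based**: a peak at index `p` refers to `samples[p + 1]`. This matches the
#' window/mask arithmetic used throughout and the plain-text annotation
#' format.
#'
#' @param samples Numeric vector, length >= 1.
#' @param fs Sampling rate in Hz (> 0). The default 500 Hz is the rate the
#'   detector and its windowing conventions are designed around.
#' @param subject_id Subject label, e.g. `"S1"`.
#' @param condition One of `"rest"`, `"static"`, `"dynamic"` — standing rest,
#'   sustained (static) muscle contraction, or repetitive (dynamic) exercise.
#' @param peaks Optional integer vector of 0-based R-apex sample indices,
#'   strictly increasing, all within `[0, length(samples))`. `NULL` means
#'   unannotated.
#' @return An object of class `rwave_recording`.
#' @seealso [read_recording()], [simulate_recording()], [fragment()]
#' @export
recording <- function(samples, fs = 500, subject_id = "S1",
                      condition = c("rest", "static", "dynamic"),
                      peaks = NULL) {
  condition <- match.arg(condition)
  samples <- as.numeric(samples)
  if (length(samples) < 1) {
    stop("`samples` must contain at least one value.", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz).", call. = FALSE)
  }
  if (!is.null(peaks)) {
    peaks <- validate_peaks(peaks, length(samples))
  }
  structure(
    list(samples = samples, fs = fs, subject_id = subject_id,
         condition = condition, peaks = peaks),
    class = "rwave_recording"
  )
}

validate_peaks <- function(peaks, n_samples) {
  if (length(peaks) == 0) return(integer(0))
  if (any(!is.finite(peaks)) || any(peaks != floor(peaks))) {
    stop("Peak indices must be integers.", call. = FALSE)
  }
  peaks <- as.integer(peaks)
  if (any(peaks < 0) || any(peaks >= n_samples)) {
    bad <- peaks[peaks < 0 | peaks >= n_samples][1]
    stop(sprintf(
      "Peak index %d outside valid range [0, %d).", bad, n_samples
    ), call. = FALSE)
  }
  if (any(diff(peaks) <= 0)) {
    stop("Peak indices must be strictly increasing.", call. = FALSE)
  }
  peaks
}

#' @export
print.rwave_recording <- function(x, ...) {
  cat(sprintf(
    "<rwave_recording> subject %s, condition %s: %d samples @ %g Hz (%.1f s), %s\n",
    x$subject_id, x$condition, length(x$samples), x$fs,
    length(x$samples) / x$fs,
    if (is.null(x$peaks)) "unannotated"
    else sprintf("%d annotated R-peaks", length(x$peaks))
  ))
  invisible(x)
}

#' @export
length.rwave_recording <- function(x) length(x$samples)

#' Read a signal trace (and optional R-peak annotations) from text files
#'
#' The signal file is UTF-8 text with one amplitude per line, or a two-column
#' `time,amplitude` CSV (header auto-detected; the time column is ignored —
#' `fs` is caller-supplied metadata, not inferred). The annotation file lists
#' one non-negative 0-based sample index per line, ascending.
#'
#' @param signal_path Path to the signal file.
#' @param annotation_path Optional path to an R-peak annotation file.
#' @param subject_id,condition,fs Metadata stamped onto the recording.
#' @return An [recording()] object.
#' @export
read_recording <- function(signal_path, annotation_path = NULL,
                           subject_id = "S1",
                           condition = c("rest", "static", "dynamic"),
                           fs = 500) {
  condition <- match.arg(condition)
  if (!file.exists(signal_path)) {
    stop(sprintf("Signal file not found: %s", signal_path), call. = FALSE)
  }
  lines <- readLines(signal_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop(sprintf("Signal file is empty: %s", signal_path), call. = FALSE)
  }
  two_col <- grepl(",", lines[[1]], fixed = TRUE)
  start <- 1L
  if (two_col && is.na(suppressWarnings(
    as.numeric(strsplit(lines[[1]], ",", fixed = TRUE)[[1]][1])
  ))) {
    start <- 2L  # header row
  }
  body <- lines[seq(start, length(lines))]
  if (two_col) {
    parts <- strsplit(body, ",", fixed = TRUE)
    vals <- suppressWarnings(vapply(
      parts, function(p) as.numeric(trimws(p[[length(p)]])), numeric(1)
    ))
  } else {
    vals <- suppressWarnings(as.numeric(trimws(body)))
  }
  if (anyNA(vals)) {
    bad_line <- which(is.na(vals))[1] + start - 1L
    stop(sprintf(
      "Non-numeric value in %s at line %d.", signal_path, bad_line
    ), call. = FALSE)
  }
  peaks <- NULL
  if (!is.null(annotation_path)) {
    peaks <- read_annotations(annotation_path)
  }
  recording(vals, fs = fs, subject_id = subject_id, condition = condition,
            peaks = peaks)
}

read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("Annotation file not found: %s", path), call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(integer(0))
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals) || any(vals != floor(vals))) {
    bad <- which(is.na(vals) | vals != floor(vals))[1]
    stop(sprintf(
      "Non-integer annotation in %s at line %d.", path, bad
    ), call. = FALSE)
  }
  as.integer(vals)
}

#' Write a signal trace to a plain-text file (one amplitude per line)
#'
#' @param rec An [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(rec, path) {
  stopifnot(inherits(rec, "rwave_recording"))
  writeLines(format(rec$samples, scientific = FALSE, trim = TRUE,
                    digits = 15),
             path)
  invisible(path)
}

#' Write R-peak annotations (0-based sample indices, one per line)
#'
#' Round-trips exactly: `read_recording(signal, write_annotations(rec, f))`
#' reproduces `rec$peaks`.
#'
#' @param rec An annotated [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(rec, path) {
  stopifnot(inherits(rec, "rwave_recording"))
  if (is.null(rec$peaks)) {
    stop("Recording has no peak annotations to write.", call. = FALSE)
  }
  writeLines(as.character(rec$peaks), path)
  invisible(path)
}
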