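#' Min-max normalize a signal to the interval -1..1
#'
#' Affine map `x -> 2 * (x - min) / (max - min) - 1`. A non-constant input
#' attains exactly -1 and +1; a constant input maps to all zeros (a flat
#' trace carries no events, and this avoids division by zero). Idempotent.
#'
#' @param samples Numeric vector, length >= 1.
#' @return Numeric vector of the same length in `[-1, 1]`.
#' @export
normalize_signal <- function(samples) {
  if (length(samples) < 1) {
    stop("Cannot normalize an empty signal.", call. = FALSE)
  }
  rng <- range(samples)
  if (rng[1] == rng[2]) return(rep(0, length(samples)))
  2 * (samples - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Build a binary R-wave label mask from apex indices
#'
#' Each apex `p` (0-based) contributes five consecutive ones centered on it,
#' positions `p-2 .. p+2`, clipped to `[0, length)` at the edges. Peaks
#' within 5 samples of each other would merge into a single run, which is
#' physiologically impossible at 500 Hz (it would mean > 5000 bpm), so such
#' inputs are rejected.
#'
#' @param peaks Sorted 0-based apex indices within `[0, length)`.
#' @param length Mask length in samples.
#' @return Integer vector of 0/1 of the given length.
#' @export
make_mask <- function(peaks, length) {
  peaks <- validate_peaks(peaks, length)
  mask <- integer(length)
  if (base::length(peaks) >= 2 && any(diff(peaks) <= 5)) {
    stop("Peaks closer than 6 samples apart: their 5-sample label runs would merge.",
         call. = FALSE)
  }
  for (p in peaks) {
    lo <- max(p - 2L, 0L)
    hi <- min(p + 2L, length - 1L)
    mask[(lo + 1):(hi + 1)] <- 1L
  }
  mask
}

#' A set of fixed-length signal windows with aligned label masks
#'
#' Internal constructor; users normally obtain window sets from
#' [fragment()]. `values` and `masks` are `n x window_len` matrices, `meta`
#' one row per window (`subject_id`, `condition`, `offset` = 0-based sample
#' index of the window start in its recording, `apexes` = list-column of
#' window-local 0-based apex indices of the peaks *owned* by the window).
#'
#' @param values,masks Numeric / integer matrices, `n x window_len`.
#' @param meta Tibble with one row per window.
#' @param fs Sampling rate in Hz.
#' @return A `window_set` object.
#' @keywords internal
#' @export
window_set <- function(values, masks, meta, fs) {
  stopifnot(nrow(values) == nrow(masks), nrow(values) == nrow(meta),
            ncol(values) == ncol(masks))
  structure(
    list(values = values, masks = masks, meta = tibble::as_tibble(meta),
         fs = fs, window_len = ncol(values)),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set> %d windows x %d samples @ %g Hz; %d subject(s), conditions: %s\n",
    n_windows(x), x$window_len, x$fs,
    length(unique(x$meta$subject_id)),
    paste(unique(x$meta$condition), collapse = ", ")
  ))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) nrow(ws$values)

#' @export
`[.window_set` <- function(x, i, ...) {
  window_set(x$values[i, , drop = FALSE], x$masks[i, , drop = FALSE],
             x$meta[i, , drop = FALSE], x$fs)
}

#' Combine window sets
#' @param ... `window_set` objects sharing `fs` and window length.
#' @return A single `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1)
  fs <- unique(vapply(sets, function(s) s$fs, numeric(1)))
  wl <- unique(vapply(sets, function(s) s$window_len, numeric(1)))
  if (length(fs) != 1 || length(wl) != 1) {
    stop("All window sets must share `fs` and window length.", call. = FALSE)
  }
  window_set(
    do.call(rbind, lapply(sets, function(s) s$values)),
    do.call(rbind, lapply(sets, function(s) s$masks)),
    dplyr::bind_rows(lapply(sets, function(s) s$meta)),
    fs
  )
}

#' Fragment a recording into fixed-length windows with label masks
#'
#' The whole recording is min-max normalized to `[-1, 1]` first (per
#' recording, not per window, so relative R-wave amplitude is preserved
#' across the trace), then cut into consecutive windows of `window_len`
#' samples starting at offsets `0, stride, 2 * stride, ...`; a trailing
#' remainder shorter than `window_len` is dropped. The default
#' `stride = window_len` gives non-overlapping windows; an overlapping
#' stride is available for training-set augmentation only — overlapping
#' windows must never be split across train and test.
#'
#' Masks are built over the full recording and sliced, so a peak whose
#' 5-sample run straddles a window boundary contributes its clipped portion
#' to each side; the window containing the apex *owns* the event for
#' evaluation (its local apex index is recorded in `meta$apexes`).
#'
#' @param rec An annotated or unannotated [recording()]. Without
#'   annotations, masks are all zero and `apexes` empty.
#' @param window_len Window length in samples (default 1600).
#' @param stride Offset step between windows (default `window_len`).
#' @return A [window_set()].
#' @export
fragment <- function(rec, window_len = 1600, stride = window_len) {
  stopifnot(inherits(rec, "rwave_recording"))
  n <- length(rec$samples)
  if (n < window_len) {
    stop(sprintf(
      "Recording has %d samples but at least %d are required for one window.",
      n, window_len
    ), call. = FALSE)
  }
  norm <- normalize_signal(rec$samples)
  peaks <- rec$peaks %||% integer(0)
  full_mask <- make_mask(peaks, n)
  offsets <- seq(0L, n - window_len, by = stride)
  vals <- matrix(0, length(offsets), window_len)
  msks <- matrix(0L, length(offsets), window_len)
  apex_list <- vector("list", length(offsets))
  for (w in seq_along(offsets)) {
    off <- offsets[w]
    idx <- (off + 1):(off + window_len)
    vals[w, ] <- norm[idx]
    msks[w, ] <- full_mask[idx]
    local <- peaks[peaks >= off & peaks < off + window_len] - off
    apex_list[[w]] <- as.integer(local)
  }
  meta <- tibble::tibble(
    subject_id = rec$subject_id, condition = rec$condition,
    offset = as.integer(offsets), apexes = apex_list
  )
  window_set(vals, msks, meta, rec$fs)
}

#' Write / read a window set as plain-text files in a directory
#'
#' `values.tsv` and `masks.tsv` hold one window per row; `meta.json` carries
#' the per-window metadata, `fs` and the window length.
#'
#' @param ws A [window_set()].
#' @param dir Directory (created if needed).
#' @return `dir` (write) or a `window_set` (read).
#' @export
write_window_set <- function(ws, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(ws$values, file.path(dir, "values.tsv"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(ws$masks, file.path(dir, "masks.tsv"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  meta <- ws$meta
  meta$apexes <- lapply(meta$apexes, as.integer)
  jsonlite::write_json(
    list(fs = ws$fs, window_len = ws$window_len, meta = meta),
    file.path(dir, "meta.json"), digits = NA
  )
  invisible(dir)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(file.path(dir, "values.tsv"),
                                      sep = "\t"))
  msks <- as.matrix(utils::read.table(file.path(dir, "masks.tsv"),
                                      sep = "\t"))
  dimnames(vals) <- NULL
  dimnames(msks) <- NULL
  meta <- tibble::as_tibble(info$meta)
  meta$apexes <- lapply(meta$apexes, as.integer)
  window_set(vals, msks, meta, info$fs)
}
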