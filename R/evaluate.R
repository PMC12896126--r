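#' Threshold a probability trace into a binary detection mask
#'
#' A sample belongs to an R-wave when its value is `>= threshold`
#' (the boundary is inclusive: exactly 0.5 counts as belonging).
#'
#' @param trace Numeric vector with values in `[0, 1]`.
#' @param threshold Decision threshold, default 0.5.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize <- function(trace, threshold = 0.5) {
  if (any(!is.finite(trace)) || any(trace < 0) || any(trace > 1)) {
    stop("Trace values must lie in [0, 1].", call. = FALSE)
  }
  as.integer(trace >= threshold)
}

#' Extract detection events from a binary mask
#'
#' Every maximal run of consecutive ones is one event — the presence of one
#' R-peak — regardless of run length (label runs are 5 samples; model
#' output runs may be any length). The apex is the argmax of `trace` within
#' the run (first index on ties), or the run midpoint when no trace is
#' supplied. All indices are 0-based; `end` is exclusive.
#'
#' @param binary Integer/logical 0/1 vector.
#' @param trace Optional response trace of the same length.
#' @return Tibble with columns `start`, `end`, `apex` (one row per event).
#' @export
extract_events <- function(binary, trace = NULL) {
  if (any(!binary %in% c(0, 1))) {
    stop("`binary` must contain only 0 and 1.", call. = FALSE)
  }
  r <- rle(as.integer(binary))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L   # 1-based
  keep <- r$values == 1L
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          apex = integer()))
  }
  apex <- integer(length(starts))
  for (i in seq_along(starts)) {
    if (is.null(trace)) {
      apex[i] <- starts[i] + (ends[i] - starts[i]) %/% 2L
    } else {
      seg <- trace[starts[i]:ends[i]]
      apex[i] <- starts[i] + which.max(seg) - 1L
    }
  }
  tibble::tibble(start = starts - 1L, end = ends, apex = apex - 1L)
}

# Optimal one-to-one event matching. Predicted and label events are each
# disjoint sorted intervals, so crossing matches are geometrically
# impossible and a sequence-alignment DP maximizing (TP, then total
# overlap) is exact. Returns the number of matched pairs and their overlap.
match_events_dp <- function(pred, lab, min_overlap = 1) {
  np <- nrow(pred); nl <- nrow(lab)
  if (np == 0 || nl == 0) return(list(tp = 0L, overlap = 0))
  # dp value encoded as tp * BIG + overlap (overlap < BIG always)
  BIG <- 1e9
  dp <- matrix(0, np + 1, nl + 1)
  for (i in seq_len(np)) {
    for (j in seq_len(nl)) {
      best <- max(dp[i, j + 1], dp[i + 1, j])
      ov <- min(pred$end[i], lab$end[j]) - max(pred$start[i], lab$start[j])
      if (ov >= min_overlap) {
        best <- max(best, dp[i, j] + BIG + ov)
      }
      dp[i + 1, j + 1] <- best
    }
  }
  v <- dp[np + 1, nl + 1]
  list(tp = as.integer(v %/% BIG), overlap = v %% BIG)
}

#' Match predicted events against label events and tally the confusion counts
#'
#' A predicted event matches a label event when their index ranges overlap
#' by at least `min_overlap` samples; matching is one-to-one and maximizes
#' the number of matched pairs (ties broken toward the largest total
#' overlap). Matched pairs are true positives; unmatched predictions false
#' positives; unmatched labels false negatives. True negatives are the
#' number of samples covered by neither mask, divided by the 5-sample event
#' duration for time normalization (`tn` may be fractional; it participates
#' in no reported metric but is tallied because the protocol defines it).
#'
#' @param predicted,labeled Event tables from [extract_events()].
#' @param window_len Window length in samples.
#' @param min_overlap Minimum overlap (samples) for a match, default 1.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
match_events <- function(predicted, labeled, window_len, min_overlap = 1) {
  for (ev in list(predicted, labeled)) {
    if (nrow(ev) == 0) next
    if (any(ev$start >= ev$end) || any(ev$start < 0) ||
        any(ev$end > window_len)) {
      stop("Events must satisfy 0 <= start < end <= window_len.",
           call. = FALSE)
    }
    if (nrow(ev) >= 2 && any(ev$start[-1] < ev$end[-nrow(ev)])) {
      stop("Events within one list must be disjoint and sorted.",
           call. = FALSE)
    }
  }
  m <- match_events_dp(predicted, labeled, min_overlap)
  pred_mask <- logical(window_len)
  lab_mask <- logical(window_len)
  for (i in seq_len(nrow(predicted))) {
    pred_mask[(predicted$start[i] + 1):predicted$end[i]] <- TRUE
  }
  for (i in seq_len(nrow(labeled))) {
    lab_mask[(labeled$start[i] + 1):labeled$end[i]] <- TRUE
  }
  confusion_counts(
    tp = m$tp,
    fp = nrow(predicted) - m$tp,
    fn = nrow(labeled) - m$tp,
    tn = sum(!pred_mask & !lab_mask) / 5
  )
}

#' Confusion-count container
#'
#' @param tp,fp,fn Non-negative integers.
#' @param tn Non-negative real (time-normalized zeros / 5).
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.numeric(tn)),
            class = "confusion_counts")
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  confusion_counts(e1$tp + e2$tp, e1$fp + e2$fp, e1$fn + e2$fn,
                   e1$tn + e2$tn)
}

#' Precision, recall and F-measure from confusion counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F = 2PR / (P + R)`.
#' Degenerate conventions: with no events and no detections
#' (`tp = fp = fn = 0`) all three are 1 (perfect silence); with `tp = 0`
#' and any error (`fp > 0` or `fn > 0`) the F-measure is 0, the empty-
#' denominator ratio among P/R being 1 and the other 0.
#'
#' @param counts A [confusion_counts()].
#' @return One-row tibble with `precision`, `recall`, `f_measure`.
#' @export
prf <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  p <- if (counts$tp + counts$fp == 0) 1 else
    counts$tp / (counts$tp + counts$fp)
  r <- if (counts$tp + counts$fn == 0) 1 else
    counts$tp / (counts$tp + counts$fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble::tibble(precision = p, recall = r, f_measure = f)
}

# Label events a window owns: runs of its mask that contain an owned apex
# (a clipped run whose apex lies in the neighbouring window is not an event
# of this window).
label_events_for_window <- function(mask, apexes) {
  ev <- extract_events(mask)
  if (nrow(ev) == 0) return(ev)
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    any(apexes >= ev$start[i] & apexes < ev$end[i])
  }, logical(1))
  ev[keep, , drop = FALSE]
}

#' Score detector output against labeled windows
#'
#' Binarizes each predicted trace, extracts events on both sides, matches
#' them per window and pools the confusion counts. Label events are the
#' mask runs owned by each window (a run clipped at a window boundary whose
#' apex belongs to the neighbouring window is not counted here).
#'
#' @param predictions `n x window_len` probability matrix from
#'   [predict.trained_detector()].
#' @param ws The corresponding labeled [window_set()].
#' @param threshold Binarization threshold.
#' @param min_overlap Event-match overlap requirement (samples).
#' @return List with `counts` (pooled [confusion_counts()]), `metrics`
#'   (one-row tibble from [prf()]) and `per_window` (tibble of counts).
#' @export
evaluate_windows <- function(predictions, ws, threshold = 0.5,
                             min_overlap = 1) {
  stopifnot(nrow(predictions) == n_windows(ws))
  rows <- vector("list", n_windows(ws))
  total <- confusion_counts()
  for (w in seq_len(n_windows(ws))) {
    pred_ev <- extract_events(binarize(predictions[w, ], threshold),
                              predictions[w, ])
    lab_ev <- label_events_for_window(ws$masks[w, ], ws$meta$apexes[[w]])
    cc <- match_events(pred_ev, lab_ev, ws$window_len, min_overlap)
    total <- total + cc
    rows[[w]] <- tibble::tibble(window = w, tp = cc$tp, fp = cc$fp,
                                fn = cc$fn, tn = cc$tn)
  }
  list(counts = total, metrics = prf(total),
       per_window = dplyr::bind_rows(rows))
}
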