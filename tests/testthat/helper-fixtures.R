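# Shared fixtures. Everything is generated in code; heavier fixtures are
# built lazily and cached for the session so several test files can share
# one trained model.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small window length keeps unit-test models fast; 128 = 2^5 * 4 admits
# two stride-2 encoder layers with room to spare.
tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(encoder_spec = list(c(9, 4, 2), c(5, 8, 2)),
         final_kernel = 5, dropout_rate = 0.1,
         max_epochs = 8, early_stop_patience = 4,
         batch_size = 16, seed = 11),
    list(...)
  )
  do.call(model_config, args)
}

tiny_sim_config <- function(...) {
  sim_config(duration_s = 10, seed = 21, ...)
}

# Noise-free short recordings fragmented into 128-sample windows: an easy,
# quickly learnable task for end-to-end tests.
tiny_windows <- function(seed = 21, emg_rms = 0, duration_s = 10,
                         window_len = 128) {
  rec <- simulate_recording(sim_config(duration_s = duration_s,
                                       emg_rms = emg_rms, seed = seed))
  fragment(rec, window_len = window_len)
}

# One small trained detector on a noise-free task, shared across tests.
tiny_trained_detector <- function() {
  cached("tiny_detector", {
    ws <- bind_window_sets(lapply(1:4, function(s) tiny_windows(seed = s)))
    sp <- rwavenet:::stratified_split(ws$meta, 0.8, 7)
    det <- build_detector(tiny_model_config(max_epochs = 25,
                                            early_stop_patience = 25),
                          window_len = 128)
    train_detector(det, ws[sp$train], ws[sp$test])
  })
}

# Brute-force one-to-one event matching oracle: enumerate all injective
# matchings, maximizing (number of pairs, total overlap). Exponential, for
# small instances only.
brute_force_match <- function(pred, lab, min_overlap = 1) {
  np <- nrow(pred); nl <- nrow(lab)
  best <- c(0, 0)
  recurse <- function(i, used, tp, ov) {
    if (i > np) {
      if (tp > best[1] || (tp == best[1] && ov > best[2])) {
        best <<- c(tp, ov)
      }
      return(invisible(NULL))
    }
    recurse(i + 1, used, tp, ov)  # leave prediction i unmatched
    for (j in seq_len(nl)) {
      if (used[j]) next
      o <- min(pred$end[i], lab$end[j]) - max(pred$start[i], lab$start[j])
      if (o >= min_overlap) {
        used[j] <- TRUE
        recurse(i + 1, used, tp + 1, ov + o)
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, nl), 0, 0)
  list(tp = best[1], overlap = best[2])
}

# Random disjoint sorted event list in [0, len): up to max_events runs of
# length 1..max_len.
random_events <- function(len, max_events, max_len = 8) {
  n <- sample(0:max_events, 1)
  if (n == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          apex = integer()))
  }
  starts <- integer(0); ends <- integer(0)
  cursor <- 0
  for (i in seq_len(n)) {
    gap <- sample(0:6, 1)
    s <- cursor + gap
    e <- s + sample(1:max_len, 1)
    if (e > len) break
    starts <- c(starts, s); ends <- c(ends, e)
    cursor <- e + 1
  }
  tibble::tibble(start = as.integer(starts), end = as.integer(ends),
                 apex = as.integer(starts + (ends - starts) %/% 2))
}

# Independent re-implementation of the printed metric formulas, with the
# documented degenerate conventions, used as the oracle for prf().
prf_reference <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(p = p, r = r, f = f)
}
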