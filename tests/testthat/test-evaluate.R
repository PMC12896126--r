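test_that("binarization uses an inclusive 0.5 boundary", {
  expect_identical(binarize(c(0.49, 0.5, 0.51)), c(0L, 1L, 1L))
  expect_identical(binarize(rep(0, 10)), rep(0L, 10))
  expect_identical(binarize(rep(0.5, 10)), rep(1L, 10))
  expect_error(binarize(c(0.2, 1.2)), "\\[0, 1\\]")
  expect_error(binarize(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("events are maximal runs of ones with argmax apexes", {
  m <- integer(1600); m[99:103] <- 1L     # ones at 0-based 98..102
  ev <- extract_events(m)
  expect_equal(ev$start, 98L)
  expect_equal(ev$end, 103L)
  expect_equal(ev$apex, 100L)             # midpoint without a trace
  b <- integer(40); b[11:13] <- 1L; b[21:28] <- 1L
  ev2 <- extract_events(b)
  expect_equal(nrow(ev2), 2)              # any run length counts
  expect_equal(ev2$start, c(10L, 20L))
  expect_equal(ev2$end, c(13L, 28L))
  expect_equal(nrow(extract_events(integer(50))), 0)
  # apex follows the response trace, first index on ties
  tr <- rep(0, 40); tr[22] <- 0.9; tr[25] <- 0.9
  ev3 <- extract_events(b, tr)
  expect_equal(ev3$apex[2], 21L)
  expect_error(extract_events(c(0, 2, 1)), "only 0 and 1")
})

test_that("event matching reproduces the worked confusion examples", {
  ev <- function(s, e) tibble::tibble(start = s, end = e,
                                      apex = s + (e - s) %/% 2)
  # exact agreement: 1595 shared zeros -> tn = 319
  cc <- match_events(ev(98L, 103L), ev(98L, 103L), 1600)
  expect_equal(cc$tp, 1); expect_equal(cc$fp, 0); expect_equal(cc$fn, 0)
  expect_equal(cc$tn, 319)
  # disjoint ranges
  cc2 <- match_events(ev(200L, 205L), ev(300L, 305L), 1600)
  expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(0, 1, 1))
  # one long prediction spanning two labels: one-to-one rule
  cc3 <- match_events(ev(98L, 111L),
                      ev(c(98L, 106L), c(103L, 111L)), 1600)
  expect_equal(c(cc3$tp, cc3$fp, cc3$fn), c(1, 0, 1))
  # invalid event lists are rejected
  expect_error(match_events(ev(c(10L, 12L), c(15L, 20L)), ev(1L, 2L), 30),
               "disjoint")
  expect_error(match_events(ev(10L, 5L), ev(1L, 2L), 30), "start < end")
})

test_that("precision/recall/F agree with the formulas on an exhaustive grid", {
  for (tp in 0:10) for (fp in 0:10) for (fn in 0:10) {
    got <- prf(confusion_counts(tp, fp, fn, 0))
    want <- prf_reference(tp, fp, fn)
    expect_equal(unlist(got), want,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("degenerate metric conventions hold", {
  silence <- prf(confusion_counts(0, 0, 0, 10))
  expect_equal(unlist(silence), c(precision = 1, recall = 1,
                                  f_measure = 1))
  expect_equal(prf(confusion_counts(0, 3, 0, 0))$f_measure, 0)
  expect_equal(prf(confusion_counts(0, 3, 0, 0))$precision, 0)
  expect_equal(prf(confusion_counts(0, 0, 4, 0))$f_measure, 0)
  ex <- prf(confusion_counts(9, 1, 0, 0))
  expect_equal(ex$precision, 0.9)
  expect_equal(ex$recall, 1)
  expect_equal(ex$f_measure, 2 * 0.9 / 1.9, tolerance = 1e-12)
})

test_that("metrics are invariant to scaling all counts", {
  set.seed(4)
  for (i in 1:25) {
    tp <- sample(0:8, 1); fp <- sample(0:8, 1); fn <- sample(0:8, 1)
    base <- prf(confusion_counts(tp, fp, fn, 0))
    for (k in c(2, 5)) {
      scaled <- prf(confusion_counts(k * tp, k * fp, k * fn, 0))
      expect_equal(scaled, base, tolerance = 1e-12)
    }
  }
})

test_that("count identities hold on random event sets", {
  set.seed(5)
  for (i in 1:50) {
    pred <- random_events(60, 4)
    lab <- random_events(60, 4)
    cc <- match_events(pred, lab, 60)
    expect_equal(cc$tp + cc$fn, nrow(lab))
    expect_equal(cc$tp + cc$fp, nrow(pred))
    expect_gte(cc$tn, 0)
  }
})

test_that("matching equals the brute-force optimum on small windows", {
  set.seed(6)
  for (i in 1:150) {
    pred <- random_events(60, 4)
    lab <- random_events(60, 4)
    got <- rwavenet:::match_events_dp(pred, lab)
    want <- brute_force_match(pred, lab)
    expect_equal(got$tp, want$tp)
    expect_equal(got$overlap, want$overlap)
  }
})

test_that("a stricter minimum overlap drops marginal matches", {
  ev <- function(s, e) tibble::tibble(start = s, end = e,
                                      apex = s + (e - s) %/% 2)
  pred <- ev(10L, 15L); lab <- ev(14L, 19L)   # overlap exactly 1
  expect_equal(match_events(pred, lab, 40, min_overlap = 1)$tp, 1)
  expect_equal(match_events(pred, lab, 40, min_overlap = 2)$tp, 0)
})

test_that("window evaluation pools counts and respects apex ownership", {
  ws <- tiny_windows(seed = 41)
  # a perfect detector: feed the masks back as predictions
  preds <- ws$masks * 1.0
  ev <- evaluate_windows(preds, ws)
  n_owned <- sum(vapply(ws$meta$apexes, length, integer(1)))
  n_runs <- sum(apply(ws$masks, 1, function(m) sum(rle(m)$values == 1)))
  expect_equal(ev$counts$tp, n_owned)
  expect_equal(ev$counts$fn, 0)
  # any run not owned by its window (apex in the neighbouring window) is
  # counted against the predictor that reproduces it
  expect_equal(ev$counts$fp, n_runs - n_owned)
  expect_equal(ev$metrics$recall, 1)
  # silence everywhere: all label events become misses
  ev0 <- evaluate_windows(matrix(0, n_windows(ws), 128), ws)
  expect_equal(ev0$counts$tp, 0)
  expect_equal(ev0$counts$fn, ev$counts$tp)
})
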