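#' Run a cross-validation scenario over a cohort
#'
#' Implements the three evaluation protocols for the detector:
#'
#' * `"pooled"` — one stratified-by-(subject, condition) 80/20 window
#'   split over the whole cohort, one model; rows report each condition in
#'   the test fraction plus an `"all"` row.
#' * `"loso"` — leave-one-subject-out: one fold per subject, training on
#'   all other subjects' windows and testing on the held-out subject; rows
#'   per (fold, condition) plus a per-fold `"all"`, with median and mean
#'   F-measure aggregates per condition across folds.
#' * `"per_subject"` — an 80/20 split within each subject's own windows
#'   only, one model per subject; rows and aggregates as for `"loso"`.
#'
#' Splits are stratified by (subject, condition) and seeded; within each
#' stratum `floor(0.8 * n)` windows train (documented rounding). Ten
#' percent of each training fraction (stratified the same way) is carved
#' off as the validation set for early stopping. Every fold's model seed is
#' derived from `split_seed` so the whole report is reproducible.
#'
#' The `"all"` row pools confusion counts across conditions by default
#' (`all_contexts = "pooled"`); `all_contexts = "mean_f"` averages the
#' per-condition F-measures instead. A condition absent from a test fold
#' yields an `NA` row that aggregates ignore.
#'
#' @param cohort Tibble from [simulate_cohort()] (columns `subject_id`,
#'   `condition`, `recording`) or a plain list of annotated recordings.
#' @param scenario `"pooled"`, `"loso"` or `"per_subject"`.
#' @param config A [model_config()] shared by all folds.
#' @param split_seed Integer seed for splits and fold model seeds.
#' @param window_len Window length in samples.
#' @param threshold,min_overlap Evaluation settings, see
#'   [evaluate_windows()].
#' @param all_contexts `"pooled"` or `"mean_f"` (see above).
#' @param verbose Print per-fold progress.
#' @return A `scenario_report`: list with `scenario`, `rows` (per-fold,
#'   per-condition tibble), `aggregates` (median/mean F per condition),
#'   `seeds`, and the configuration echo. [tidy()] returns the rows,
#'   [glance()] the aggregates in wide form.
#' @export
run_scenario <- function(cohort,
                         scenario = c("pooled", "loso", "per_subject"),
                         config = model_config(), split_seed = 1L,
                         window_len = 1600, threshold = 0.5,
                         min_overlap = 1,
                         all_contexts = c("pooled", "mean_f"),
                         verbose = FALSE) {
  scenario <- match.arg(scenario)
  all_contexts <- match.arg(all_contexts)
  cohort <- as_cohort_tibble(cohort)
  subjects <- unique(cohort$subject_id)
  if (scenario %in% c("loso") && length(subjects) < 2) {
    stop("Leave-one-subject-out needs at least 2 subjects.", call. = FALSE)
  }
  windows <- bind_window_sets(lapply(cohort$recording, fragment,
                                     window_len = window_len))
  folds <- switch(scenario,
    pooled = {
      sp <- stratified_split(windows$meta, 0.8,
                             derive_seed(split_seed, "pooled"))
      list(list(fold = "pooled", train = sp$train, test = sp$test))
    },
    loso = lapply(subjects, function(s) {
      list(fold = s,
           train = which(windows$meta$subject_id != s),
           test = which(windows$meta$subject_id == s))
    }),
    per_subject = lapply(subjects, function(s) {
      own <- which(windows$meta$subject_id == s)
      sp <- stratified_split(windows$meta[own, ], 0.8,
                             derive_seed(split_seed, "per_subject", s))
      list(fold = s, train = own[sp$train], test = own[sp$test])
    })
  )
  conditions <- unique(windows$meta$condition)
  rows <- list()
  seeds <- list()
  for (fd in folds) {
    fold_seed <- derive_seed(split_seed, "fold", fd$fold)
    seeds[[fd$fold]] <- fold_seed
    cfg <- config
    cfg$seed <- fold_seed
    class(cfg) <- "model_config"
    tr_ws <- windows[fd$train]
    te_ws <- windows[fd$test]
    vs <- stratified_split(tr_ws$meta, 0.9,
                           derive_seed(split_seed, "val", fd$fold))
    detector <- build_detector(cfg, window_len)
    detector <- train_detector(detector, tr_ws[vs$train], tr_ws[vs$test])
    if (verbose) {
      message(sprintf("fold %s: trained %d epochs (best %d)", fd$fold,
                      nrow(detector$training_log), detector$best_epoch))
    }
    preds <- predict(detector, te_ws)
    cond_counts <- list()
    for (cond in conditions) {
      in_cond <- which(te_ws$meta$condition == cond)
      if (length(in_cond) == 0) {
        rows[[length(rows) + 1]] <- scenario_row(scenario, fd$fold, cond,
                                                 NULL, length(fd$train), 0)
        next
      }
      ev <- evaluate_windows(preds[in_cond, , drop = FALSE],
                             te_ws[in_cond], threshold, min_overlap)
      cond_counts[[cond]] <- ev$counts
      rows[[length(rows) + 1]] <- scenario_row(scenario, fd$fold, cond,
                                               ev$counts, length(fd$train),
                                               length(in_cond))
    }
    all_counts <- Reduce(`+`, cond_counts)
    all_row <- scenario_row(scenario, fd$fold, "all", all_counts,
                            length(fd$train), length(fd$test))
    if (all_contexts == "mean_f") {
      fs <- vapply(cond_counts, function(cc) prf(cc)$f_measure, numeric(1))
      all_row$f_measure <- mean(fs)
    }
    rows[[length(rows) + 1]] <- all_row
  }
  rows <- dplyr::bind_rows(rows)
  aggregates <- rows |>
    dplyr::filter(!is.na(.data$f_measure)) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(median_f = median(.data$f_measure),
                     mean_f = mean(.data$f_measure),
                     n_folds = dplyr::n(), .groups = "drop")
  structure(
    list(scenario = scenario, rows = rows, aggregates = aggregates,
         seeds = seeds, split_seed = split_seed, config = config,
         window_len = window_len, threshold = threshold,
         min_overlap = min_overlap, all_contexts = all_contexts),
    class = "scenario_report"
  )
}

scenario_row <- function(scenario, fold, condition, counts, n_train,
                         n_test) {
  if (is.null(counts)) {
    return(tibble::tibble(
      scenario = scenario, fold = fold, condition = condition,
      n_train_windows = n_train, n_test_windows = n_test,
      tp = NA_integer_, fp = NA_integer_, fn = NA_integer_, tn = NA_real_,
      precision = NA_real_, recall = NA_real_, f_measure = NA_real_
    ))
  }
  m <- prf(counts)
  tibble::tibble(
    scenario = scenario, fold = fold, condition = condition,
    n_train_windows = n_train, n_test_windows = n_test,
    tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn,
    precision = m$precision, recall = m$recall, f_measure = m$f_measure
  )
}

as_cohort_tibble <- function(cohort) {
  if (tibble::is_tibble(cohort) || is.data.frame(cohort)) {
    stopifnot(all(c("subject_id", "condition", "recording") %in%
                    names(cohort)))
    return(tibble::as_tibble(cohort))
  }
  if (is.list(cohort) &&
      all(vapply(cohort, inherits, logical(1), "rwave_recording"))) {
    return(tibble::tibble(
      subject_id = vapply(cohort, function(r) r$subject_id, character(1)),
      condition = vapply(cohort, function(r) r$condition, character(1)),
      recording = cohort
    ))
  }
  stop("`cohort` must be a cohort tibble or a list of recordings.",
       call. = FALSE)
}

# Stratified split of window metadata by (subject_id, condition):
# floor(frac * n) per stratum goes to `train` (at least 1 when n > 1).
stratified_split <- function(meta, frac, seed) {
  withr_seed(seed)
  strata <- paste(meta$subject_id, meta$condition, sep = "\r")
  train <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_tr <- max(floor(frac * length(idx)), min(1L, length(idx) - 1L))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(meta)), train))
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> scenario '%s': %d fold(s)\n", x$scenario,
              length(x$seeds)))
  print(x$aggregates)
  invisible(x)
}

#' @method tidy scenario_report
#' @export
tidy.scenario_report <- function(x, ...) x$rows

#' @method glance scenario_report
#' @export
glance.scenario_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$aggregates[, c("condition", "median_f")],
    names_from = "condition", values_from = "median_f",
    names_prefix = "median_f_"
  )
  dplyr::bind_cols(
    tibble::tibble(scenario = x$scenario, n_folds = length(x$seeds)),
    wide
  )
}

#' Write a scenario report as a delimited table plus a JSON sidecar
#'
#' The TSV mirrors the usual presentation (one row per fold with one column
#' per condition); the sidecar records per-fold seeds, counts and settings.
#'
#' @param report A `scenario_report`.
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scenario_report <- function(report, path) {
  wide <- tidyr::pivot_wider(
    report$rows[, c("fold", "condition", "f_measure")],
    names_from = "condition", values_from = "f_measure"
  )
  utils::write.table(wide, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(scenario = report$scenario, split_seed = report$split_seed,
         seeds = report$seeds, threshold = report$threshold,
         min_overlap = report$min_overlap,
         all_contexts = report$all_contexts, rows = report$rows),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
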