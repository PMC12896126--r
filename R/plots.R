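#' Plot a recording trace with its R-peak annotations
#'
#' @param object An [recording()].
#' @param from_s,to_s Time range to draw (seconds); defaults to the whole
#'   trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rwave_recording
#' @export
autoplot.rwave_recording <- function(object, from_s = 0, to_s = NULL,
                                     ...) {
  to_s <- to_s %||% (length(object$samples) / object$fs)
  tt <- (seq_along(object$samples) - 1) / object$fs
  keep <- tt >= from_s & tt <= to_s
  df <- tibble::tibble(t = tt[keep], amplitude = object$samples[keep])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t,
                                        y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (a.u.)",
      title = sprintf("%s / %s", object$subject_id, object$condition)
    )
  if (!is.null(object$peaks)) {
    pk_t <- object$peaks / object$fs
    pk <- tibble::tibble(t = pk_t[pk_t >= from_s & pk_t <= to_s])
    pk$amplitude <- object$samples[round(pk$t * object$fs) + 1]
    p <- p + ggplot2::geom_point(data = pk, colour = "red", size = 1)
  }
  p
}

#' Plot a rhythmogram (tachogram of R-R intervals over time)
#'
#' @param object A [build_rhythmogram()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rhythmogram
#' @export
autoplot.rhythmogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_end_s, y = .data$rr_s)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "R-R interval (s)",
                  title = "Rhythmogram")
}

#' Plot per-fold F-measures of a scenario report by condition
#'
#' @param object A [run_scenario()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_report
#' @export
autoplot.scenario_report <- function(object, ...) {
  df <- dplyr::filter(object$rows, !is.na(.data$f_measure))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$f_measure)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0),
                        alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "red",
                          linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "recording condition", y = "event F-measure",
                  title = sprintf("Scenario: %s", object$scenario))
}

#' Plot a window's signal, label mask and model output together
#'
#' @param ws A [window_set()].
#' @param index Window index (1-based row of the set).
#' @param prediction Optional probability trace for the same window.
#' @return A ggplot object.
#' @export
plot_window <- function(ws, index = 1, prediction = NULL) {
  df <- tibble::tibble(
    sample = seq_len(ws$window_len) - 1,
    signal = ws$values[index, ],
    mask = ws$masks[index, ]
  )
  long <- tidyr::pivot_longer(df, -"sample", names_to = "trace")
  if (!is.null(prediction)) {
    long <- dplyr::bind_rows(long, tibble::tibble(
      sample = df$sample, trace = "model output",
      value = as.numeric(prediction)
    ))
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample,
                                     y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$trace), scales = "free_y") +
    ggplot2::labs(x = "sample within window", y = NULL)
}
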