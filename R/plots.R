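#' Plot a temporal generalization matrix
#'
#' @param object A `generalization_matrix`.
#' @param ... Unused.
#' @return A ggplot: train time by test time, fill = statistic.
#' @method autoplot generalization_matrix
#' @export
autoplot.generalization_matrix <- function(object, ...) {
  df <- tidy(object)
  mid <- if (object$statistic %in% c("accuracy", "choice")) 0.5 else 0
  ggplot2::ggplot(df, ggplot2::aes(.data$test_time, .data$train_time,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = mid, low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(
      x = paste0("test time (s, ", object$test_alignment, ")"),
      y = paste0("train time (s, ", object$train_alignment, ")"),
      fill = object$statistic,
      title = paste0("train ", object$train_condition, " → test ",
                     object$test_condition)) +
    ggplot2::theme_minimal()
}

#' Plot an accuracy time course
#'
#' @param object An `accuracy_timecourse`.
#' @param chance Reference level drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot accuracy_timecourse
#' @export
autoplot.accuracy_timecourse <- function(object, chance = 0.5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$accuracy)) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "proportion correct") +
    ggplot2::theme_minimal()
}

#' Plot a diagonal-band trace
#'
#' @param object A `diagonal_trace`.
#' @param chance Reference level drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diagonal_trace
#' @export
autoplot.diagonal_trace <- function(object, chance = 0.5, ...) {
  prov <- attr(object, "provenance")
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = paste0("test time (s, ", prov$test_alignment, ")"),
      y = attr(object, "statistic"),
      title = paste0("diagonal band, width ",
                     round(attr(object, "width") * 1000), " ms")) +
    ggplot2::theme_minimal()
}

#' Plot an evoked map as a site-by-time image
#'
#' @param object An `evoked_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot evoked_map
#' @export
autoplot.evoked_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$site,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = paste0("time (s, ", attr(object, "alignment"), ")"),
                  y = "site", fill = "combined\ngradient") +
    ggplot2::theme_minimal()
}

#' Plot an eye trace with detected or ground-truth events
#'
#' @param object An `eye_trace`.
#' @param events Optional event tibble to overlay (defaults to the trace's
#'   ground-truth events).
#' @param ... Unused.
#' @return A ggplot of x/y position over time.
#' @method autoplot eye_trace
#' @export
autoplot.eye_trace <- function(object, events = attr(object, "events"),
                               ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("x_deg", "y_deg"),
                            names_to = "axis", values_to = "deg")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$deg,
                                        color = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "gaze position (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = events$onset,
                                 linetype = "dotted", color = "grey40")
  }
  p
}
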