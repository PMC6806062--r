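# ggplot2 autoplot methods for the package's result objects.

#' Plot a t-SNE embedding colored by class
#'
#' @param object A [tsne_embed()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tsne_embedding
#' @export
autoplot.tsne_embedding <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$dim1, .data$dim2, colour = .data$label)) +
    geom_point(alpha = 0.7) +
    labs(
      x = "t-SNE dimension 1", y = "t-SNE dimension 2", colour = NULL,
      subtitle = sprintf("silhouette = %.3f", attr(object, "silhouette"))
    ) +
    theme_minimal()
}

#' Bar chart of LASSO coefficients
#'
#' Mirrors the usual feature-importance layout: one bar per feature,
#' ordered by coefficient magnitude, with the selection threshold drawn as
#' a reference line.
#'
#' @param object A [lasso_rank()] result.
#' @param threshold Selection cutoff to display (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lasso_ranking
#' @export
autoplot.lasso_ranking <- function(object, threshold = 0.01, ...) {
  d <- as_tibble(unclass(object)[c("feature", "abs_coefficient")])
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot(d, aes(.data$feature, .data$abs_coefficient)) +
    geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    coord_flip() +
    labs(x = NULL, y = "|regression coefficient| (standardized)") +
    theme_minimal()
}

#' Per-fold accuracy chart of a LOSO evaluation
#'
#' @param object An [run_experiment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$per_fold[, c("held_out_subject", "accuracy", "f1")],
    c("accuracy", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot(d, aes(.data$held_out_subject, .data$value)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~metric) +
    labs(x = "held-out subject", y = NULL) +
    theme_minimal()
}

#' Plot a signal segment with detected events
#'
#' Convenience plot for visual inspection of preprocessing: the signal with
#' markers at detected R-peaks or SCR peaks.
#'
#' @param signal A signal tibble (`t_seconds`, `value`).
#' @param event_times Numeric vector of event times (seconds).
#' @param xlim Optional two-element time range to display.
#' @return A ggplot object.
#' @export
plot_signal_events <- function(signal, event_times = numeric(0), xlim = NULL) {
  d <- as_tibble(signal)
  if (!is.null(xlim)) {
    d <- d[d$t_seconds >= xlim[1] & d$t_seconds <= xlim[2], ]
    event_times <- event_times[event_times >= xlim[1] & event_times <= xlim[2]]
  }
  p <- ggplot(d, aes(.data$t_seconds, .data$value)) +
    geom_line(colour = "grey30") +
    labs(x = "time (s)", y = "amplitude") +
    theme_minimal()
  if (length(event_times)) {
    marks <- tibble(
      t_seconds = event_times,
      value = approx(d$t_seconds, d$value, xout = event_times)$y
    )
    p <- p + geom_point(data = marks, colour = "red", size = 2)
  }
  p
}
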