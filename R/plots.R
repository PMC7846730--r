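#' Plot a two-channel recording
#'
#' Time traces of both channels; labeled recordings are shaded by
#' orientation along the time axis.
#'
#' @param object A `motion_recording`.
#' @param max_points Recordings longer than this are thinned for plotting.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motion_recording <- function(object, max_points = 20000, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  long <- tidyr::pivot_longer(df, c("ch_slash", "ch_backslash"),
                              names_to = "channel", values_to = "value")
  long$channel <- ifelse(long$channel == "ch_slash", "\"/\" thread",
                         "\"\\\" thread")
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$time_s, y = .data$value,
                                    colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)",
      y = if (isTRUE(attr(object, "normalized"))) {
        "normalized level"
      } else {
        "impedance (a.u.)"
      },
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!all(is.na(df$label))) {
    p <- p + ggplot2::facet_wrap(~channel, ncol = 1)
  }
  p
}

#' Plot per-orientation feature distributions
#'
#' Boxplots of one feature by segment label, mirroring the per-orientation
#' feature-range views used to design the predictors.
#'
#' @param features A `motion_features` tibble with labels.
#' @param feature Feature column to plot.
#' @return A ggplot object.
#' @export
plot_feature_by_orientation <- function(features, feature = "delta_mu") {
  stopifnot(feature %in% motion_feature_names())
  df <- features[!is.na(features$label), ]
  df$label <- factor(df$label,
                     levels = intersect(orientation_levels(),
                                        unique(df$label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label,
                                   y = .data[[feature]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a pooled confusion matrix
#'
#' Heatmap of one classifier's pooled confusion matrix from a
#' [repeated_holdout()] evaluation, rows true and columns predicted, in
#' the canonical orientation order.
#'
#' @param object A `motion_eval`.
#' @param classifier Classifier to show; default the one with the highest
#'   averaged accuracy.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motion_eval <- function(object, classifier = NULL, ...) {
  if (is.null(classifier)) {
    classifier <- tidy(object)$classifier[1]
  }
  m <- object$confusion[[classifier]]
  df <- tibble::as_tibble(as.table(m))
  names(df) <- c("true", "predicted", "count")
  lev <- object$protocol$levels
  df$true <- factor(df$true, levels = rev(lev))
  df$predicted <- factor(df$predicted, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = classifier, x = "predicted", y = "true") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
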