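#' Plot a sensor record
#'
#' Drain current against time with the injection boundaries marked and,
#' when present, the anomaly kind in the subtitle.
#'
#' @param object an `apta_signal`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method
autoplot.apta_signal <- function(object, ...) {
  b <- signal_boundaries(object)
  dt <- object$time_s[2] - object$time_s[1]
  anom <- signal_anomaly(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$current)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = b$start[-1] * dt,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "time (s)",
      y = if (isTRUE(attr(object, "normalized"))) "drain current (z-score)"
          else "drain current (a.u.)",
      subtitle = if (!is.null(anom)) paste("anomaly:", anom$kind)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram
#'
#' Time-frequency heat map of the squared STFT magnitude (log10 colour
#' scale).
#'
#' @param object an `apta_spectrogram` from [compute_spectrogram()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method
autoplot.apta_spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(frequency_bin = seq_len(nrow(object)),
                           frame = seq_len(ncol(object)))
  df$power <- as.vector(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$frequency_bin,
                                   fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "frame", y = "frequency bin") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' Heat map of the confusion matrix of an evaluation report with accuracy
#' and macro-F1 in the title.
#'
#' @param object an `apta_metrics` from [confusion_and_metrics()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method
autoplot.apta_metrics <- function(object, ...) {
  cm <- object$confusion
  df <- tidyr::expand_grid(true = seq_len(nrow(cm)), predicted = seq_len(ncol(cm)))
  df$count <- cm[cbind(df$true, df$predicted)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(cm))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(cm))) +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("accuracy %.3f | macro-F1 %.3f",
                                  object$accuracy, object$macro_f1)) +
    ggplot2::theme_minimal()
}

#' Plot segments by class
#'
#' Overlays segment traces coloured by concentration class; a quick
#' morphology check of real or augmented segments.
#'
#' @param object an `apta_segments` tibble.
#' @param max_per_class at most this many traces per class.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method
autoplot.apta_segments <- function(object, max_per_class = 5L, ...) {
  df <- object %>%
    dplyr::group_by(.data$concentration) %>%
    dplyr::slice(seq_len(min(max_per_class, dplyr::n()))) %>%
    dplyr::ungroup()
  long <- tidyr::unnest_longer(
    dplyr::mutate(df, class = factor(.data$concentration))[, c("segment_id", "class", "values")],
    "values", values_to = "value", indices_to = "sample"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value,
                                     group = .data$segment_id,
                                     colour = .data$class)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::labs(x = "sample", y = "z-scored current",
                  colour = "concentration (M)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
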