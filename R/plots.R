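#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an attenuation function
#'
#' Attenuation in dB against log frequency, with the 2-16 kHz band mean
#' drawn as a dashed reference.
#'
#' @param object A `masksim_attenuation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.masksim_attenuation <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$hz > 0, ]
  m <- band_mean_attenuation(object, 2000, 16000)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hz, y = .data$db)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = m, linetype = "dashed", color = "grey40") +
    ggplot2::scale_x_log10(breaks = c(100, 1000, 10000),
                           labels = c("0.1", "1", "10")) +
    ggplot2::labs(x = "Frequency (kHz)", y = "Attenuation (dB)",
                  title = object$label,
                  subtitle = sprintf("mean 2-16 kHz: %.1f dB", m)) +
    ggplot2::theme_minimal()
}

#' Plot a consonant confusion matrix
#'
#' @param object A `masksim_confusion` (12x12 counts).
#' @param ... Unused.
#' @return A ggplot heat map (rows = target, columns = response).
#' @export
autoplot.masksim_confusion <- function(object, ...) {
  m <- as.matrix(object)
  d <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
  names(d) <- c("target", "response", "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$response, y = .data$target,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$count > 0,
                                                   .data$count, "")),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(consonants())) +
    ggplot2::scale_x_discrete(limits = consonants(), position = "top") +
    ggplot2::scale_fill_gradient(low = "white", high = "#d7301f",
                                 guide = "none") +
    ggplot2::labs(x = "Response", y = "Target") +
    ggplot2::theme_minimal()
}

#' Plot per-condition scores
#'
#' RAU scores (or feature transmissions) by mask condition, faceted by
#' modality and colored by group.
#'
#' @param scores A score table from [score_trials()].
#' @param y Column to plot (default `"rau"`).
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, y = "rau") {
  stopifnot(y %in% names(scores))
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = factor(.data$mask, levels = mask_levels()),
                               y = .data[[y]], color = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = "dodge") +
    ggplot2::facet_wrap(~modality) +
    ggplot2::labs(x = "Mask", y = y) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
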