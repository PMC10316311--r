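#' Plot a genotype matrix as a presence/absence grid
#'
#' @param object A [genotype_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.genotype_matrix <- function(object, ...) {
  df <- tidy(object)
  df$cultivar <- factor(df$cultivar, levels = rev(cultivars(object)))
  df$marker <- factor(df$marker, levels = marker_ids(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker, y = .data$cultivar,
                                   fill = factor(.data$present))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "steelblue4"),
                               name = "fragment",
                               labels = c(`0` = "absent", `1` = "present")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a strip band pattern
#'
#' Draws the detection lines of the strip, filled where a band develops.
#'
#' @param object A `band_pattern` from [predict_bands()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.band_pattern <- function(object, ...) {
  df <- object$lines
  df$y <- -df$line
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(xmin = 0, xmax = 1,
                       ggplot2::aes(ymin = .data$y - 0.15,
                                    ymax = .data$y + 0.15,
                                    alpha = .data$present),
                       fill = "royalblue4") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.08),
                                guide = "none") +
    ggplot2::geom_text(ggplot2::aes(x = 1.25, y = .data$y,
                                    label = .data$marker),
                       hjust = 0, size = 3) +
    ggplot2::xlim(0, 3) +
    ggplot2::labs(
      title = sprintf("kit '%s' on '%s': %d band(s), %s",
                      object$target, object$sample, object$band_count,
                      diagnose(object))) +
    ggplot2::theme_void()
}

#' Plot per-cultivar cluster read fractions
#'
#' Heat map of the fraction of each cultivar's reads falling in each
#' cluster, the quantity the presence/absence threshold is applied to.
#'
#' @param object An `insertion_clusters` object from [cluster_reads()].
#' @param threshold Read-fraction cutoff drawn into the legend title.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.insertion_clusters <- function(object, threshold = 0.001, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster_id, y = .data$cultivar,
                                   fill = .data$fraction >= threshold)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "steelblue4", `FALSE` = "grey95"),
      name = sprintf("fraction >= %g", threshold)) +
    ggplot2::labs(x = "cluster", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
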