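#' Stacked read-partition plot
#'
#' The classic stacked-fraction view of the species partition per sample
#' (tumor-only / host-only / ambiguous / unmapped).
#'
#' @param summary output of [summarize_classification()] (with or without a
#'   `sample` column).
#' @return a ggplot object.
#' @export
plot_classification <- function(summary) {
  if (!"sample" %in% names(summary)) summary$sample <- "sample"
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$sample, y = .data$percent,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "% of reads", fill = "class") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.de_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(pmax(.data$p_adj, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::geom_vline(xintercept = c(-attr(object, "lfc_cutoff"),
                                       attr(object, "lfc_cutoff")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  title = paste(attr(object, "contrast"),
                                collapse = " vs ")) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sample_pca <- function(object, colour = NULL, ...) {
  d <- object$scores
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * (object$var_explained[2] %||% 0))) +
    ggplot2::theme_minimal()
  p
}
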