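# Optional biplot of an ordination (requires ggplot2).

#' Biplot of a PCA ordination
#'
#' Food scores as points and the three systems' loading vectors as arrows on
#' the first two components, the visual counterpart of the reported loading
#' angles.
#'
#' @param ord An `ordination` from [run_pca()].
#' @param arrow_scale Multiplier applied to the loading arrows for legibility.
#' @return A ggplot object.
#' @export
plot_ordination <- function(ord, arrow_scale = 2) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_nc("plot_ordination requires the ggplot2 package")
  }
  scores <- tibble::as_tibble(ord$scores, .name_repair = "minimal")
  names(scores) <- c("PC1", "PC2")
  arrows <- tibble::as_tibble(ord$loadings, rownames = "system")
  names(arrows) <- c("system", "PC1", "PC2")
  ggplot2::ggplot(scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(alpha = 0.3, colour = "grey40",
                        position = ggplot2::position_jitter(0.08, 0.08)) +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = 0, y = 0,
                   xend = arrow_scale * .data$PC1,
                   yend = arrow_scale * .data$PC2),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.25, "cm")),
      colour = "blue"
    ) +
    ggplot2::geom_text(
      data = arrows,
      ggplot2::aes(x = arrow_scale * .data$PC1 * 1.12,
                   y = arrow_scale * .data$PC2 * 1.12,
                   label = .data$system),
      colour = "blue"
    ) +
    ggplot2::labs(
      title = sprintf("Ordination of classification systems: %s", ord$stratum),
      x = sprintf("PC1 (%.0f%%)", 100 * ord$explained_variance[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * ord$explained_variance[2])
    ) +
    ggplot2::theme_minimal()
}
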