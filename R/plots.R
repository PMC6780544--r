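# ggplot2 views of the result objects: PCA score and scree plots, RF
# proximity-MDS and importance plots, and the targeted-panel heatmap.

#' @describeIn pca_samples Score plot of the first two components, colored
#'   by group.
#' @param object An `iroa_pca` object.
#' @method autoplot iroa_pca
#' @export
autoplot.iroa_pca <- function(object, ...) {
  stopifnot(ncol(object$scores) >= 4)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_frac[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Scree plot of PCA variance fractions
#'
#' @param pca An `iroa_pca` object.
#' @param n_components Components to show. Default: all retained.
#' @return A ggplot.
#' @export
plot_pca_scree <- function(pca, n_components = length(pca$var_frac)) {
  d <- tibble::tibble(component = seq_len(n_components),
                      var_frac = pca$var_frac[seq_len(n_components)])
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$var_frac)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_x_continuous(breaks = d$component) +
    ggplot2::labs(x = "component", y = "fraction of variance") +
    ggplot2::theme_minimal()
}

#' @describeIn rf_classify Dot plot of the metabolites with highest mean
#'   decrease accuracy, colored by direction of change under treatment.
#' @param object An `iroa_rf` object.
#' @param top Number of metabolites shown. Default 40.
#' @method autoplot iroa_rf
#' @export
autoplot.iroa_rf <- function(object, top = 40L, ...) {
  d <- top_importance(object, min(top, nrow(object$importance)))
  d$row_id <- factor(d$row_id, levels = rev(d$row_id))
  ggplot2::ggplot(d, ggplot2::aes(.data$mda, .data$row_id,
                                  colour = .data$direction)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(increase = "#E69F00",
                                            decrease = "#0072B2")) +
    ggplot2::labs(x = "mean decrease accuracy", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' MDS plot of the random-forest proximity matrix
#'
#' @param rf An `iroa_rf` object.
#' @return A ggplot of the samples embedded by classical MDS of
#'   `1 - proximity`.
#' @export
plot_rf_mds <- function(rf) {
  ggplot2::ggplot(rf$mds, ggplot2::aes(.data$mds1, .data$mds2,
                                       colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of targeted-panel log2 fold changes
#'
#' Panel entries along the x axis (in pathway order when a
#' `pathway_position` column is present), log2 fold change as fill;
#' undetected entries are shown in grey.
#'
#' @param targeted Output of [targeted_extract()].
#' @return A ggplot.
#' @export
plot_targeted_heatmap <- function(targeted) {
  d <- targeted
  d$name <- factor(d$name, levels = unique(d$name))
  ggplot2::ggplot(d, ggplot2::aes(.data$name, y = "log2 FC",
                                  fill = .data$log2fc)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#0072B2", mid = "white",
                                  high = "#D55E00", na.value = "grey70") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
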