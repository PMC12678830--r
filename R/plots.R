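#' @importFrom rlang .data
NULL

#' Plot sample PCA coordinates
#'
#' @param object A [pca_embed()] result.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2, colored by condition when available,
#'   with axis labels carrying the variance fractions.
#' @method autoplot shutoff_pca
#' @export
autoplot.shutoff_pca <- function(object, ...) {
  d <- object$coords
  pct <- function(i) sprintf("PC%d (%.0f%% variance)", i,
                             100 * object$var_fraction[i])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("condition" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$condition),
                                 size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = pct(1), y = pct(2)) + ggplot2::theme_minimal()
}

#' Plot a t-SNE embedding of candidate genes
#'
#' @param object A [tsne_embed()] result.
#' @param color Optional per-gene tibble `gene_id`, `value` overlaid as
#'   point color (e.g. an effect L2FC or a similarity column).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shutoff_tsne
#' @export
autoplot.shutoff_tsne <- function(object, color = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(color)) {
    stopifnot(all(c("gene_id", "value") %in% names(color)))
    d <- dplyr::left_join(d, color, by = "gene_id")
    ggplot2::ggplot(d, ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                                    color = .data$value)) +
      ggplot2::geom_point(size = 1) +
      ggplot2::scale_color_gradient2(low = "blue", mid = "grey85",
                                     high = "red", midpoint = 0) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$tsne1, y = .data$tsne2)) +
      ggplot2::geom_point(size = 1) +
      ggplot2::theme_minimal()
  }
}

#' Bar chart of shut-off categories
#'
#' @param object An [overlap_summary()] result.
#' @param ... Unused.
#' @return A ggplot of category counts over evaluable induced genes.
#' @method autoplot shutoff_overlap
#' @export
autoplot.shutoff_overlap <- function(object, ...) {
  d <- object$categories
  d$category <- factor(d$category, levels = d$category)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' Diverging bar chart of the shut-off ranking
#'
#' @param ranking A [build_ranking()] tibble.
#' @return A ggplot of total shut-off percentages, strongest first.
#' @export
plot_shutoff_ranking <- function(ranking) {
  d <- ranking
  d$gene_id <- factor(d$gene_id, levels = rev(d$gene_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$shutoff_pct, y = .data$gene_id,
                                  fill = .data$induction_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "total shut-off (%)", y = NULL) +
    ggplot2::theme_minimal()
}
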