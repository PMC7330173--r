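#' Volcano plot of a phenotype scan
#'
#' Log2 fold change against -log10 p-value, nominal hits highlighted.
#'
#' @param object A [run_platform_scan()] or [ald_vs_control_scan()]
#'   result.
#' @param p_threshold Highlight cutoff on the nominal p-value.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modifier_scan <- function(object, p_threshold = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$p_value), ]
  d$hit <- d$p_value < p_threshold
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (CALD / non-CALD)",
                  y = expression(-log[10] ~ p),
                  title = paste0(attr(object, "platform"), " scan")) +
    ggplot2::theme_minimal()
}

#' Bar chart of an exact upset partition
#'
#' One bar per intersection cell (combination of sets), faceted by
#' category, ordered by decreasing depth then count.
#'
#' @param x An `upset_partition`.
#' @param max_cells Show at most this many cells per category.
#' @return A ggplot object.
#' @export
plot_upset_partition <- function(x, max_cells = 30) {
  d <- x$partition
  d <- dplyr::slice_head(
    dplyr::group_by(dplyr::arrange(d, dplyr::desc(.data$degree),
                                   dplyr::desc(.data$n)),
                    .data$category),
    n = max_cells)
  d <- dplyr::ungroup(d)
  d$families <- factor(d$families, levels = unique(d$families))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$families, y = .data$n,
                                  fill = factor(.data$degree))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free") +
    ggplot2::labs(x = "set combination", y = "variants", fill = "depth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Distribution of variance fractions across features
#'
#' Boxplots of the per-feature variance fractions of each model
#' component.
#'
#' @param fractions A [partition_variance_scan()] result.
#' @return A ggplot object.
#' @export
plot_variance_fractions <- function(fractions) {
  d <- tibble::as_tibble(fractions)
  d <- d[!d$undefined, ]
  long <- tidyr::pivot_longer(
    d, cols = dplyr::any_of(c("family", "age", "phenotype",
                              "phenotype_age", "residual")),
    names_to = "component", values_to = "fraction")
  long <- long[!is.na(long$fraction), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component,
                                     y = .data$fraction)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "fraction of variance") +
    ggplot2::theme_minimal()
}

#' Family score plot of a fold-change PCA
#'
#' @param object A [pca_cluster()] result.
#' @param ... Unused.
#' @return A ggplot object of the first two components, coloured by
#'   cluster.
#' @export
autoplot.family_pca <- function(object, ...) {
  d <- dplyr::left_join(object$scores, object$clusters, by = "family")
  ycol <- if ("PC2" %in% names(d)) "PC2" else "PC1"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data[[ycol]],
                                  colour = factor(.data$cluster),
                                  label = .data$family)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::labs(colour = "cluster",
                  x = sprintf("PC1 (%.0f%%)",
                              100 * object$explained_variance[1]),
                  y = if (ycol == "PC2")
                    sprintf("PC2 (%.0f%%)",
                            100 * object$explained_variance[2]) else ycol) +
    ggplot2::theme_minimal()
}
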