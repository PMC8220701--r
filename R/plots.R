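#' Volcano plot of a DE table
#'
#' @param object A `de_table` from [de_test()].
#' @param ... Unused.
#' @return A ggplot object: one panel per line, -log10 adjusted p against
#'   logFC, flagged genes highlighted.
#' @export
autoplot.de_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$logFC,
                               y = -log10(pmax(.data$adj_p, 1e-300)),
                               colour = .data$de_flag)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~line) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change vs reference",
                  y = "-log10 adjusted p", colour = "DE") +
    ggplot2::theme_bw()
}

#' PCA quality-control plot
#'
#' @param object A `pca_qc` object.
#' @param ... Unused.
#' @return A ggplot object of the first two principal-component scores,
#'   coloured by line.
#' @export
autoplot.pca_qc <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$line)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_bw()
}

#' Group size bar plot
#'
#' @param groups Output of [classify_groups()].
#' @return A ggplot object: labeled gene counts per group, cores stacked.
#' @export
plot_group_sizes <- function(groups) {
  gs <- group_sizes(groups) %>%
    dplyr::filter(.data$label != "none") %>%
    tidyr::pivot_longer(c("n", "n_core"), names_to = "set",
                        values_to = "count") %>%
    dplyr::mutate(set = ifelse(.data$set == "n", "group", "core"))
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$label, y = .data$count,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "group", y = "genes", fill = NULL) +
    ggplot2::theme_bw()
}

#' Enrichment dot plot
#'
#' @param enrichment Tibble from [hypergeom_enrich()].
#' @param top Number of top terms to show.
#' @return A ggplot object: terms against -log10 adjusted p, dot size the
#'   overlap count.
#' @export
plot_enrichment <- function(enrichment, top = 20L) {
  df <- utils::head(dplyr::arrange(enrichment, .data$adj_p), top)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$adj_p, 1e-300)), y = .data$term,
    size = .data$k)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL, size = "overlap") +
    ggplot2::theme_bw()
}

#' Subnetwork layout plot
#'
#' @param object A `subnetwork_set`.
#' @param ... Unused.
#' @return A ggplot object: force-directed layout of the final components;
#'   seeds coloured by group label, connectors grey.
#' @export
autoplot.subnetwork_set <- function(object, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty subnetwork set"))
  }
  g <- igraph::graph_from_data_frame(
    object$edges[, c("source", "target")], directed = FALSE,
    vertices = object$nodes$gene)
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  seg <- dplyr::left_join(
    object$edges, nodes[, c("gene", "x", "y")],
    by = c(source = "gene")) %>%
    dplyr::left_join(nodes[, c("gene", "x", "y")],
                     by = c(target = "gene"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$label,
                                     shape = .data$connector),
                        size = 2) +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "group", shape = "connector")
}

#' Feedback trend plot
#'
#' @param object A `feedback_trend` object.
#' @param ... Unused.
#' @return A ggplot object: mean |logFC| of the gene set against the
#'   phenotypic suppression rank.
#' @export
autoplot.feedback_trend <- function(object, ...) {
  ggplot2::ggplot(object$per_line,
                  ggplot2::aes(x = .data$rank,
                               y = .data$mean_abs_logfc)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$line), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = "suppression rank (1 = best)",
                  y = "mean |logFC| of gene set") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
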