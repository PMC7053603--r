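#' Volcano plot of a differential-expression table
#'
#' @param de DE tibble from [fit_de()]/[apply_de_thresholds()].
#' @param p_field Which p-value to plot on the y axis.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, p_field = c("adjusted", "raw")) {
  p_field <- match.arg(p_field)
  pv <- if (p_field == "adjusted") de$adj_p else de$p
  df <- mutate(de, neglog_p = -log10(pmax(pv, .Machine$double.xmin)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC, y = .data$neglog_p,
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (tumour - normal)",
                  y = sprintf("-log10 %s p", p_field), colour = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param x A `cerna_roc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_roc <- function(x, ...) {
  ggplot2::ggplot(x$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", x$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cerna_roc
#' @param roc A `cerna_roc` object.
#' @export
plot_roc <- function(roc) autoplot.cerna_roc(roc)

#' ceRNA network plot
#'
#' Lays the network out with a force-directed algorithm (via igraph) and
#' draws regulatory edges solid, coexpression edges dashed; node shape
#' encodes molecule kind, colour the regulation direction, size the degree.
#'
#' @param x A `cerna_network` object.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_network <- function(x, seed = 1L, ...) {
  if (nrow(x$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  g <- igraph::graph_from_data_frame(
    x$edges[, c("source", "target")], directed = FALSE,
    vertices = x$nodes$id)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- mutate(x$nodes, x = xy[, 1], y = xy[, 2])
  pos <- setNames(seq_len(nrow(nodes)), nodes$id)
  edges <- mutate(x$edges,
                  x = nodes$x[pos[.data$source]],
                  y = nodes$y[pos[.data$source]],
                  xend = nodes$x[pos[.data$target]],
                  yend = nodes$y[pos[.data$target]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linetype = .data$edge_kind),
                          colour = "grey55") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$node_kind,
                                     colour = .data$direction,
                                     size = .data$degree)) +
    ggplot2::scale_linetype_manual(values = c(mir_lnc = "solid",
                                              mir_mrna = "solid",
                                              lnc_mrna_coexpr = "dashed")) +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            undetermined = "grey50")) +
    ggplot2::theme_void()
}

#' @rdname autoplot.cerna_network
#' @param network A `cerna_network` object.
#' @export
plot_network <- function(network, seed = 1L) autoplot.cerna_network(network, seed)

#' Enrichment dot plot
#'
#' @param enrichment Tibble from [enrich_sets()].
#' @param top Number of top sets (by p) to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 15L) {
  df <- head(arrange(enrichment, .data$p), top)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p), y = .data$set_name,
                                   size = .data$k, colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 p", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}
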