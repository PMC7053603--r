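#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' Tidy and glance methods for ceRNA result objects
#'
#' `tidy()` returns the row-level content of a result object as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A `cerna_roc`, `cerna_network` or `cerna_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @name cernetr-tidiers
NULL

#' @rdname cernetr-tidiers
#' @export
tidy.cerna_roc <- function(x, ...) x$curve

#' @rdname cernetr-tidiers
#' @export
glance.cerna_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
         positive = x$positive)
}

#' @rdname cernetr-tidiers
#' @export
tidy.cerna_network <- function(x, ...) x$nodes

#' @rdname cernetr-tidiers
#' @export
glance.cerna_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_mrna = sum(x$nodes$node_kind == "mRNA"),
         n_lncrna = sum(x$nodes$node_kind == "lncRNA"),
         n_mirna = sum(x$nodes$node_kind == "miRNA"),
         max_degree = if (nrow(x$nodes)) max(x$nodes$degree) else 0L)
}

#' @rdname cernetr-tidiers
#' @export
tidy.cerna_run <- function(x, ...) x$triples

#' @rdname cernetr-tidiers
#' @export
glance.cerna_run <- function(x, ...) {
  as_tibble(as.list(x$manifest$counts))
}
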