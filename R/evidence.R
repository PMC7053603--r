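#' Filter a target-evidence table by multi-source support
#'
#' Keeps miRNA--mRNA pairs flagged by at least `min_sources` of the
#' prediction sources (inclusive: "at least six of twelve" keeps support 6).
#'
#' @param evidence Evidence tibble: `mirna_id`, `mrna_id`, one 0/1 column
#'   per source; a `support` column (flag sum) is recomputed if absent.
#' @param min_sources Minimum number of supporting sources (default 6).
#' @return Tibble of kept pairs: `mirna_id`, `mrna_id`, `support`.
#' @export
#' @examples
#' ev <- tibble::tibble(mirna_id = c("m1", "m2"), mrna_id = c("g1", "g2"),
#'                      s1 = c(1, 0), s2 = c(1, 0), support = c(2L, 0L))
#' filter_evidence(ev, min_sources = 2)
filter_evidence <- function(evidence, min_sources = 6L) {
  check_count(min_sources, "min_sources", min = 1L)
  if (!all(c("mirna_id", "mrna_id") %in% names(evidence))) {
    stop_input("evidence table must carry mirna_id and mrna_id columns")
  }
  src_cols <- setdiff(names(evidence), c("mirna_id", "mrna_id", "support"))
  n_sources <- length(src_cols)
  if ("support" %in% names(evidence) && n_sources == 0L) {
    n_sources <- max(evidence$support, min_sources)
  } else {
    flags <- as.matrix(evidence[src_cols])
    if (!all(flags %in% c(0, 1))) {
      stop_input("evidence source columns must be 0/1 presence flags")
    }
    evidence$support <- as.integer(rowSums(flags))
    if (min_sources > n_sources) {
      stop_config(sprintf("min_sources (%d) exceeds the number of sources (%d)",
                          min_sources, n_sources))
    }
  }
  if (anyDuplicated(evidence[, c("mirna_id", "mrna_id")])) {
    stop_input("(mirna_id, mrna_id) pairs must be unique in the evidence table")
  }
  evidence |>
    filter(.data$support >= min_sources) |>
    select("mirna_id", "mrna_id", "support") |>
    arrange(.data$mirna_id, .data$mrna_id)
}

#' Intersect predicted target pairs with negatively correlated pairs
#'
#' Keeps the miRNA--mRNA pairs present both in the evidence-supported
#' prediction list and in the expression-based negative-correlation list;
#' the output carries the support count and the correlation.
#'
#' @param predicted Pair tibble from [filter_evidence()] (`mirna_id`,
#'   `mrna_id`, optionally `support`).
#' @param correlated Correlation pairs of kind `mir_mrna` from
#'   [screen_correlations()] (`a_id` = miRNA, `b_id` = mRNA).
#' @return Tibble: `mirna_id`, `mrna_id`, `support`, `r`, `p`, `n`.
#' @export
intersect_targets <- function(predicted, correlated) {
  if (nrow(correlated) > 0 && "pair_kind" %in% names(correlated) &&
      !all(correlated$pair_kind == "mir_mrna")) {
    stop_input("`correlated` must contain mir_mrna pairs only")
  }
  corr <- correlated |>
    rename(mirna_id = "a_id", mrna_id = "b_id") |>
    select(dplyr::any_of(c("mirna_id", "mrna_id", "r", "p", "n")))
  predicted |>
    inner_join(corr, by = c("mirna_id", "mrna_id")) |>
    arrange(.data$mirna_id, .data$mrna_id)
}
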