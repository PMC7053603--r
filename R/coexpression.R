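#' Pearson correlation of all feature pairs across two expression tables
#'
#' Computes the sample Pearson correlation for every (feature in `expr_a`,
#' feature in `expr_b`) pair over the shared, identically ordered samples,
#' together with the two-sided significance from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (p is 0 when |r| = 1).
#'
#' @param expr_a,expr_b Expression tibbles (`feature_id` + sample columns)
#'   sharing the same sample columns in the same order.
#' @param pair_kind `"lnc_mrna"` or `"mir_mrna"`; recorded on each pair.
#' @param features_a,features_b Optional feature subsets (e.g. the
#'   differentially expressed features) to restrict the pair universe.
#' @return Tibble of pairs: `a_id`, `b_id`, `pair_kind`, `r`, `p`, `n`.
#'   Zero-variance features are skipped with a warning.
#' @export
correlate_pairs <- function(expr_a, expr_b,
                            pair_kind = c("lnc_mrna", "mir_mrna"),
                            features_a = NULL, features_b = NULL) {
  pair_kind <- match.arg(pair_kind)
  ma <- expr_to_matrix(expr_a)
  mb <- expr_to_matrix(expr_b)
  if (!identical(colnames(ma), colnames(mb))) {
    stop_input("expression tables must share an identical ordered sample list")
  }
  if (!is.null(features_a)) ma <- ma[rownames(ma) %in% features_a, , drop = FALSE]
  if (!is.null(features_b)) mb <- mb[rownames(mb) %in% features_b, , drop = FALSE]
  n <- ncol(ma)
  if (n < 3L) stop_input("need at least 3 shared samples for correlation")

  sda <- apply(ma, 1L, sd)
  sdb <- apply(mb, 1L, sd)
  if (any(sda == 0) || any(sdb == 0)) {
    warn(sprintf("skipping %d zero-variance feature(s)",
                 sum(sda == 0) + sum(sdb == 0)))
    ma <- ma[sda > 0, , drop = FALSE]
    mb <- mb[sdb > 0, , drop = FALSE]
  }
  if (nrow(ma) == 0 || nrow(mb) == 0) {
    return(tibble(a_id = character(0), b_id = character(0),
                  pair_kind = character(0), r = numeric(0), p = numeric(0),
                  n = integer(0)))
  }

  rmat <- cor(t(ma), t(mb))
  out <- tibble(
    a_id = rep(rownames(ma), times = ncol(rmat)),
    b_id = rep(colnames(rmat), each = nrow(rmat)),
    pair_kind = pair_kind,
    r = as.vector(rmat),
    n = n
  )
  out$p <- pearson_p(out$r, n)
  arrange(select(out, "a_id", "b_id", "pair_kind", "r", "p", "n"),
          .data$a_id, .data$b_id)
}

# Two-sided p for a sample Pearson r on n observations via the t transform.
pearson_p <- function(r, n) {
  # clamp tiny floating-point excursions beyond +/-1 from cor()
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0, {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  })
  p
}

#' Screen correlation pairs under the coexpression rules
#'
#' `mode = "positive_synergy"` keeps pairs with r > r_min and p < p_max
#' (both strict) — the lncRNA--mRNA synergy rule. `mode = "negative_only"`
#' keeps pairs with r < 0 and applies no p-value filter — the
#' miRNA--mRNA inverse-regulation rule (a p filter can be opted in via
#' `p_max`).
#'
#' @param pairs Tibble of correlation pairs from [correlate_pairs()].
#' @param mode Screening mode.
#' @param r_min Strict lower bound on r (positive_synergy only).
#' @param p_max Strict upper bound on p; default `NULL` in negative_only
#'   mode (no filter), 0.05 in positive_synergy mode.
#' @return The kept pairs.
#' @export
#' @examples
#' pairs <- tibble::tibble(a_id = "l1", b_id = "g1", pair_kind = "lnc_mrna",
#'                         r = 0.75, p = 0.01, n = 20)
#' screen_correlations(pairs, "positive_synergy")
screen_correlations <- function(pairs,
                                mode = c("positive_synergy", "negative_only"),
                                r_min = 0.7, p_max = NULL) {
  mode <- match.arg(mode)
  if (mode == "positive_synergy") {
    p_max <- p_max %||% 0.05
    check_number(r_min, "r_min", min = 0, max = 1, strict_min = TRUE)
    check_number(p_max, "p_max", min = 0, max = 1, strict_min = TRUE)
    filter(pairs, .data$r > r_min, .data$p < p_max)
  } else {
    out <- filter(pairs, .data$r < 0)
    if (!is.null(p_max)) out <- filter(out, .data$p < p_max)
    out
  }
}

#' Intersect correlation-pair sets across datasets
#'
#' Keeps the pairs (keyed on `(a_id, b_id)`) present in every supplied set;
#' the retained record carries one r column per dataset (`r_<name>`), the
#' maximum p and the per-set sample counts.
#'
#' @param pair_sets Named list of pair tibbles (one per dataset).
#' @return Tibble of pairs present in all sets.
#' @export
intersect_correlations <- function(pair_sets) {
  if (!is.list(pair_sets) || length(pair_sets) == 0 || is.data.frame(pair_sets)) {
    stop_input("`pair_sets` must be a non-empty list of pair tables")
  }
  nm <- names(pair_sets) %||% sprintf("set%d", seq_along(pair_sets))
  nm[nm == ""] <- sprintf("set%d", which(nm == ""))
  keyed <- map2(pair_sets, nm, function(s, id) {
    s <- select(s, "a_id", "b_id", "pair_kind", "r", "p", "n")
    names(s)[4:6] <- paste0(c("r_", "p_", "n_"), id)
    s
  })
  out <- purrr::reduce(keyed, function(x, y) {
    inner_join(x, y, by = c("a_id", "b_id", "pair_kind"))
  })
  arrange(out, .data$a_id, .data$b_id)
}
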