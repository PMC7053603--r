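#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT dialect (set name, description, then member
#' genes) into a long tibble.
#'
#' @param path Path to a `.gmt` file.
#' @param category Category label recorded on every set (e.g.
#'   `"GOTERM_BP"`, `"KEGG_PATHWAY"`); defaults to the file name stem.
#' @return Tibble with `set_name`, `category`, `gene`.
#' @export
read_gmt <- function(path, category = NULL) {
  if (!file.exists(path)) stop_input(sprintf("GMT file not found: %s", path))
  category <- category %||% sub("\\.gmt$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop_input(sprintf("malformed GMT line (need name, description, >=1 gene): %s",
                         substr(l, 1, 40)))
    }
    tibble(set_name = f[1], category = category, gene = unique(f[-(1:2)]))
  })
  bind_rows(rows)
}

# Upper-tail hypergeometric probability P(X >= k) for X ~ Hyper(N, K, n).
hyper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis (hypergeometric / EASE)
#'
#' For each gene set, tests whether the query over-represents the set
#' within the universe. The hypergeometric method computes the exact upper
#' tail `P(X >= k)`; the EASE variant (the DAVID convention, default)
#' conservatively replaces the overlap `k` by `max(k - 1, 0)` before taking
#' the tail. P-values are BH-adjusted within each category.
#'
#' @param query Character vector of query gene ids (must lie within the
#'   universe).
#' @param collections Gene-set tibble from [read_gmt()] (`set_name`,
#'   `category`, `gene`), or a list of such tibbles.
#' @param universe Character vector of background gene ids; defaults to the
#'   union of all collection members. Sets are intersected with the
#'   universe before sizing.
#' @param method `"ease"` or `"hypergeometric"`.
#' @return Tibble sorted by p: `set_name`, `category`, `k`, `overlap_genes`
#'   (comma-joined), `K`, `n`, `N`, `p`, `adj_p`, `method`.
#' @export
enrich_sets <- function(query, collections, universe = NULL,
                        method = c("ease", "hypergeometric")) {
  method <- match.arg(method)
  if (is.list(collections) && !is.data.frame(collections)) {
    collections <- bind_rows(collections)
  }
  if (!all(c("set_name", "category", "gene") %in% names(collections))) {
    stop_input("collections must carry set_name, category and gene columns")
  }
  universe <- unique(universe %||% collections$gene)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop_input(sprintf("%d query gene(s) are not in the universe",
                       sum(!query %in% universe)))
  }
  N <- length(universe)
  n <- length(query)
  res <- collections |>
    filter(.data$gene %in% universe) |>
    group_by(.data$set_name, .data$category) |>
    summarise(K = dplyr::n_distinct(.data$gene),
              overlap_genes = paste(sort(intersect(unique(.data$gene), query)),
                                    collapse = ","),
              k = length(intersect(unique(.data$gene), query)),
              .groups = "drop")
  if (nrow(res) == 0) {
    return(tibble(set_name = character(0), category = character(0),
                  k = integer(0), overlap_genes = character(0), K = integer(0),
                  n = integer(0), N = integer(0), p = numeric(0),
                  adj_p = numeric(0), method = character(0)))
  }
  k_eff <- if (method == "ease") pmax(res$k - 1L, 0L) else res$k
  res$p <- map_dbl(seq_len(nrow(res)), function(i) {
    hyper_tail(k_eff[i], N, res$K[i], n)
  })
  res |>
    mutate(n = n, N = N, method = method) |>
    group_by(.data$category) |>
    mutate(adj_p = adjust_bh(.data$p)) |>
    ungroup() |>
    select("set_name", "category", "k", "overlap_genes", "K", "n", "N",
           "p", "adj_p", "method") |>
    arrange(.data$p, .data$set_name)
}

#' ROC curve and AUC for a diagnostic score
#'
#' Builds the ROC curve over all distinct score thresholds and computes the
#' area under it by the trapezoid rule, which (with ties credited 0.5)
#' equals the Mann-Whitney statistic `U / (n_pos * n_neg)`. The score
#' orientation is explicit: no automatic direction flipping is performed.
#'
#' @param data Data frame holding scores and class labels.
#' @param score,label Column names (strings) of the numeric score and the
#'   class label.
#' @param positive Label value treated as the positive class; defaults to
#'   the lexicographically larger unique label.
#' @param positive_is_high If `TRUE` (default) larger scores indicate the
#'   positive class.
#' @return A `cerna_roc` object with elements `curve` (tibble `threshold`,
#'   `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' d <- data.frame(s = c(3, 2, 1, 2), y = c("pos", "pos", "neg", "neg"))
#' roc_auc(d, "s", "y", positive = "pos")$auc
roc_auc <- function(data, score = "score", label = "label", positive = NULL,
                    positive_is_high = TRUE) {
  if (!is.data.frame(data) || !all(c(score, label) %in% names(data))) {
    stop_input("`data` must contain the score and label columns")
  }
  s <- data[[score]]
  y <- as.character(data[[label]])
  if (any(!is.finite(s))) stop_input("scores must be finite")
  lv <- sort(unique(y))
  positive <- positive %||% lv[length(lv)]
  pos <- y == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop_input("both classes must be non-empty for ROC analysis")
  }
  if (!positive_is_high) s <- -s

  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(s[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!pos] >= t), numeric(1))
  curve <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1) {
    curve <- bind_rows(curve, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 positive = positive),
            class = "cerna_roc")
}

#' @export
print.cerna_roc <- function(x, ...) {
  cat(sprintf("<cerna_roc> AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Merge tumour T-stages into early/advanced groups
#'
#' T1 and T2 tumours form the early group; T3 tumours the advanced group.
#'
#' @param stages Character vector of stage labels (whitespace and case are
#'   normalised).
#' @return Character vector over `{"early", "advanced"}`.
#' @export
#' @examples
#' group_stages(c("T1", "T2", "T3"))
group_stages <- function(stages) {
  norm <- toupper(trimws(as.character(stages)))
  bad <- setdiff(unique(norm), c("T1", "T2", "T3"))
  if (length(bad) > 0) {
    stop_input(sprintf("unmapped stage label(s): %s",
                       paste(bad, collapse = ", ")))
  }
  ifelse(norm == "T3", "advanced", "early")
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddct_fold_change()` takes the four Ct values of one case/control
#' comparison; `ddct_from_table()` averages the per-sample delta-Ct
#' (target minus reference) within each group before differencing.
#' Delta-delta-Ct is case minus control and the fold change is
#' `2^-ddCt`.
#'
#' @param ct_target_case,ct_ref_case,ct_target_control,ct_ref_control
#'   Finite Ct values.
#' @return Tibble: `delta_ct_case`, `delta_ct_control`, `ddct`, `fold`.
#' @export
#' @examples
#' ddct_fold_change(25, 20, 24, 21)  # ddct = 2, fold = 0.25
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_control, ct_ref_control) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_control, ct_ref_control)
  if (!all(is.finite(vals))) stop_input("Ct values must be finite")
  d_case <- ct_target_case - ct_ref_case
  d_ctrl <- ct_target_control - ct_ref_control
  ddct <- d_case - d_ctrl
  tibble(delta_ct_case = d_case, delta_ct_control = d_ctrl, ddct = ddct,
         fold = 2^(-ddct))
}

#' @rdname ddct_fold_change
#' @param ct_table Tibble with `group` (`"case"`/`"control"`), `ct_target`
#'   and `ct_ref` columns (one row per sample), as produced by
#'   [simulate_validation_tables()].
#' @export
ddct_from_table <- function(ct_table) {
  req <- c("group", "ct_target", "ct_ref")
  if (!is.data.frame(ct_table) || !all(req %in% names(ct_table))) {
    stop_input("Ct table must carry group, ct_target and ct_ref columns")
  }
  if (!all(ct_table$group %in% c("case", "control"))) {
    stop_input("Ct table group must be 'case' or 'control'")
  }
  dct <- ct_table |>
    mutate(dct = .data$ct_target - .data$ct_ref) |>
    group_by(.data$group) |>
    summarise(mean_dct = mean(.data$dct), .groups = "drop")
  ddct_fold_change(dct$mean_dct[dct$group == "case"], 0,
                   dct$mean_dct[dct$group == "control"], 0)
}

#' Two-group comparison of expression or fold values
#'
#' Convenience wrapper for the unpaired two-sided t-test used to compare
#' two groups of measurements.
#'
#' @param x,y Numeric vectors for the two groups.
#' @return Tibble with `estimate` (mean difference x - y), `t_stat`, `df`,
#'   `p`.
#' @export
compare_groups <- function(x, y) {
  ht <- t.test(x, y, var.equal = FALSE)
  tibble(estimate = unname(ht$estimate[1] - ht$estimate[2]),
         t_stat = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}
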