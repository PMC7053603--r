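#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up false-discovery-rate
#' adjustment, returning adjusted values in the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted p-values, capped at 1.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03))
adjust_bh <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
      any(pvals < 0) || any(pvals > 1)) {
    stop_input("p-values must be numeric, non-missing and in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Named per-dataset differential-expression threshold presets
#'
#' Threshold presets for the five study accessions, as `(p_field, p_max,
#' abs_logfc_min)` triples per molecule kind. `de_thresholds()` builds a
#' single threshold object; `de_threshold_presets()` returns the shipped
#' table of presets.
#'
#' @param p_field Which p-value column gates significance: `"adjusted"`
#'   (BH) or `"raw"`.
#' @param p_max Strict upper bound on the chosen p-value.
#' @param abs_logfc_min Strict lower bound on |logFC| (log2 units).
#' @return `de_thresholds()`: a `cerna_de_thresholds` list.
#' @export
#' @examples
#' de_thresholds("adjusted", 0.05, 1)
de_thresholds <- function(p_field = c("adjusted", "raw"), p_max = 0.05,
                          abs_logfc_min = 1) {
  p_field <- match.arg(p_field)
  check_number(p_max, "p_max", min = 0, max = 1, strict_min = TRUE)
  check_number(abs_logfc_min, "abs_logfc_min", min = 0)
  structure(list(p_field = p_field, p_max = p_max,
                 abs_logfc_min = abs_logfc_min),
            class = "cerna_de_thresholds")
}

#' @rdname de_thresholds
#' @return `de_threshold_presets()`: a tibble with one row per
#'   (accession, molecule kind) pair and the threshold fields.
#' @export
de_threshold_presets <- function() {
  tibble::tribble(
    ~accession,  ~kind,     ~p_field,   ~p_max, ~abs_logfc_min,
    "GSE61850",  "mrna",    "adjusted", 0.05,   1,
    "GSE61850",  "lncrna",  "adjusted", 0.05,   1,
    "GSE103909", "mrna",    "raw",      0.05,   0.585,
    "GSE103909", "lncrna",  "raw",      0.05,   0.585,
    "GSE57555",  "mrna",    "adjusted", 0.05,   1,
    "GSE57555",  "mirna",   "raw",      0.05,   0.263,
    "GSE53992",  "mirna",   "raw",      0.05,   0,
    "GSE53870",  "mirna",   "adjusted", 0.05,   0.585
  )
}

# Per-feature effect and residual variance for a paired or two-group design.
# Returns logFC, s2 (residual variance), df and the unscaled standard error
# factor u such that se = sqrt(s2) * u.
de_effects <- function(m, metadata, design) {
  tum <- metadata$condition == "tumor"
  if (design == "paired") {
    subj <- unique(metadata$subject_id)
    if (length(subj) < 2L) {
      stop_input("paired design needs at least 2 subject pairs")
    }
    t_cols <- which(tum)[match(subj, metadata$subject_id[tum])]
    n_cols <- which(!tum)[match(subj, metadata$subject_id[!tum])]
    diffs <- m[, t_cols, drop = FALSE] - m[, n_cols, drop = FALSE]
    n <- length(subj)
    list(logFC = rowMeans(diffs),
         s2 = apply(diffs, 1L, var),
         df = n - 1L,
         u = 1 / sqrt(n))
  } else {
    n1 <- sum(tum); n2 <- sum(!tum)
    if (n1 < 2L || n2 < 2L) {
      stop_input("group design needs at least 2 samples per condition")
    }
    mt <- m[, tum, drop = FALSE]; mn <- m[, !tum, drop = FALSE]
    s2 <- ((n1 - 1) * apply(mt, 1L, var) + (n2 - 1) * apply(mn, 1L, var)) /
      (n1 + n2 - 2)
    list(logFC = rowMeans(mt) - rowMeans(mn),
         s2 = s2,
         df = n1 + n2 - 2L,
         u = sqrt(1 / n1 + 1 / n2))
  }
}

#' Per-dataset differential expression with moderated t-statistics
#'
#' Fits tumour-vs-normal differential expression for one expression table.
#' The effect is the log2 fold change (tumour minus normal; for paired
#' designs the mean of within-pair differences). With `moderation = TRUE`
#' (default) the residual variances are shrunk towards an empirical-Bayes
#' prior: the prior degrees of freedom and variance are estimated from the
#' variance distribution across features (or supplied directly), the
#' posterior variance is the df-weighted average of prior and observed
#' variance, and the t-statistic is referred to a t distribution with
#' augmented degrees of freedom. With `moderation = FALSE` the ordinary
#' paired/group t-test is used.
#'
#' @param expr Expression tibble: `feature_id` plus one numeric log2 column
#'   per sample.
#' @param metadata Sample metadata tibble with `sample_id`, `subject_id`,
#'   `condition` (`"tumor"`/`"normal"`).
#' @param kind Molecule kind of the features (`"mrna"`, `"lncrna"`,
#'   `"mirna"`).
#' @param design `"paired"` (one tumour and one normal sample per subject)
#'   or `"group"`.
#' @param moderation Apply empirical-Bayes variance moderation?
#' @param prior_df,prior_var Optional prior degrees of freedom and variance
#'   overriding the data-driven estimate; `prior_df = Inf` fixes the
#'   posterior variance at `prior_var`.
#' @return Tibble with one row per feature: `feature_id`, `kind`, `logFC`,
#'   `t_stat`, `p`, `adj_p`, `direction` (all `"ns"`; see
#'   [apply_de_thresholds()]).
#' @export
fit_de <- function(expr, metadata, kind = "mrna",
                   design = c("paired", "group"),
                   moderation = TRUE, prior_df = NULL, prior_var = NULL) {
  design <- match.arg(design)
  m <- expr_to_matrix(expr)
  md <- check_metadata(metadata, colnames(m), design)
  eff <- de_effects(m, md, design)

  if (moderation) {
    if (is.null(prior_df) || is.null(prior_var)) {
      fd <- limma::fitFDist(eff$s2, df1 = eff$df)
      prior_df <- prior_df %||% fd$df2
      prior_var <- prior_var %||% fd$scale
    }
    if (is.infinite(prior_df)) {
      post_var <- rep(prior_var, length(eff$s2))
      df_total <- Inf
    } else {
      post_var <- (prior_df * prior_var + eff$df * eff$s2) /
        (prior_df + eff$df)
      df_total <- eff$df + prior_df
    }
    t_stat <- eff$logFC / (sqrt(post_var) * eff$u)
    p <- 2 * pt(-abs(t_stat), df = df_total)
  } else {
    zero <- eff$s2 == 0
    t_stat <- eff$logFC / (sqrt(eff$s2) * eff$u)
    p <- 2 * pt(-abs(t_stat), df = eff$df)
    if (any(zero)) {
      warn(sprintf("%d feature(s) with zero residual variance; p set to 0 (|logFC|>0) or 1 (logFC=0)",
                   sum(zero)))
      p[zero] <- ifelse(eff$logFC[zero] == 0, 1, 0)
      t_stat[zero] <- ifelse(eff$logFC[zero] == 0, 0,
                             sign(eff$logFC[zero]) * Inf)
    }
  }

  tibble(feature_id = rownames(m), kind = kind,
         logFC = unname(eff$logFC), t_stat = unname(t_stat),
         p = unname(p), adj_p = adjust_bh(unname(p)), direction = "ns")
}

#' Call differential-expression directions under thresholds
#'
#' Sets `direction` to `"up"` when the chosen p-value is strictly below
#' `p_max` and `logFC` strictly above `abs_logfc_min`, `"down"` for the
#' mirrored condition, and `"ns"` otherwise. Inequalities are strict.
#'
#' @param de A DE tibble from [fit_de()].
#' @param thresholds A [de_thresholds()] object.
#' @return The DE tibble with `direction` filled in.
#' @export
#' @examples
#' de <- tibble::tibble(feature_id = "g1", kind = "mrna", logFC = 1.2,
#'                      t_stat = 5, p = 0.001, adj_p = 0.01, direction = "ns")
#' apply_de_thresholds(de, de_thresholds("adjusted", 0.05, 1))
apply_de_thresholds <- function(de, thresholds) {
  if (!inherits(thresholds, "cerna_de_thresholds")) {
    stop_config("`thresholds` must be created with de_thresholds()")
  }
  if (!all(c("logFC", "p", "adj_p") %in% names(de))) {
    stop_input("DE table must carry logFC, p and adj_p columns")
  }
  pv <- if (thresholds$p_field == "adjusted") de$adj_p else de$p
  mutate(de, direction = dplyr::case_when(
    pv < thresholds$p_max & .data$logFC > thresholds$abs_logfc_min ~ "up",
    pv < thresholds$p_max & .data$logFC < -thresholds$abs_logfc_min ~ "down",
    TRUE ~ "ns"
  ))
}

#' Cross-dataset consensus of differential-expression calls
#'
#' A feature belongs to the consensus set of its molecule kind when it is
#' significant (direction not `"ns"`) in every supplied dataset profiling
#' that kind. Features whose significant directions conflict across datasets
#' are flagged `consistent = FALSE` and get `consensus_direction =
#' "undetermined"`; downstream assembly excludes or retains them according
#' to per-kind policy (see [resolve_directions()]).
#'
#' @param de_tables A tibble of thresholded DE records carrying a
#'   `dataset_id` column (rows from several [fit_de()] +
#'   [apply_de_thresholds()] runs bound together), or a named list of such
#'   tibbles (names become `dataset_id`).
#' @return Tibble with one row per consensus feature: `feature_id`, `kind`,
#'   `n_datasets`, `directions` (comma-joined per-dataset map),
#'   `consistent`, `consensus_direction`.
#' @export
consensus_de <- function(de_tables) {
  if (is.data.frame(de_tables)) {
    combined <- de_tables
  } else if (is.list(de_tables) && length(de_tables) > 0) {
    if (is.null(names(de_tables)) || any(names(de_tables) == "")) {
      stop_input("list input to consensus_de() must be named by dataset_id")
    }
    combined <- bind_rows(imap(de_tables, function(d, id) {
      mutate(d, dataset_id = id)
    }))
  } else {
    stop_input("`de_tables` must be a non-empty data frame or named list")
  }
  if (nrow(combined) == 0) stop_input("no DE records supplied")
  if (!"dataset_id" %in% names(combined)) {
    stop_input("DE records must carry a dataset_id column")
  }

  per_kind_n <- combined |>
    distinct(.data$kind, .data$dataset_id) |>
    dplyr::count(.data$kind, name = "n_datasets_kind")

  combined |>
    group_by(.data$kind, .data$feature_id) |>
    summarise(
      n_datasets = dplyr::n_distinct(.data$dataset_id),
      n_sig = sum(.data$direction != "ns"),
      directions = paste(sprintf("%s=%s", .data$dataset_id, .data$direction),
                         collapse = ","),
      has_up = any(.data$direction == "up"),
      has_down = any(.data$direction == "down"),
      .groups = "drop"
    ) |>
    left_join(per_kind_n, by = "kind") |>
    filter(.data$n_sig == .data$n_datasets_kind) |>
    mutate(
      consistent = !(.data$has_up & .data$has_down),
      consensus_direction = dplyr::case_when(
        .data$has_up & !.data$has_down ~ "up",
        .data$has_down & !.data$has_up ~ "down",
        TRUE ~ "undetermined"
      )
    ) |>
    select("feature_id", "kind", "n_datasets", "directions", "consistent",
           "consensus_direction") |>
    arrange(.data$kind, .data$feature_id)
}
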