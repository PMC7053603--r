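#' Resolve node regulation directions from consensus records
#'
#' Features with a consistent cross-dataset direction keep it. For features
#' whose significant directions conflict, the per-kind policy decides:
#' `"exclude"` removes them from assembly, `"undetermined"` retains them
#' without a direction (drawn grey in the network figure convention). The
#' defaults exclude conflicting mRNAs and lncRNAs but retain conflicting
#' miRNAs as undetermined.
#'
#' @param consensus Consensus tibble from [consensus_de()].
#' @param policy_mrna,policy_lncrna,policy_mirna `"exclude"` or
#'   `"undetermined"`.
#' @return Tibble `feature_id`, `kind`, `direction` (`up`/`down`/
#'   `undetermined`).
#' @export
resolve_directions <- function(consensus,
                               policy_mrna = "exclude",
                               policy_lncrna = "exclude",
                               policy_mirna = "undetermined") {
  policies <- c(mrna = match.arg(policy_mrna, c("exclude", "undetermined")),
                lncrna = match.arg(policy_lncrna, c("exclude", "undetermined")),
                mirna = match.arg(policy_mirna, c("exclude", "undetermined")))
  consensus |>
    mutate(policy = policies[.data$kind]) |>
    filter(.data$consistent | .data$policy == "undetermined") |>
    mutate(direction = ifelse(.data$consistent, .data$consensus_direction,
                              "undetermined")) |>
    select("feature_id", "kind", "direction") |>
    arrange(.data$kind, .data$feature_id)
}

#' Assemble lncRNA--miRNA--mRNA ceRNA triples
#'
#' Emits a triple (lncRNA l, miRNA m, mRNA g) when all four membership
#' rules hold: m targets l (duplex screen), m targets g (evidence +
#' negative correlation), l and g are synergistically coexpressed, and the
#' expression directions are consistent with the sponge model --- l and g
#' share the same direction while m, when determined, has the opposite one.
#'
#' @param mir_lnc Pair tibble with `mirna_id`, `lncrna_id` (e.g. a renamed
#'   [screen_duplex_hits()] result).
#' @param mir_mrna Pair tibble with `mirna_id`, `mrna_id` (e.g. from
#'   [intersect_targets()]).
#' @param lnc_mrna Pair tibble with `lncrna_id`, `mrna_id` (e.g. a renamed
#'   [intersect_correlations()] result).
#' @param directions Direction map from [resolve_directions()].
#' @return Triple tibble sorted by (`lncrna_id`, `mirna_id`, `mrna_id`)
#'   with per-member directions; provenance columns present on the pair
#'   inputs are carried through.
#' @export
assemble_triples <- function(mir_lnc, mir_mrna, lnc_mrna, directions) {
  need <- function(d, cols, nm) {
    if (!all(cols %in% names(d))) {
      stop_input(sprintf("`%s` must carry columns: %s", nm,
                         paste(cols, collapse = ", ")))
    }
  }
  need(mir_lnc, c("mirna_id", "lncrna_id"), "mir_lnc")
  need(mir_mrna, c("mirna_id", "mrna_id"), "mir_mrna")
  need(lnc_mrna, c("lncrna_id", "mrna_id"), "lnc_mrna")
  need(directions, c("feature_id", "direction"), "directions")
  dmap <- setNames(directions$direction, directions$feature_id)

  triples <- mir_lnc |>
    distinct(.data$mirna_id, .data$lncrna_id, .keep_all = TRUE) |>
    inner_join(distinct(mir_mrna, .data$mirna_id, .data$mrna_id,
                        .keep_all = TRUE),
               by = "mirna_id", suffix = c("_mir_lnc", "_mir_mrna"),
               relationship = "many-to-many") |>
    inner_join(distinct(lnc_mrna, .data$lncrna_id, .data$mrna_id,
                        .keep_all = TRUE),
               by = c("lncrna_id", "mrna_id"))

  triples <- triples |>
    mutate(lnc_direction = unname(dmap[.data$lncrna_id]),
           mrna_direction = unname(dmap[.data$mrna_id]),
           mirna_direction = unname(dmap[.data$mirna_id])) |>
    filter(!is.na(.data$lnc_direction), !is.na(.data$mrna_direction),
           !is.na(.data$mirna_direction),
           .data$lnc_direction %in% c("up", "down"),
           .data$mrna_direction %in% c("up", "down"),
           .data$lnc_direction == .data$mrna_direction,
           .data$mirna_direction == "undetermined" |
             .data$mirna_direction != .data$mrna_direction)

  triples |>
    select("lncrna_id", "mirna_id", "mrna_id", "lnc_direction",
           "mrna_direction", "mirna_direction",
           dplyr::any_of(c("score", "energy", "support", "r", "p"))) |>
    distinct(.data$lncrna_id, .data$mirna_id, .data$mrna_id,
             .keep_all = TRUE) |>
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
}

#' Build the ceRNA network from assembled triples
#'
#' One node per distinct molecule; for each triple, a miRNA--lncRNA edge, a
#' miRNA--mRNA edge and a (distinctly typed) lncRNA--mRNA coexpression
#' edge. Node degree is the unweighted count of incident edges; by default
#' coexpression edges count towards degree (`degree_edges = "all"`), as the
#' connectivity analysis is run on the drawn network; set
#' `degree_edges = "regulatory"` to count only miRNA edges.
#'
#' @param triples Triple tibble from [assemble_triples()].
#' @param degree_edges `"all"` or `"regulatory"`.
#' @return A `cerna_network` list with `nodes` (id, node_kind, direction,
#'   degree) and `edges` (source, target, edge_kind) tibbles.
#' @export
build_network <- function(triples, degree_edges = c("all", "regulatory")) {
  degree_edges <- match.arg(degree_edges)
  if (nrow(triples) == 0) {
    net <- list(nodes = tibble(id = character(0), node_kind = character(0),
                               direction = character(0), degree = integer(0)),
                edges = tibble(source = character(0), target = character(0),
                               edge_kind = character(0)),
                degree_edges = degree_edges)
    return(structure(net, class = "cerna_network"))
  }
  edges <- bind_rows(
    tibble(source = triples$mirna_id, target = triples$lncrna_id,
           edge_kind = "mir_lnc"),
    tibble(source = triples$mirna_id, target = triples$mrna_id,
           edge_kind = "mir_mrna"),
    tibble(source = triples$lncrna_id, target = triples$mrna_id,
           edge_kind = "lnc_mrna_coexpr")
  ) |>
    distinct() |>
    arrange(.data$edge_kind, .data$source, .data$target)

  nodes <- bind_rows(
    tibble(id = triples$lncrna_id, node_kind = "lncRNA",
           direction = triples$lnc_direction),
    tibble(id = triples$mirna_id, node_kind = "miRNA",
           direction = triples$mirna_direction),
    tibble(id = triples$mrna_id, node_kind = "mRNA",
           direction = triples$mrna_direction)
  ) |>
    distinct(.data$id, .data$node_kind, .data$direction)

  deg_edges <- if (degree_edges == "all") {
    edges
  } else {
    filter(edges, .data$edge_kind != "lnc_mrna_coexpr")
  }
  deg <- table(c(deg_edges$source, deg_edges$target))
  nodes$degree <- as.integer(deg[nodes$id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  nodes <- arrange(nodes, .data$node_kind, .data$id)

  structure(list(nodes = nodes, edges = edges, degree_edges = degree_edges),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes) > 0) {
    print(dplyr::count(x$nodes, .data$node_kind))
  }
  invisible(x)
}

#' Composite weights for ranking candidate core ceRNA axes
#'
#' @param w_degree,w_logfc,w_reproducibility Non-negative weights summing
#'   to 1 for the connectivity, effect-size and cross-dataset
#'   reproducibility components.
#' @return A `cerna_axis_weights` list.
#' @export
axis_weights <- function(w_degree = 1 / 3, w_logfc = 1 / 3,
                         w_reproducibility = 1 / 3) {
  check_number(w_degree, "w_degree", min = 0)
  check_number(w_logfc, "w_logfc", min = 0)
  check_number(w_reproducibility, "w_reproducibility", min = 0)
  if (abs(w_degree + w_logfc + w_reproducibility - 1) > 1e-8) {
    stop_config("axis weights must sum to 1")
  }
  structure(list(w_degree = w_degree, w_logfc = w_logfc,
                 w_reproducibility = w_reproducibility),
            class = "cerna_axis_weights")
}

minmax_norm <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rep(1, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Rank candidate core regulatory axes
#'
#' Scores each assembled triple as a weighted sum of three min-max
#' normalised components: the mean degree of its three nodes, the mean
#' |logFC| of its members across datasets, and the reproducibility of each
#' member (fraction of profiling datasets in which it is significant with
#' its consensus direction, averaged over the three members). Ties are
#' broken lexicographically by (lncrna_id, mirna_id, mrna_id).
#'
#' @param triples Triple tibble from [assemble_triples()].
#' @param network `cerna_network` from [build_network()].
#' @param de_tables Thresholded DE records with a `dataset_id` column (as
#'   accepted by [consensus_de()]).
#' @param weights An [axis_weights()] object.
#' @return Triple tibble with component columns and `axis_score`, sorted by
#'   descending score; `rank` is 1-based.
#' @export
rank_axes <- function(triples, network, de_tables, weights = axis_weights()) {
  if (!inherits(weights, "cerna_axis_weights")) {
    stop_config("`weights` must be created with axis_weights()")
  }
  if (nrow(triples) == 0) {
    return(mutate(triples, axis_score = numeric(0), rank = integer(0)))
  }
  if (is.list(de_tables) && !is.data.frame(de_tables)) {
    de_tables <- bind_rows(imap(de_tables, function(d, id) {
      mutate(d, dataset_id = id)
    }))
  }
  deg <- setNames(minmax_norm(network$nodes$degree), network$nodes$id)

  stats_per_feature <- de_tables |>
    group_by(.data$feature_id) |>
    summarise(mean_abs_logfc = mean(abs(.data$logFC)),
              n_ds = dplyr::n_distinct(.data$dataset_id),
              n_sig = sum(.data$direction != "ns"),
              n_up = sum(.data$direction == "up"),
              n_down = sum(.data$direction == "down"),
              .groups = "drop") |>
    mutate(repro = pmax(.data$n_up, .data$n_down) / .data$n_ds)
  lfc <- setNames(minmax_norm(stats_per_feature$mean_abs_logfc),
                  stats_per_feature$feature_id)
  rep_frac <- setNames(stats_per_feature$repro, stats_per_feature$feature_id)

  member_mean <- function(map, ids_mat, default = 0) {
    vals <- matrix(map[ids_mat], ncol = 3)
    vals[is.na(vals)] <- default
    rowMeans(vals)
  }
  ids_mat <- cbind(triples$lncrna_id, triples$mirna_id, triples$mrna_id)
  scored <- triples |>
    mutate(
      degree_component = member_mean(deg, ids_mat),
      logfc_component = member_mean(lfc, ids_mat),
      reproducibility_component = member_mean(rep_frac, ids_mat),
      axis_score = weights$w_degree * .data$degree_component +
        weights$w_logfc * .data$logfc_component +
        weights$w_reproducibility * .data$reproducibility_component
    ) |>
    arrange(dplyr::desc(.data$axis_score), .data$lncrna_id, .data$mirna_id,
            .data$mrna_id) |>
    mutate(rank = dplyr::row_number())
  scored
}
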