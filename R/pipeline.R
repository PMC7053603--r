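#' Run the full ceRNA network inference pipeline on a study bundle
#'
#' Executes the complete inference chain on an in-memory study bundle (from
#' [simulate_study()] or assembled from files): per-dataset differential
#' expression for each molecule kind, thresholding, cross-dataset
#' consensus, lncRNA--mRNA positive-synergy coexpression screening
#' intersected across datasets, miRNA--mRNA negative-correlation screening,
#' evidence-support filtering intersected with the negative correlations,
#' miRNA--lncRNA duplex scanning with score/energy gates (or a precomputed
#' pair list), direction resolution, triple assembly, network construction
#' with unweighted connectivity, and axis ranking.
#'
#' Correlations are computed among differentially expressed features only,
#' over all samples (tumour and normal) of a dataset. The miRNA--mRNA
#' correlation uses the first dataset; the lncRNA--mRNA screen is
#' intersected across all datasets.
#'
#' @param bundle A `cerna_bundle`.
#' @param de_thresholds A [de_thresholds()] object applied to every
#'   (dataset, kind); or a function `(dataset_id, kind) ->` thresholds
#'   object for per-dataset presets.
#' @param moderation Use empirical-Bayes moderated t-statistics?
#' @param r_min,p_max Positive-synergy coexpression gates (strict).
#' @param min_sources Minimum evidence support for predicted targets.
#' @param scoring A [duplex_scoring()] object.
#' @param score_min,energy_max Duplex screening gates (strict).
#' @param mir_lnc_pairs Optional precomputed miRNA--lncRNA pair tibble
#'   (`mirna_id`, `lncrna_id`); skips the duplex scan.
#' @param weights [axis_weights()] for axis ranking.
#' @param out_dir Optional directory; when given, every intermediate table
#'   is written as TSV/SIF/JSON and the manifest records the paths.
#' @return A `cerna_run` list: `de`, `consensus`, `directions`, `lnc_mrna`,
#'   `mir_mrna_corr`, `mir_mrna`, `mir_lnc`, `triples`, `network`, `axes`,
#'   and `manifest` (per-stage row counts, paths, parameters).
#' @export
run_cerna_pipeline <- function(bundle,
                               de_thresholds = cernetr::de_thresholds("adjusted", 0.05, 1),
                               moderation = TRUE,
                               r_min = 0.7, p_max = 0.05,
                               min_sources = 6L,
                               scoring = duplex_scoring(),
                               score_min = 140, energy_max = -20,
                               mir_lnc_pairs = NULL,
                               weights = axis_weights(),
                               out_dir = NULL) {
  if (!inherits(bundle, "cerna_bundle")) {
    stop_config("`bundle` must be a cerna_bundle")
  }
  if (length(bundle$datasets) == 0) {
    stop_config("bundle contains no datasets")
  }
  thr_fun <- if (is.function(de_thresholds)) {
    de_thresholds
  } else {
    function(dataset_id, kind) de_thresholds
  }

  # --- differential expression, per dataset and molecule kind ------------
  de <- bind_rows(imap(bundle$datasets, function(ds, id) {
    bind_rows(imap(ds$expr, function(expr, kind) {
      fit_de(expr, ds$metadata, kind = kind, design = ds$design,
             moderation = moderation) |>
        apply_de_thresholds(thr_fun(id, kind)) |>
        mutate(dataset_id = id)
    }))
  }))
  consensus <- consensus_de(de)
  directions <- resolve_directions(consensus)

  de_features <- function(kind) {
    unique(filter(de, .data$kind == !!kind,
                  .data$direction != "ns")$feature_id)
  }
  de_mrna <- de_features("mrna")
  de_lnc <- de_features("lncrna")
  de_mir <- de_features("mirna")

  # --- lncRNA-mRNA synergy, screened per dataset then intersected --------
  lnc_sets <- imap(bundle$datasets, function(ds, id) {
    correlate_pairs(ds$expr$lncrna, ds$expr$mrna, "lnc_mrna",
                    features_a = de_lnc, features_b = de_mrna) |>
      screen_correlations("positive_synergy", r_min = r_min, p_max = p_max)
  })
  lnc_mrna <- intersect_correlations(lnc_sets) |>
    rename(lncrna_id = "a_id", mrna_id = "b_id")

  # --- miRNA-mRNA negative correlation (first dataset) -------------------
  ds1 <- bundle$datasets[[1]]
  mir_mrna_corr <- correlate_pairs(ds1$expr$mirna, ds1$expr$mrna, "mir_mrna",
                                   features_a = de_mir,
                                   features_b = de_mrna) |>
    screen_correlations("negative_only")

  # --- evidence filter intersected with negative correlation -------------
  predicted <- filter_evidence(bundle$evidence, min_sources = min_sources)
  mir_mrna <- intersect_targets(predicted, mir_mrna_corr)

  # --- miRNA-lncRNA duplex screen ----------------------------------------
  if (is.null(mir_lnc_pairs)) {
    mir_tbl <- filter(bundle$sequences$mirna, .data$id %in% de_mir)
    lnc_tbl <- filter(bundle$sequences$lncrna, .data$id %in% de_lnc)
    hits <- scan_duplexes(mir_tbl, lnc_tbl, scoring = scoring,
                          min_score = score_min)
    mir_lnc <- screen_duplex_hits(hits, score_min = score_min,
                                  energy_max = energy_max) |>
      rename(lncrna_id = "target_id")
  } else {
    mir_lnc <- mir_lnc_pairs
  }

  # --- assembly, network, ranking ----------------------------------------
  triples <- assemble_triples(mir_lnc, mir_mrna, lnc_mrna, directions)
  network <- build_network(triples)
  axes <- rank_axes(triples, network, de, weights = weights)

  stages <- list(de = de, consensus = consensus, directions = directions,
                 lnc_mrna = lnc_mrna, mir_mrna_corr = mir_mrna_corr,
                 mir_mrna = mir_mrna, mir_lnc = mir_lnc, triples = triples,
                 axes = axes)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cernetr")),
    seed = bundle$config$seed,
    parameters = list(r_min = r_min, p_max = p_max,
                      min_sources = min_sources, score_min = score_min,
                      energy_max = energy_max, moderation = moderation,
                      weights = unclass(weights)),
    counts = c(map_int(stages, nrow),
               c(network_nodes = nrow(network$nodes),
                 network_edges = nrow(network$edges))),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- imap(stages, function(tbl, nm) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      write_tsv_sorted(tbl, p)
      p
    })
    net_paths <- write_network(network, out_dir)
    manifest$paths <- c(paths, as.list(net_paths))
    manifest_json <- manifest
    manifest_json$counts <- as.list(manifest$counts)
    jsonlite::write_json(manifest_json, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(c(stages, list(network = network, manifest = manifest)),
            class = "cerna_run")
}

#' @export
print.cerna_run <- function(x, ...) {
  cat("<cerna_run>\n")
  cnt <- x$manifest$counts
  for (nm in names(cnt)) cat(sprintf("  %-16s %d\n", nm, cnt[[nm]]))
  invisible(x)
}

#' Score pipeline output against a bundle's planted truth
#'
#' Compares assembled triples with the generator's planted triples,
#' reporting the recovery rate (planted triples assembled / planted) and
#' the spurious fraction (assembled triples not planted / assembled).
#'
#' @param run A `cerna_run` from [run_cerna_pipeline()].
#' @param truth The bundle's `truth` element.
#' @return Tibble: `n_planted`, `n_assembled`, `n_recovered`, `recovery`,
#'   `spurious_fraction`.
#' @export
score_against_truth <- function(run, truth) {
  key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id, sep = "|")
  planted <- key(truth$planted_triples)
  got <- key(run$triples)
  n_rec <- sum(planted %in% got)
  tibble(n_planted = length(planted), n_assembled = length(got),
         n_recovered = n_rec,
         recovery = if (length(planted) == 0) NA_real_ else n_rec / length(planted),
         spurious_fraction = if (length(got) == 0) 0 else
           sum(!(got %in% planted)) / length(got))
}
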