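#' Configuration for the synthetic ceRNA study generator
#'
#' Defines the size, planted signal and noise of a multi-dataset synthetic
#' study emulating a paired tumour/normal expression design: a handful of
#' pseudo-datasets profiling mRNAs, lncRNAs and miRNAs on the log2 scale,
#' with a set of planted lncRNA--miRNA--mRNA triples whose members are
#' differentially expressed (miRNA opposite in sign to the mRNA and lncRNA)
#' and whose expression is coupled so that the lncRNA--mRNA correlation is
#' positive and the miRNA--mRNA correlation is negative.
#'
#' The planted triple is generated as a Gaussian structural chain
#' (miRNA -> mRNA -> lncRNA): the mRNA is an affine-negative function of the
#' miRNA plus noise, and the lncRNA an affine-positive function of the mRNA
#' plus noise, calibrated so that the within-condition Pearson correlation of
#' each coupled pair equals `coupling_strength` in magnitude while every
#' planted log2 fold change stays exactly `effect_logfc` in expectation.
#'
#' @param n_mrna,n_lncrna,n_mirna Number of features of each molecule kind.
#' @param n_pairs_per_dataset Integer vector, one element per pseudo-dataset,
#'   giving the number of tumour/normal subject pairs in each.
#' @param n_planted_triples Number of planted lncRNA--miRNA--mRNA triples.
#' @param n_planted_de_singletons Number of additional differentially
#'   expressed features planted per molecule kind (not part of any triple).
#' @param effect_logfc Planted |log2 fold change| (tumour minus normal).
#' @param noise_sd Standard deviation of the log2-normal noise.
#' @param coupling_strength Within-triple correlation magnitude, in (0, 1].
#' @param evidence_n_sources Number of target-prediction evidence sources.
#' @param evidence_sensitivity Probability a source flags a true pair.
#' @param evidence_fpr Probability a source flags a decoy pair.
#' @param decoy_factor Decoy evidence rows sampled per true pair.
#' @param mirna_length,lncrna_length Lengths (nt) of generated sequences.
#' @param site_strength `"strong"` embeds the full reverse complement of the
#'   miRNA at each planted site; `"weak"` embeds only the reverse complement
#'   of the seed (miRNA positions 2--8).
#' @param n_validation Samples per group in the generated validation tables.
#' @param planted_ddct Planted delta-delta-Ct (case minus control, Ct units).
#' @param ct_sd Ct measurement noise standard deviation.
#' @param score_separation Mean difference (in SD units) between the positive
#'   and negative class in the generated diagnostic score table; `Inf` gives
#'   disjoint supports.
#' @param seed Master seed; per-component streams are derived from it.
#'
#' @return A validated `cerna_sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_mrna = 50, n_lncrna = 10, n_mirna = 5,
#'                   n_planted_triples = 2, seed = 7)
#' bundle <- simulate_study(cfg)
sim_config <- function(n_mrna = 200, n_lncrna = 50, n_mirna = 20,
                       n_pairs_per_dataset = c(10, 10),
                       n_planted_triples = 10,
                       n_planted_de_singletons = 5,
                       effect_logfc = 2, noise_sd = 0.5,
                       coupling_strength = 0.95,
                       evidence_n_sources = 12,
                       evidence_sensitivity = 0.9,
                       evidence_fpr = 0.02,
                       decoy_factor = 5,
                       mirna_length = 22, lncrna_length = 300,
                       site_strength = c("strong", "weak"),
                       n_validation = 20, planted_ddct = 2, ct_sd = 0.2,
                       score_separation = 3,
                       seed = 1L) {
  site_strength <- match.arg(site_strength)
  cfg <- list(
    n_mrna = check_count(n_mrna, "n_mrna"),
    n_lncrna = check_count(n_lncrna, "n_lncrna"),
    n_mirna = check_count(n_mirna, "n_mirna"),
    n_pairs_per_dataset = vapply(seq_along(n_pairs_per_dataset), function(i) {
      check_count(n_pairs_per_dataset[i], "n_pairs_per_dataset", min = 2L)
    }, integer(1)),
    n_planted_triples = check_count(n_planted_triples, "n_planted_triples"),
    n_planted_de_singletons = check_count(n_planted_de_singletons,
                                          "n_planted_de_singletons"),
    effect_logfc = check_number(effect_logfc, "effect_logfc", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE),
    coupling_strength = check_number(coupling_strength, "coupling_strength",
                                     min = 0, max = 1, strict_min = TRUE),
    evidence_n_sources = check_count(evidence_n_sources, "evidence_n_sources",
                                     min = 1L),
    evidence_sensitivity = check_prob(evidence_sensitivity,
                                      "evidence_sensitivity"),
    evidence_fpr = check_prob(evidence_fpr, "evidence_fpr"),
    decoy_factor = check_count(decoy_factor, "decoy_factor"),
    mirna_length = check_count(mirna_length, "mirna_length", min = 8L),
    lncrna_length = check_count(lncrna_length, "lncrna_length", min = 20L),
    site_strength = site_strength,
    n_validation = check_count(n_validation, "n_validation", min = 2L),
    planted_ddct = check_number(planted_ddct, "planted_ddct"),
    ct_sd = check_number(ct_sd, "ct_sd", min = 0),
    score_separation = check_number(score_separation, "score_separation",
                                    min = 0, allow_inf = TRUE),
    seed = check_count(seed, "seed")
  )
  if (length(cfg$n_pairs_per_dataset) < 1L) {
    stop_config("invalid value for `n_pairs_per_dataset`: need at least one pseudo-dataset")
  }
  if (cfg$n_planted_triples > min(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna)) {
    stop_config("invalid value for `n_planted_triples`: exceeds the smallest feature count")
  }
  if (cfg$n_planted_triples + cfg$n_planted_de_singletons >
      min(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna)) {
    stop_config("invalid value for `n_planted_de_singletons`: planted features exceed feature count")
  }
  structure(cfg, class = "cerna_sim_config")
}

feature_ids <- function(prefix, n) {
  if (n == 0) character(0) else sprintf("%s%03d", prefix, seq_len(n))
}

simulate_truth <- function(config) {
  nt <- config$n_planted_triples
  ns <- config$n_planted_de_singletons
  ids <- list(mrna = feature_ids("gene", config$n_mrna),
              lncrna = feature_ids("lnc", config$n_lncrna),
              mirna = feature_ids("mir", config$n_mirna))
  dir_triple <- rep_len(c("up", "down"), nt)
  planted_triples <- tibble(
    lncrna_id = ids$lncrna[seq_len(nt)],
    mirna_id = ids$mirna[seq_len(nt)],
    mrna_id = ids$mrna[seq_len(nt)],
    direction = dir_triple
  )
  flip <- function(d) as.character(ifelse(d == "up", "down", "up"))
  singleton <- function(kind) {
    if (ns == 0) return(tibble(feature_id = character(0), kind = character(0),
                               direction = character(0)))
    tibble(feature_id = ids[[kind]][nt + seq_len(ns)], kind = kind,
           direction = rep_len(c("up", "down"), ns))
  }
  planted_de <- bind_rows(
    tibble(feature_id = planted_triples$mrna_id, kind = "mrna",
           direction = dir_triple),
    tibble(feature_id = planted_triples$lncrna_id, kind = "lncrna",
           direction = dir_triple),
    tibble(feature_id = planted_triples$mirna_id, kind = "mirna",
           direction = flip(dir_triple)),
    singleton("mrna"), singleton("lncrna"), singleton("mirna")
  )
  list(ids = ids, planted_triples = planted_triples, planted_de = planted_de)
}

simulate_dataset <- function(config, truth, dataset_id, n_pairs, seed) {
  with_seed(seed, {
    n_samples <- 2L * n_pairs
    subject <- rep(sprintf("%s_subj%02d", dataset_id, seq_len(n_pairs)),
                   each = 2L)
    condition <- rep(c("normal", "tumor"), times = n_pairs)
    sample_id <- sprintf("%s_s%02d", dataset_id, seq_len(n_samples))
    metadata <- tibble(sample_id = sample_id, subject_id = subject,
                       condition = condition)
    tum <- as.numeric(condition == "tumor")
    eff <- config$effect_logfc
    sigma <- config$noise_sd

    make_null <- function(ids) {
      mu <- runif(length(ids), 6, 10)
      m <- matrix(rnorm(length(ids) * n_samples, sd = sigma),
                  nrow = length(ids))
      m <- m + mu
      rownames(m) <- ids
      colnames(m) <- sample_id
      m
    }
    mats <- lapply(truth$ids, make_null)

    # planted DE singletons: simple mean shift in tumour samples
    sing <- truth$planted_de[!(truth$planted_de$feature_id %in%
                                 unlist(truth$planted_triples[1:3])), ]
    for (i in seq_len(nrow(sing))) {
      k <- sing$kind[i]
      d <- if (sing$direction[i] == "up") 1 else -1
      mats[[k]][sing$feature_id[i], ] <-
        mats[[k]][sing$feature_id[i], ] + d * eff * tum
    }

    # planted triples: structural chain miRNA -> mRNA -> lncRNA with
    # within-condition correlation +/- coupling_strength and exact expected
    # logFC of +/- effect_logfc for every member
    cc <- config$coupling_strength
    sigma_y <- sigma * sqrt(1 / cc^2 - 1)
    sd_res <- sigma / cc                       # sd of the mRNA residual
    tau <- sd_res * sqrt(1 - cc^2) / cc
    tri <- truth$planted_triples
    for (i in seq_len(nrow(tri))) {
      d <- if (tri$direction[i] == "up") 1 else -1
      z1 <- rnorm(n_samples); z2 <- rnorm(n_samples); z3 <- rnorm(n_samples)
      mu_x <- runif(1, 6, 10); mu_y <- runif(1, 6, 10); mu_l <- runif(1, 6, 10)
      x <- mu_x - d * eff * tum + sigma * z1
      res_y <- -sigma * z1 + sigma_y * z2
      y <- mu_y + d * eff * tum + res_y
      l <- mu_l + d * eff * tum + res_y + tau * z3
      mats$mirna[tri$mirna_id[i], ] <- x
      mats$mrna[tri$mrna_id[i], ] <- y
      mats$lncrna[tri$lncrna_id[i], ] <- l
    }

    list(dataset_id = dataset_id, design = "paired",
         expr = lapply(mats, matrix_to_expr), metadata = metadata)
  })
}

#' Generate a complete synthetic ceRNA study bundle
#'
#' Produces, deterministically for a given config (including its seed), a
#' list of pseudo-datasets (per-kind log2 expression tables plus paired
#' sample metadata), a multi-source target-evidence table, miRNA and lncRNA
#' sequences with planted binding sites, and the ground truth needed to
#' score recovery.
#'
#' @param config A [sim_config()] object.
#' @return A `cerna_bundle` list with elements `datasets`, `evidence`,
#'   `sequences`, `truth` and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  if (!inherits(config, "cerna_sim_config")) {
    stop_config("`config` must be created with sim_config()")
  }
  truth <- simulate_truth(config)
  datasets <- list()
  for (k in seq_along(config$n_pairs_per_dataset)) {
    id <- sprintf("synth%d", k)
    datasets[[id]] <- simulate_dataset(
      config, truth, id, config$n_pairs_per_dataset[k],
      derive_seed(config$seed, paste0("dataset", k))
    )
  }
  evidence <- simulate_evidence(truth$planted_triples, config)
  sequences <- simulate_sequences(truth$planted_triples, config)
  truth_out <- list(planted_triples = truth$planted_triples,
                    planted_de = truth$planted_de,
                    planted_sites = sequences$sites)
  structure(list(datasets = datasets, evidence = evidence,
                 sequences = sequences[c("mirna", "lncrna")],
                 truth = truth_out, config = config),
            class = "cerna_bundle")
}

#' @export
print.cerna_bundle <- function(x, ...) {
  cat("<cerna_bundle>\n")
  cat(sprintf("  %d pseudo-dataset(s): %s\n", length(x$datasets),
              paste(names(x$datasets), collapse = ", ")))
  cat(sprintf("  features: %d mRNA, %d lncRNA, %d miRNA\n",
              x$config$n_mrna, x$config$n_lncrna, x$config$n_mirna))
  cat(sprintf("  planted triples: %d; evidence rows: %d\n",
              nrow(x$truth$planted_triples), nrow(x$evidence)))
  invisible(x)
}

#' Default evidence source names
#'
#' The twelve target-prediction sources conventionally aggregated by
#' miRWalk-style evidence tables.
#' @return Character vector of length 12.
#' @export
default_source_names <- function() {
  c("miRWalk", "MicroT4", "miRanda", "miRBridge", "miRDB", "miRMap",
    "miRNAMap", "PICTAR2", "PITA", "RNA22", "RNAhybrid", "Targetscan")
}

#' Generate a synthetic multi-source target-evidence table
#'
#' True miRNA--mRNA pairs (the planted triples) are flagged by each source
#' with probability `evidence_sensitivity`; decoy pairs (sampled from the
#' complement, `decoy_factor` per true pair) with probability `evidence_fpr`.
#'
#' @param planted_triples Tibble with `mirna_id` and `mrna_id` columns (the
#'   true target pairs), e.g. `bundle$truth$planted_triples`.
#' @param config A [sim_config()] object.
#' @return Evidence tibble: `mirna_id`, `mrna_id`, one 0/1 column per
#'   source, and `support` (the flag sum).
#' @export
simulate_evidence <- function(planted_triples, config) {
  ns <- config$evidence_n_sources
  src <- if (ns == 12L) default_source_names() else sprintf("src%02d", seq_len(ns))
  true_pairs <- distinct(planted_triples[, c("mirna_id", "mrna_id")])
  with_seed(derive_seed(config$seed, "evidence"), {
    all_mir <- feature_ids("mir", config$n_mirna)
    all_gene <- feature_ids("gene", config$n_mrna)
    grid <- tidyr::expand_grid(mirna_id = all_mir, mrna_id = all_gene)
    decoy_pool <- anti_join(grid, true_pairs, by = c("mirna_id", "mrna_id"))
    n_decoy <- min(nrow(decoy_pool), config$decoy_factor * max(nrow(true_pairs), 1L))
    decoys <- decoy_pool[sample.int(nrow(decoy_pool), n_decoy), ]
    pairs <- bind_rows(mutate(true_pairs, .true = TRUE),
                       mutate(decoys, .true = FALSE))
    prob <- ifelse(pairs$.true, config$evidence_sensitivity, config$evidence_fpr)
    flags <- matrix(rbinom(nrow(pairs) * ns, 1L, rep(prob, times = ns)),
                    nrow = nrow(pairs))
    colnames(flags) <- src
    out <- dplyr::bind_cols(pairs[, c("mirna_id", "mrna_id")],
                            as_tibble(flags))
    out$support <- as.integer(rowSums(flags))
    arrange(out, .data$mirna_id, .data$mrna_id)
  })
}

RNA_ALPHABET <- c("A", "C", "G", "U")

rna_revcomp <- function(seq) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  chars <- strsplit(seq, "")[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

#' Generate synthetic miRNA and lncRNA sequences with planted binding sites
#'
#' lncRNA sequences are random-composition RNA; for each planted
#' (miRNA, lncRNA) pair the reverse complement of the miRNA (full length for
#' strong sites, seed positions 2--8 only for weak sites) is embedded at a
#' recorded 1-based inclusive position on the target's 5'->3' strand.
#'
#' @inheritParams simulate_evidence
#' @return List with `mirna` and `lncrna` sequence tibbles (`id`, `seq`) and
#'   a `sites` tibble recording each planted interval.
#' @export
simulate_sequences <- function(planted_triples, config) {
  with_seed(derive_seed(config$seed, "sequences"), {
    mir_ids <- feature_ids("mir", config$n_mirna)
    lnc_ids <- feature_ids("lnc", config$n_lncrna)
    rand_seq <- function(len) {
      paste(sample(RNA_ALPHABET, len, replace = TRUE), collapse = "")
    }
    mirna <- tibble(id = mir_ids,
                    seq = vapply(mir_ids, function(i) rand_seq(config$mirna_length),
                                 character(1)))
    lnc_seq <- setNames(vapply(lnc_ids, function(i) rand_seq(config$lncrna_length),
                               character(1)), lnc_ids)

    pairs <- distinct(planted_triples[, c("mirna_id", "lncrna_id")])
    sites <- tibble(mirna_id = character(0), lncrna_id = character(0),
                    start = integer(0), end = integer(0),
                    site_type = character(0))
    occupied <- lapply(lnc_ids, function(i) integer(0))
    names(occupied) <- lnc_ids
    for (i in seq_len(nrow(pairs))) {
      m <- pairs$mirna_id[i]; l <- pairs$lncrna_id[i]
      mseq <- mirna$seq[mirna$id == m]
      site <- if (config$site_strength == "strong") {
        rna_revcomp(mseq)
      } else {
        rna_revcomp(substr(mseq, 2L, 8L))
      }
      len <- nchar(site)
      tlen <- nchar(lnc_seq[[l]])
      if (tlen < len) {
        stop_input(sprintf("lncRNA %s (%d nt) is shorter than the planted site (%d nt)",
                           l, tlen, len))
      }
      placed <- FALSE
      for (try in seq_len(200L)) {
        start <- sample.int(tlen - len + 1L, 1L)
        span <- start:(start + len - 1L)
        if (!any(span %in% occupied[[l]])) {
          substr(lnc_seq[[l]], start, start + len - 1L) <- site
          occupied[[l]] <- c(occupied[[l]], span)
          sites <- bind_rows(sites, tibble(
            mirna_id = m, lncrna_id = l, start = start,
            end = start + len - 1L, site_type = config$site_strength))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_input(sprintf("could not place a non-overlapping site on lncRNA %s", l))
      }
    }
    list(mirna = mirna,
         lncrna = tibble(id = lnc_ids, seq = unname(lnc_seq[lnc_ids])),
         sites = arrange(sites, .data$mirna_id, .data$lncrna_id))
  })
}

#' Generate validation fixtures: Ct, stage and diagnostic-score tables
#'
#' @inheritParams simulate_study
#' @return List of three tibbles: `ct` (per-sample target and reference Ct
#'   for case and control groups, with the configured planted delta-delta-Ct),
#'   `stages` (T1/T2/T3 labels), and `scores` (class-separated diagnostic
#'   scores with mean separation `score_separation`).
#' @export
simulate_validation_tables <- function(config = sim_config()) {
  with_seed(derive_seed(config$seed, "validation"), {
    n <- config$n_validation
    base_dct <- 5
    grp <- rep(c("control", "case"), each = n)
    ct_ref <- rnorm(2 * n, mean = 20, sd = config$ct_sd)
    dct <- base_dct + ifelse(grp == "case", config$planted_ddct, 0)
    ct_target <- ct_ref + dct + rnorm(2 * n, sd = config$ct_sd)
    ct <- tibble(sample_id = sprintf("v%03d", seq_len(2 * n)),
                 group = grp, ct_target = ct_target, ct_ref = ct_ref)

    stages <- tibble(sample_id = sprintf("t%03d", seq_len(3 * n)),
                     stage = rep(c("T1", "T2", "T3"), each = n))

    neg <- rnorm(n)
    pos <- rnorm(n)
    pos <- if (is.infinite(config$score_separation)) {
      pos - min(pos) + max(neg) + 1   # disjoint supports
    } else {
      pos + config$score_separation
    }
    scores <- tibble(sample_id = sprintf("r%03d", seq_len(2 * n)),
                     class = rep(c("negative", "positive"), each = n),
                     score = c(neg, pos))
    list(ct = ct, stages = stages, scores = scores)
  })
}
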