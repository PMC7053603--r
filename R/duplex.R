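#' Scoring parameters for the miRNA:target duplex scanner
#'
#' Complementarity scoring for local alignment of a miRNA (3'->5') against a
#' target (5'->3'): A:U and G:C pairs are matches, G:U wobbles score
#' separately, everything else is a mismatch; gaps are affine. Substitution
#' scores inside the miRNA seed window (positions `seed_start`--`seed_end`,
#' 1-based from the 5' end) are multiplied by `seed_scale`, reflecting the
#' dominant contribution of seed pairing to target recognition. The defaults
#' approximate published miRanda conventions; absolute score reproduction of
#' the original binary is not a goal.
#'
#' @param match_score Score of a Watson-Crick pair.
#' @param gu_wobble_score Score of a G:U wobble pair.
#' @param mismatch_score Score of any other juxtaposition.
#' @param gap_open,gap_extend Affine gap penalties (both <= 0).
#' @param seed_start,seed_end Seed window on the miRNA, 1-based from 5'.
#' @param seed_scale Multiplier (>= 1) applied to substitution scores at
#'   seed positions.
#' @return A `cerna_duplex_scoring` list.
#' @export
duplex_scoring <- function(match_score = 5, gu_wobble_score = 1,
                           mismatch_score = -3, gap_open = -9,
                           gap_extend = -4, seed_start = 2L, seed_end = 8L,
                           seed_scale = 4) {
  check_number(match_score, "match_score")
  check_number(gu_wobble_score, "gu_wobble_score")
  check_number(mismatch_score, "mismatch_score")
  check_number(gap_open, "gap_open", max = 0)
  check_number(gap_extend, "gap_extend", max = 0)
  check_count(seed_start, "seed_start", min = 1L)
  check_count(seed_end, "seed_end", min = 1L)
  check_number(seed_scale, "seed_scale", min = 1)
  if (seed_start >= seed_end) {
    stop_config("invalid value for `seed_start`: must be < seed_end")
  }
  structure(list(match_score = match_score,
                 gu_wobble_score = gu_wobble_score,
                 mismatch_score = mismatch_score, gap_open = gap_open,
                 gap_extend = gap_extend, seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end), seed_scale = seed_scale),
            class = "cerna_duplex_scoring")
}

# Encode an RNA string as integers 1=A, 2=C, 3=G, 4=U (T accepted).
encode_rna <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[chars == "T"] <- "U"
  idx <- match(chars, RNA_ALPHABET)
  if (any(is.na(idx))) {
    stop_input(sprintf("invalid %s alphabet: found '%s' (A/C/G/U/T allowed)",
                       what, chars[which(is.na(idx))[1]]))
  }
  idx
}

# 4x4 base-substitution matrix under complementarity scoring. Rows index the
# miRNA base, columns the target base.
substitution_matrix <- function(scoring) {
  s <- matrix(scoring$mismatch_score, 4, 4,
              dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  s["A", "U"] <- s["U", "A"] <- scoring$match_score
  s["C", "G"] <- s["G", "C"] <- scoring$match_score
  s["G", "U"] <- s["U", "G"] <- scoring$gu_wobble_score
  s
}

# Turner-style nearest-neighbor stack free energies (kcal/mol) for RNA pair
# steps, approximating published magnitudes. Rows: pair at the 5' side of
# the target strand (target base : miRNA base); columns: the following pair.
# Used with a duplex-initiation term; loop entropies are ignored.
stack_energy_table <- function() {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  e <- matrix(c(
    # AU    UA    CG    GC    GU    UG     (3' pair)
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,  # 5' AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,  # 5' UA
    -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,  # 5' CG
    -2.4, -2.2, -3.4, -3.3, -1.5, -2.5,  # 5' GC
    -1.3, -1.4, -2.5, -2.1, -0.5, -0.5,  # 5' GU
    -1.0, -0.6, -1.5, -1.4, -0.3, -0.5   # 5' UG
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  e
}

DUPLEX_INIT_ENERGY <- 4.09
DUPLEX_TERMINAL_AU_PENALTY <- 0.45
DUPLEX_LOOP_PENALTY <- 3.0

# Free energy of one aligned duplex: nearest-neighbor stacking summed over
# consecutive paired columns, plus initiation, terminal AU/GU penalties and
# a fixed destabilisation per helix interruption (any maximal run of
# mismatched or gapped columns between paired columns), approximating the
# interior-loop/bulge cost of thermodynamic duplex models.
duplex_energy <- function(aln_mirna, aln_target) {
  qa <- strsplit(aln_mirna, "")[[1]]
  ta <- strsplit(aln_target, "")[[1]]
  pair_of <- function(tb, qb) {
    p <- paste0(tb, qb)
    if (p %in% rownames(stack_energy_table())) p else NA_character_
  }
  pairs <- vapply(seq_along(qa), function(i) {
    if (qa[i] == "-" || ta[i] == "-") NA_character_ else pair_of(ta[i], qa[i])
  }, character(1))
  if (!any(!is.na(pairs))) return(0)
  tab <- stack_energy_table()
  e <- DUPLEX_INIT_ENERGY
  for (i in seq_len(length(pairs) - 1L)) {
    if (!is.na(pairs[i]) && !is.na(pairs[i + 1L])) {
      e <- e + tab[pairs[i], pairs[i + 1L]]
    }
  }
  paired <- which(!is.na(pairs))
  for (idx in c(paired[1], paired[length(paired)])) {
    if (pairs[idx] %in% c("AU", "UA", "GU", "UG")) {
      e <- e + DUPLEX_TERMINAL_AU_PENALTY
    }
  }
  # interior loops / bulges: each gap between consecutive paired columns
  n_interruptions <- sum(diff(paired) > 1L)
  e + n_interruptions * DUPLEX_LOOP_PENALTY
}

#' Scan miRNA:target sequence pairs for complementary duplex sites
#'
#' Aligns each miRNA (reversed, so 3'->5' against the target's 5'->3'
#' strand) locally against each target under complementarity scoring with
#' seed-window weighting and affine gaps, reporting all maximal
#' non-overlapping local optima with score > 0. Each hit carries 1-based
#' inclusive target coordinates, the aligned strings (miRNA 3'->5', pairing
#' line with `|` for Watson-Crick and `:` for G:U wobble), the alignment
#' score and the stacking free energy (kcal/mol) of the paired positions.
#'
#' @param mirnas,targets Sequence tibbles with `id` and `seq` columns
#'   (RNA; T is accepted and read as U).
#' @param scoring A [duplex_scoring()] object.
#' @param max_hits Maximum hits reported per (miRNA, target) pair.
#' @param min_score Report only hits with score strictly above this floor
#'   (default 0, i.e. every positive local optimum). Raising it to the
#'   downstream screening gate skips the enumeration of sub-threshold
#'   optima without changing the screened result.
#' @return Hit tibble: `mirna_id`, `target_id`, `target_start`,
#'   `target_end`, `score`, `energy`, `aln_mirna`, `aln_pairing`,
#'   `aln_target`, sorted by score descending then target_start.
#' @export
#' @examples
#' mir <- tibble::tibble(id = "mir1", seq = "UGAGGUAGUAGGUUGUAUAGUU")
#' tgt <- tibble::tibble(id = "lnc1",
#'   seq = paste0("GGGGG", "AACUAUACAACCUACUACCUCA", "GGGGG"))
#' scan_duplexes(mir, tgt)
scan_duplexes <- function(mirnas, targets, scoring = duplex_scoring(),
                          max_hits = 16L, min_score = 0) {
  if (!inherits(scoring, "cerna_duplex_scoring")) {
    stop_config("`scoring` must be created with duplex_scoring()")
  }
  for (d in list(mirnas, targets)) {
    if (!is.data.frame(d) || !all(c("id", "seq") %in% names(d))) {
      stop_input("sequence tables must carry `id` and `seq` columns")
    }
  }
  sub <- substitution_matrix(scoring)
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    mseq <- encode_rna(mirnas$seq[i], "miRNA")
    if (length(mseq) < scoring$seed_end) {
      stop_input(sprintf("miRNA %s is shorter than the seed window end (%d)",
                         mirnas$id[i], scoring$seed_end))
    }
    # reverse the miRNA (3'->5' vs target 5'->3'); weights follow positions
    q <- rev(mseq)
    mir_pos <- rev(seq_along(mseq))  # original 5'-based position per row
    w <- ifelse(mir_pos >= scoring$seed_start & mir_pos <= scoring$seed_end,
                scoring$seed_scale, 1)
    for (j in seq_len(nrow(targets))) {
      tseq <- encode_rna(targets$seq[j], "target")
      hits <- duplex_align_cpp(q, tseq, sub, w, scoring$gap_open,
                               scoring$gap_extend, as.integer(max_hits),
                               min_score)
      for (h in hits) {
        L <- length(q)
        qpos <- h$q_idx[h$q_idx > 0]          # rows of the reversed query
        mir_lo <- L - max(qpos) + 1L          # 5'-based positions involved
        mir_hi <- L - min(qpos) + 1L
        qa <- ifelse(h$q_idx == 0, "-", RNA_ALPHABET[q[pmax(h$q_idx, 1L)]])
        ta <- ifelse(h$t_idx == 0, "-", RNA_ALPHABET[tseq[pmax(h$t_idx, 1L)]])
        pairing <- vapply(seq_along(qa), function(k) {
          if (qa[k] == "-" || ta[k] == "-") return(" ")
          pr <- paste0(qa[k], ta[k])
          if (pr %in% c("AU", "UA", "CG", "GC")) "|"
          else if (pr %in% c("GU", "UG")) ":"
          else " "
        }, character(1))
        aln_mirna <- paste(qa, collapse = "")
        aln_target <- paste(ta, collapse = "")
        out[[length(out) + 1L]] <- tibble(
          mirna_id = mirnas$id[i], target_id = targets$id[j],
          target_start = h$tstart, target_end = h$tend,
          mirna_start = mir_lo, mirna_end = mir_hi,
          score = h$score,
          energy = duplex_energy(aln_mirna, aln_target),
          aln_mirna = aln_mirna,
          aln_pairing = paste(pairing, collapse = ""),
          aln_target = aln_target)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(mirna_id = character(0), target_id = character(0),
                  target_start = integer(0), target_end = integer(0),
                  mirna_start = integer(0), mirna_end = integer(0),
                  score = numeric(0), energy = numeric(0),
                  aln_mirna = character(0), aln_pairing = character(0),
                  aln_target = character(0)))
  }
  bind_rows(out) |>
    arrange(dplyr::desc(.data$score), .data$target_start)
}

#' Re-score an emitted duplex alignment
#'
#' Recomputes the alignment score of a hit from its aligned strings and
#' miRNA coordinates under a scoring object; by construction this
#' reproduces the scanner's score exactly for every emitted hit.
#'
#' @param aln_mirna,aln_target Aligned strings from a [scan_duplexes()] hit
#'   (miRNA 3'->5', `-` for gaps).
#' @param mirna_end The hit's `mirna_end`: the 5'-based miRNA position of
#'   the leftmost (3'-most) aligned miRNA base.
#' @param scoring A [duplex_scoring()] object.
#' @return The alignment score.
#' @export
rescore_duplex_alignment <- function(aln_mirna, aln_target, mirna_end,
                                     scoring = duplex_scoring()) {
  qa <- strsplit(toupper(aln_mirna), "")[[1]]
  ta <- strsplit(toupper(aln_target), "")[[1]]
  if (length(qa) != length(ta)) stop_input("aligned strings differ in length")
  sub <- substitution_matrix(scoring)
  score <- 0
  pos <- mirna_end  # miRNA 5'-based position of the next non-gap miRNA base
  gap_state <- ""   # "q" = gap in miRNA column run, "t" = gap in target
  for (k in seq_along(qa)) {
    if (qa[k] == "-") {            # gap in miRNA strand (target consumed)
      score <- score + if (gap_state == "q") scoring$gap_extend else scoring$gap_open
      gap_state <- "q"
    } else if (ta[k] == "-") {     # gap in target strand (miRNA consumed)
      score <- score + if (gap_state == "t") scoring$gap_extend else scoring$gap_open
      gap_state <- "t"
      pos <- pos - 1L
    } else {
      w <- if (pos >= scoring$seed_start && pos <= scoring$seed_end) {
        scoring$seed_scale
      } else {
        1
      }
      score <- score + sub[qa[k], ta[k]] * w
      gap_state <- ""
      pos <- pos - 1L
    }
  }
  score
}

#' Screen duplex hits under score and energy gates
#'
#' Keeps (miRNA, target) pairs having at least one hit with
#' `score > score_min` and `energy < energy_max` (both strict); the pair
#' list is deduplicated with the best-scoring passing hit retained as
#' representative.
#'
#' @param hits Hit tibble from [scan_duplexes()].
#' @param score_min Strict lower score bound (default 140).
#' @param energy_max Strict upper free-energy bound, kcal/mol (default -20).
#' @return Deduplicated pair tibble with the representative hit columns.
#' @export
screen_duplex_hits <- function(hits, score_min = 140, energy_max = -20) {
  check_number(score_min, "score_min")
  check_number(energy_max, "energy_max")
  hits |>
    filter(.data$score > score_min, .data$energy < energy_max) |>
    group_by(.data$mirna_id, .data$target_id) |>
    arrange(dplyr::desc(.data$score), .data$target_start, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup() |>
    arrange(.data$mirna_id, .data$target_id)
}
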