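# Independent oracles used across the suite. Each reimplements the checked
# quantity from its definition, without touching the package's code paths.

# Benjamini-Hochberg step-up, literally: sort ascending, take the running
# minimum of p_(j) * n / j from the largest rank down, cap at 1, restore
# input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  running <- Inf
  for (j in n:1) {
    running <- min(running, ps[j] * n / j)
    adj[j] <- min(running, 1)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric upper tail P(X >= k) by summing the mass
# function from its choose() definition.
hyper_tail_oracle <- function(k, N, K, n) {
  kk <- max(0, k):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# AUC as the normalised Mann-Whitney statistic: the fraction of
# (positive, negative) score pairs won by the positive, ties half credit.
auc_mw_oracle <- function(scores_pos, scores_neg) {
  cmp <- outer(scores_pos, scores_neg, function(a, b) {
    (a > b) + 0.5 * (a == b)
  })
  mean(cmp)
}

# Affine-gap Smith-Waterman optimum by the plain three-matrix recurrence:
# query rows carry a multiplicative substitution weight. Returns only the
# best local score (what the scanner's top hit must reproduce).
sw_oracle <- function(q, t, sub, row_weight, gap_open, gap_extend) {
  m <- length(q); n <- length(t)
  NEG <- -1e18
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- sub[q[i], t[j]] * row_weight[i]
      M[i + 1, j + 1] <- max(0, s + max(M[i, j], X[i, j], Y[i, j]))
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open, X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, Y[i + 1, j] + gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Substitution matrix and row weights matching a duplex_scoring object,
# built independently of the package internals (bases as integers 1=A,
# 2=C, 3=G, 4=U; query already reversed).
oracle_scoring_tables <- function(scoring, mirna_len) {
  sub <- matrix(scoring$mismatch_score, 4, 4)
  sub[1, 4] <- sub[4, 1] <- scoring$match_score  # A:U
  sub[2, 3] <- sub[3, 2] <- scoring$match_score  # C:G
  sub[3, 4] <- sub[4, 3] <- scoring$gu_wobble_score  # G:U
  pos <- rev(seq_len(mirna_len))
  w <- ifelse(pos >= scoring$seed_start & pos <= scoring$seed_end,
              scoring$seed_scale, 1)
  list(sub = sub, w = w)
}

rna_int <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "U"))

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

revcomp_oracle <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Re-check the four ceRNA triple membership predicates by brute force.
validate_triples_oracle <- function(triples, mir_lnc, mir_mrna, lnc_mrna,
                                    directions) {
  dmap <- stats::setNames(directions$direction, directions$feature_id)
  key2 <- function(a, b) paste(a, b, sep = "\r")
  ml <- key2(mir_lnc$mirna_id, mir_lnc$lncrna_id)
  mg <- key2(mir_mrna$mirna_id, mir_mrna$mrna_id)
  lg <- key2(lnc_mrna$lncrna_id, lnc_mrna$mrna_id)
  ok <- logical(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    l <- triples$lncrna_id[i]; m <- triples$mirna_id[i]; g <- triples$mrna_id[i]
    dl <- dmap[[l]]; dg <- dmap[[g]]; dm <- dmap[[m]]
    ok[i] <- key2(m, l) %in% ml &&
      key2(m, g) %in% mg &&
      key2(l, g) %in% lg &&
      !is.null(dl) && !is.null(dg) && dl %in% c("up", "down") && dl == dg &&
      (dm == "undetermined" || dm != dg)
  }
  ok
}

# Small, fast simulation config for tests that only need structure.
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(n_mrna = 40, n_lncrna = 12, n_mirna = 6,
                   n_pairs_per_dataset = c(8, 8), n_planted_triples = 4,
                   n_planted_de_singletons = 2, lncrna_length = 120,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
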