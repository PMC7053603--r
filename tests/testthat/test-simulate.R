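test_that("config validation names the offending field", {
  expect_error(sim_config(noise_sd = 0), "noise_sd",
               class = "cernetr_config_error")
  expect_error(sim_config(evidence_sensitivity = 1.2), "evidence_sensitivity",
               class = "cernetr_config_error")
  expect_error(sim_config(n_mrna = -1), "n_mrna",
               class = "cernetr_config_error")
  expect_error(sim_config(n_planted_triples = 30, n_mirna = 5),
               "n_planted_triples", class = "cernetr_config_error")
})

test_that("bundles are byte-identical for identical config and seed", {
  cfg <- tiny_config(seed = 11)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1, b2)
  b3 <- simulate_study(tiny_config(seed = 12))
  expect_false(identical(b1$datasets, b3$datasets))
})

test_that("noise-free limit gives exact planted logFC of the right signs", {
  cfg <- tiny_config(seed = 2, noise_sd = 1e-12, effect_logfc = 2)
  b <- simulate_study(cfg)
  ds <- b$datasets[[1]]
  tum <- ds$metadata$condition == "tumor"
  lfc <- function(kind, id) {
    m <- as.matrix(ds$expr[[kind]][ds$expr[[kind]]$feature_id == id, -1])
    mean(m[, tum]) - mean(m[, !tum])
  }
  for (i in seq_len(nrow(b$truth$planted_triples))) {
    tri <- b$truth$planted_triples[i, ]
    d <- if (tri$direction == "up") 1 else -1
    expect_equal(lfc("mrna", tri$mrna_id), d * 2, tolerance = 1e-9)
    expect_equal(lfc("lncrna", tri$lncrna_id), d * 2, tolerance = 1e-9)
    expect_equal(lfc("mirna", tri$mirna_id), -d * 2, tolerance = 1e-9)
  }
  # miRNA direction is always opposite to the mRNA/lncRNA direction
  de <- b$truth$planted_de
  tri_mir <- de[de$feature_id %in% b$truth$planted_triples$mirna_id, ]
  tri_mrna <- de[de$feature_id %in% b$truth$planted_triples$mrna_id, ]
  expect_true(all(tri_mir$direction != tri_mrna$direction))
})

test_that("no planted triples means empty truth and null features", {
  cfg <- tiny_config(seed = 3, n_planted_triples = 0,
                     n_planted_de_singletons = 0)
  b <- simulate_study(cfg)
  expect_equal(nrow(b$truth$planted_triples), 0)
  expect_equal(nrow(b$truth$planted_de), 0)
  de <- fit_de(b$datasets[[1]]$expr$mrna, b$datasets[[1]]$metadata,
               design = "paired") |>
    apply_de_thresholds(de_thresholds("adjusted", 0.05, 1))
  expect_true(all(de$direction == "ns"))
})

test_that("planted triples show the assumed correlation structure", {
  # strong coupling: positive lncRNA-mRNA and negative miRNA-mRNA Pearson r
  hits <- vapply(1:40, function(s) {
    b <- simulate_study(tiny_config(seed = s, coupling_strength = 0.95,
                                    n_pairs_per_dataset = 12))
    ds <- b$datasets[[1]]
    row_of <- function(kind, id) {
      as.numeric(ds$expr[[kind]][ds$expr[[kind]]$feature_id == id, -1])
    }
    ok <- vapply(seq_len(nrow(b$truth$planted_triples)), function(i) {
      tri <- b$truth$planted_triples[i, ]
      g <- row_of("mrna", tri$mrna_id)
      l <- row_of("lncrna", tri$lncrna_id)
      m <- row_of("mirna", tri$mirna_id)
      cor(l, g) > 0.7 && cor(m, g) < 0
    }, logical(1))
    all(ok)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("evidence flags follow sensitivity and false-positive rate", {
  cfg <- tiny_config(seed = 5, evidence_sensitivity = 1, evidence_fpr = 0)
  b <- simulate_study(cfg)
  truth_keys <- paste(b$truth$planted_triples$mirna_id,
                      b$truth$planted_triples$mrna_id)
  ev_keys <- paste(b$evidence$mirna_id, b$evidence$mrna_id)
  expect_true(all(b$evidence$support[ev_keys %in% truth_keys] == 12))
  expect_true(all(b$evidence$support[!ev_keys %in% truth_keys] == 0))
  # every row carries exactly evidence_n_sources flag columns
  flag_cols <- setdiff(names(b$evidence), c("mirna_id", "mrna_id", "support"))
  expect_length(flag_cols, 12)
  expect_identical(flag_cols, default_source_names())

  # intermediate sensitivity: support is binomial around sens * n_sources
  cfg2 <- tiny_config(seed = 6, evidence_sensitivity = 0.5,
                      n_planted_triples = 6, n_mirna = 6,
                      n_planted_de_singletons = 0)
  ev2 <- simulate_evidence(simulate_study(cfg2)$truth$planted_triples, cfg2)
  truth_keys2 <- paste(simulate_study(cfg2)$truth$planted_triples$mirna_id,
                       simulate_study(cfg2)$truth$planted_triples$mrna_id)
  sup <- ev2$support[paste(ev2$mirna_id, ev2$mrna_id) %in% truth_keys2]
  expect_true(all(sup >= 0 & sup <= 12))
  # mean of 6 Binomial(12, 0.5) draws: within 4 sd of 6
  expect_lt(abs(mean(sup) - 6), 4 * sqrt(12 * 0.25 / length(sup)))
  # identical stream reproduces identical support
  ev3 <- simulate_evidence(simulate_study(cfg2)$truth$planted_triples, cfg2)
  expect_identical(ev2, ev3)
})

test_that("planted sequence sites are exact reverse complements", {
  cfg <- tiny_config(seed = 7)
  b <- simulate_study(cfg)
  for (i in seq_len(nrow(b$truth$planted_sites))) {
    site <- b$truth$planted_sites[i, ]
    mir <- b$sequences$mirna$seq[b$sequences$mirna$id == site$mirna_id]
    lnc <- b$sequences$lncrna$seq[b$sequences$lncrna$id == site$lncrna_id]
    expect_identical(substr(lnc, site$start, site$end), revcomp_oracle(mir))
  }

  weak_cfg <- tiny_config(seed = 8, site_strength = "weak")
  bw <- simulate_study(weak_cfg)
  site <- bw$truth$planted_sites[1, ]
  mir <- bw$sequences$mirna$seq[bw$sequences$mirna$id == site$mirna_id]
  lnc <- bw$sequences$lncrna$seq[bw$sequences$lncrna$id == site$lncrna_id]
  expect_identical(substr(lnc, site$start, site$end),
                   revcomp_oracle(substr(mir, 2, 8)))
  expect_equal(site$end - site$start + 1L, 7L)

  expect_error(simulate_study(tiny_config(seed = 9, lncrna_length = 20)),
               "shorter", class = "cernetr_input_error")
})

test_that("unplanted sequences rarely contain sites passing default gates", {
  n_clean <- vapply(1:20, function(s) {
    cfg <- tiny_config(seed = 100 + s, n_planted_triples = 0,
                       n_mirna = 4, n_lncrna = 6)
    b <- simulate_study(cfg)
    hits <- scan_duplexes(b$sequences$mirna, b$sequences$lncrna,
                          min_score = 140)
    nrow(screen_duplex_hits(hits)) == 0
  }, logical(1))
  expect_gte(mean(n_clean), 0.95)
})

test_that("validation tables behave at their planted parameters", {
  cfg0 <- tiny_config(seed = 10, planted_ddct = 0, ct_sd = 0)
  v0 <- simulate_validation_tables(cfg0)
  expect_equal(ddct_from_table(v0$ct)$fold, 1.0, tolerance = 1e-12)

  cfg_inf <- tiny_config(seed = 10, score_separation = Inf)
  vi <- simulate_validation_tables(cfg_inf)
  roc <- roc_auc(vi$scores, "score", "class", positive = "positive")
  expect_equal(roc$auc, 1.0)

  expect_identical(simulate_validation_tables(cfg0),
                   simulate_validation_tables(cfg0))
})
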