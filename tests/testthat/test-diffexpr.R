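make_paired_dataset <- function(m, n_pairs) {
  sample_id <- sprintf("s%02d", seq_len(2 * n_pairs))
  colnames(m) <- sample_id
  list(
    expr = dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)),
                            tibble::as_tibble(m)),
    metadata = tibble::tibble(
      sample_id = sample_id,
      subject_id = rep(sprintf("p%02d", seq_len(n_pairs)), each = 2),
      condition = rep(c("normal", "tumor"), times = n_pairs))
  )
}

test_that("BH adjustment matches the step-up oracle and validates input", {
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(c(1, 1, 1)), c(1, 1, 1))
  set.seed(42)
  for (i in 1:200) {
    p <- runif(sample(1:500, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(adjust_bh(c(0.5, 1.2)), class = "cernetr_input_error")
  expect_error(adjust_bh(c(-0.1)), class = "cernetr_input_error")
})

test_that("unmoderated paired t matches the closed form", {
  # pairs differ by (1, 2, 3): logFC 2, t = 2 / (1/sqrt(3)) = 3.4641, df 2
  normal <- c(5, 5, 5)
  tumor <- normal + c(1, 2, 3)
  m <- rbind(f1 = as.vector(rbind(normal, tumor)))
  ds <- make_paired_dataset(m, 3)
  de <- fit_de(ds$expr, ds$metadata, design = "paired", moderation = FALSE)
  expect_equal(de$logFC, 2)
  expect_equal(de$t_stat, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(de$t_stat, 3.4641, tolerance = 1e-4)
  expect_equal(de$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
})

test_that("unmoderated p-values match the t CDF on random matrices", {
  set.seed(7)
  m <- matrix(rnorm(20 * 12), nrow = 20,
              dimnames = list(sprintf("f%02d", 1:20), NULL))
  ds <- make_paired_dataset(m, 6)
  de <- fit_de(ds$expr, ds$metadata, design = "paired", moderation = FALSE)
  for (i in 1:20) {
    x <- m[i, seq(2, 12, 2)] - m[i, seq(1, 12, 2)]
    ht <- t.test(x)
    expect_equal(de$p[i], ht$p.value, tolerance = 1e-12)
    expect_equal(de$t_stat[i], unname(ht$statistic), tolerance = 1e-12)
  }
})

test_that("constant features give logFC 0 and ns; zero variance is flagged", {
  m <- rbind(flat = rep(3, 8), shift = rep(c(1, 2), 4))
  ds <- make_paired_dataset(m, 4)
  expect_warning(
    de <- fit_de(ds$expr, ds$metadata, design = "paired", moderation = FALSE),
    "zero residual variance")
  expect_equal(de$logFC[de$feature_id == "flat"], 0)
  expect_equal(de$p[de$feature_id == "flat"], 1)
  # constant within-pair difference of +1: logFC 1, zero variance, p = 0
  expect_equal(de$logFC[de$feature_id == "shift"], 1)
  expect_equal(de$p[de$feature_id == "shift"], 0)
  thr <- apply_de_thresholds(de, de_thresholds("adjusted", 0.05, 0.5))
  expect_equal(thr$direction[thr$feature_id == "flat"], "ns")
})

test_that("an infinite prior fixes the posterior variance at prior_var", {
  set.seed(8)
  m <- matrix(rnorm(10 * 10, sd = 0.3) + 5, nrow = 10,
              dimnames = list(sprintf("f%02d", 1:10), NULL))
  ds <- make_paired_dataset(m, 5)
  v0 <- 0.25
  de <- fit_de(ds$expr, ds$metadata, design = "paired", moderation = TRUE,
               prior_df = Inf, prior_var = v0)
  # analytic limit: t = logFC / sqrt(v0 / n_pairs), normal reference
  expect_equal(de$t_stat, de$logFC / sqrt(v0 / 5), tolerance = 1e-12)
  expect_equal(de$p, 2 * pt(-abs(de$t_stat), df = Inf), tolerance = 1e-12)
})

test_that("moderated statistics agree with the limma empirical-Bayes fit", {
  set.seed(9)
  n_pairs <- 6
  m <- matrix(rnorm(50 * 2 * n_pairs, sd = 0.5) + 6, nrow = 50,
              dimnames = list(sprintf("f%02d", 1:50), NULL))
  m[1:5, seq(2, 2 * n_pairs, 2)] <- m[1:5, seq(2, 2 * n_pairs, 2)] + 1.5
  ds <- make_paired_dataset(m, n_pairs)
  de <- fit_de(ds$expr, ds$metadata, design = "paired", moderation = TRUE)

  # oracle: limma on the within-pair differences, intercept-only design
  diffs <- m[, seq(2, 2 * n_pairs, 2)] - m[, seq(1, 2 * n_pairs, 2)]
  fit <- limma::eBayes(limma::lmFit(diffs, rep(1, n_pairs)))
  expect_equal(de$logFC, unname(fit$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(de$t_stat, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 1]), tolerance = 1e-8)

  # group design against the two-group limma fit
  grp_meta <- ds$metadata
  design <- cbind(1, grp_meta$condition == "tumor")
  fit2 <- limma::eBayes(limma::lmFit(m, design))
  de2 <- fit_de(ds$expr, ds$metadata, design = "group", moderation = TRUE)
  expect_equal(de2$logFC, unname(fit2$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(de2$t_stat, unname(fit2$t[, 2]), tolerance = 1e-8)
  expect_equal(de2$p, unname(fit2$p.value[, 2]), tolerance = 1e-8)
})

test_that("threshold calls use strict inequalities on the chosen p-field", {
  de <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"), kind = "mrna",
    logFC = c(1.2, 0.6, 1.0, -1.4),
    t_stat = 0, p = c(0.001, 0.03, 0.001, 0.001),
    adj_p = c(0.01, 0.2, 0.01, 0.01), direction = "ns")
  adj <- apply_de_thresholds(de, de_thresholds("adjusted", 0.05, 1))
  expect_equal(adj$direction, c("up", "ns", "ns", "down"))
  raw <- apply_de_thresholds(de, de_thresholds("raw", 0.05, 0.585))
  expect_equal(raw$direction[2], "up")
  # |logFC| exactly at the bound fails the strict inequality
  expect_equal(adj$direction[3], "ns")
})

test_that("the shipped accession presets carry the study thresholds", {
  pre <- de_threshold_presets()
  g618 <- pre[pre$accession == "GSE61850" & pre$kind == "mrna", ]
  expect_equal(g618$p_field, "adjusted")
  expect_equal(g618$abs_logfc_min, 1)
  g575_mir <- pre[pre$accession == "GSE57555" & pre$kind == "mirna", ]
  expect_equal(g575_mir$p_field, "raw")
  expect_equal(g575_mir$abs_logfc_min, 0.263)
  expect_equal(nrow(pre), 8)
})

test_that("consensus requires significance in every dataset of the kind", {
  rec <- function(id, dir, ds) {
    tibble::tibble(feature_id = id, kind = "lncrna", logFC = 1, t_stat = 1,
                   p = 0.01, adj_p = 0.02,
                   direction = dir, dataset_id = ds)
  }
  de <- dplyr::bind_rows(
    rec("A", "up", "d1"), rec("B", "up", "d1"), rec("C", "up", "d1"),
    rec("B", "up", "d2"), rec("C", "up", "d2"), rec("D", "up", "d2"),
    rec("A", "ns", "d2"))
  cons <- consensus_de(de)
  expect_setequal(cons$feature_id, c("B", "C"))
  expect_true(all(cons$consensus_direction == "up"))
  expect_true(all(cons$consistent))

  # conflicting direction across datasets: flagged, not silently dropped
  de2 <- dplyr::bind_rows(rec("E", "up", "d1"), rec("E", "down", "d2"))
  cons2 <- consensus_de(de2)
  expect_false(cons2$consistent)
  expect_equal(cons2$consensus_direction, "undetermined")

  expect_error(consensus_de(list()), class = "cernetr_input_error")
})
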