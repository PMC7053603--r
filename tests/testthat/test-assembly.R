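consensus_fixture <- function() {
  tibble::tibble(
    feature_id = c("g1", "g2", "l1", "l2", "m1", "m2"),
    kind = c("mrna", "mrna", "lncrna", "lncrna", "mirna", "mirna"),
    n_datasets = 2L,
    directions = "d1=up,d2=up",
    consistent = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    consensus_direction = c("up", "undetermined", "down", "undetermined",
                            "down", "undetermined"))
}

test_that("direction resolution applies the per-kind conflict policy", {
  dirs <- resolve_directions(consensus_fixture())
  expect_setequal(dirs$feature_id, c("g1", "l1", "m1", "m2"))
  expect_equal(dirs$direction[dirs$feature_id == "g1"], "up")
  expect_equal(dirs$direction[dirs$feature_id == "m2"], "undetermined")

  all_excl <- resolve_directions(consensus_fixture(),
                                 policy_mirna = "exclude")
  expect_false("m2" %in% all_excl$feature_id)
  all_keep <- resolve_directions(consensus_fixture(),
                                 policy_mrna = "undetermined",
                                 policy_lncrna = "undetermined")
  expect_setequal(all_keep$feature_id,
                  c("g1", "g2", "l1", "l2", "m1", "m2"))
})

test_that("triple assembly enforces all four membership predicates", {
  mir_lnc <- tibble::tibble(mirna_id = "m1", lncrna_id = "l1")
  mir_mrna <- tibble::tibble(mirna_id = "m1", mrna_id = "g1")
  lnc_mrna <- tibble::tibble(lncrna_id = "l1", mrna_id = "g1")
  dirs <- tibble::tibble(feature_id = c("l1", "g1", "m1"),
                         kind = c("lncrna", "mrna", "mirna"),
                         direction = c("down", "down", "up"))
  tri <- assemble_triples(mir_lnc, mir_mrna, lnc_mrna, dirs)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$lncrna_id, "l1")
  expect_equal(tri$mirna_direction, "up")

  # missing coexpression edge: no triple
  expect_equal(nrow(assemble_triples(mir_lnc, mir_mrna, lnc_mrna[0, ], dirs)), 0)

  # lncRNA and mRNA directions must agree
  dirs2 <- dirs; dirs2$direction <- c("up", "down", "up")
  expect_equal(nrow(assemble_triples(mir_lnc, mir_mrna, lnc_mrna, dirs2)), 0)

  # a determined miRNA must oppose the mRNA
  dirs3 <- dirs; dirs3$direction <- c("down", "down", "down")
  expect_equal(nrow(assemble_triples(mir_lnc, mir_mrna, lnc_mrna, dirs3)), 0)

  # an undetermined miRNA is allowed through
  dirs4 <- dirs; dirs4$direction <- c("down", "down", "undetermined")
  expect_equal(nrow(assemble_triples(mir_lnc, mir_mrna, lnc_mrna, dirs4)), 1)
})

test_that("assembled triples pass an independent predicate validator", {
  b <- simulate_study(tiny_config(seed = 41))
  run <- run_cerna_pipeline(b)
  ok <- validate_triples_oracle(run$triples, run$mir_lnc, run$mir_mrna,
                                run$lnc_mrna, run$directions)
  expect_true(all(ok))
  expect_gt(nrow(run$triples), 0)
})

test_that("network construction counts unweighted degrees", {
  empty <- build_network(tibble::tibble(
    lncrna_id = character(0), mirna_id = character(0),
    mrna_id = character(0), lnc_direction = character(0),
    mrna_direction = character(0), mirna_direction = character(0)))
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)

  one <- build_network(tibble::tibble(
    lncrna_id = "l1", mirna_id = "m1", mrna_id = "g1",
    lnc_direction = "up", mrna_direction = "up", mirna_direction = "down"))
  expect_equal(nrow(one$nodes), 3)
  expect_equal(nrow(one$edges), 3)
  expect_true(all(one$nodes$degree == 2))

  # one miRNA shared by 4 triples with distinct lncRNAs and mRNAs
  fan <- build_network(tibble::tibble(
    lncrna_id = sprintf("l%d", 1:4), mirna_id = "m1",
    mrna_id = sprintf("g%d", 1:4),
    lnc_direction = "up", mrna_direction = "up", mirna_direction = "down"))
  expect_equal(fan$nodes$degree[fan$nodes$id == "m1"], 8L)

  # regulatory-only degree drops the coexpression edges
  reg <- build_network(tibble::tibble(
    lncrna_id = "l1", mirna_id = "m1", mrna_id = "g1",
    lnc_direction = "up", mrna_direction = "up", mirna_direction = "down"),
    degree_edges = "regulatory")
  expect_equal(reg$nodes$degree[reg$nodes$id == "m1"], 2L)
  expect_equal(reg$nodes$degree[reg$nodes$id == "l1"], 1L)
})

test_that("degree sums to twice the edge count and matches igraph", {
  b <- simulate_study(tiny_config(seed = 42))
  run <- run_cerna_pipeline(b)
  net <- run$network
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  g <- igraph::graph_from_data_frame(net$edges[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = net$nodes$id)
  expect_equal(net$nodes$degree,
               unname(igraph::degree(g)[net$nodes$id]))
})

test_that("axis ranking follows the weighted composite and its ties", {
  expect_error(axis_weights(0.5, 0.5, 0.5), class = "cernetr_config_error")

  tri <- tibble::tibble(
    lncrna_id = "l1", mirna_id = "m1", mrna_id = "g1",
    lnc_direction = "up", mrna_direction = "up", mirna_direction = "down")
  net <- build_network(tri)
  de <- tibble::tibble(feature_id = c("l1", "m1", "g1"), kind = "x",
                       logFC = c(2, -2, 2), t_stat = 0, p = 0.01,
                       adj_p = 0.01, direction = c("up", "down", "up"),
                       dataset_id = "d1")
  ranked <- rank_axes(tri, net, de)
  expect_equal(ranked$rank, 1L)

  # larger mRNA degree wins when only degree is weighted
  tri2 <- dplyr::bind_rows(
    tibble::tibble(lncrna_id = "l1", mirna_id = "m1", mrna_id = "g1",
                   lnc_direction = "up", mrna_direction = "up",
                   mirna_direction = "down"),
    tibble::tibble(lncrna_id = "l1", mirna_id = "m1", mrna_id = "g2",
                   lnc_direction = "up", mrna_direction = "up",
                   mirna_direction = "down"),
    tibble::tibble(lncrna_id = "l2", mirna_id = "m2", mrna_id = "g2",
                   lnc_direction = "up", mrna_direction = "up",
                   mirna_direction = "down"))
  net2 <- build_network(tri2)
  de2 <- tibble::tibble(
    feature_id = c("l1", "l2", "m1", "m2", "g1", "g2"), kind = "x",
    logFC = 2, t_stat = 0, p = 0.01, adj_p = 0.01,
    direction = "up", dataset_id = "d1")
  ranked2 <- rank_axes(tri2, net2, de2, axis_weights(1, 0, 0))
  # g2 sits in two triples, so (l1, m1, g2) outranks (l1, m1, g1)
  r_g2 <- ranked2$rank[ranked2$mrna_id == "g2" & ranked2$lncrna_id == "l1"]
  r_g1 <- ranked2$rank[ranked2$mrna_id == "g1"]
  expect_lt(r_g2, r_g1)

  # identical scores break ties lexicographically
  ranked3 <- rank_axes(tri2, net2, de2, axis_weights(0, 0, 1))
  expect_equal(ranked3$axis_score, rep(ranked3$axis_score[1], 3))
  expect_equal(ranked3$lncrna_id, sort(ranked3$lncrna_id))
})

test_that("assembly and ranking are deterministic in output order", {
  b <- simulate_study(tiny_config(seed = 43))
  r1 <- run_cerna_pipeline(b)
  r2 <- run_cerna_pipeline(b)
  expect_identical(r1$triples, r2$triples)
  expect_identical(r1$axes, r2$axes)
  expect_true(!is.unsorted(rev(r1$axes$axis_score)))
})
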