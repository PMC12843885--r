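# Personalized PageRank, empirical p-scores, Fisher ORA and the enrichment
# wrappers.

test_that("PageRank reproduces symmetric and closed-form cases", {
  k3 <- new_fiems_graph(
    data.frame(id = c("a", "b", "c"), type = "compound", label = ""),
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  s <- personalized_pagerank(k3, c("a", "b", "c"))
  expect_equal(unname(s), rep(1 / 3, 3), tolerance = 1e-9)

  two <- new_fiems_graph(
    data.frame(id = c("A", "B"), type = "compound", label = ""),
    data.frame(from = "A", to = "B"))
  d <- 0.85
  s2 <- personalized_pagerank(two, "A", enrichment_config(damping = d))
  expect_equal(unname(s2["A"]), 1 / (1 + d), tolerance = 1e-8)
  expect_equal(unname(s2["B"]), d / (1 + d), tolerance = 1e-8)

  s3 <- personalized_pagerank(two, "A", enrichment_config(damping = 1e-9))
  expect_equal(unname(s3), c(1, 0), tolerance = 1e-6)

  expect_error(personalized_pagerank(two, "Z"), "absent.*Z")
})

test_that("PageRank sums to one and matches a dense linear solve", {
  set.seed(11)
  for (rep in 1:5) {
    g <- random_connected_graph(sample(10:50, 1))
    seeds <- sample(g$nodes$id, sample(1:4, 1))
    s <- personalized_pagerank(g, seeds)
    expect_equal(sum(s), 1, tolerance = 1e-8)
    expect_true(all(s >= 0))
    ref <- oracle_pagerank(g, seeds, 0.85)
    expect_equal(s[names(ref)], ref, tolerance = 1e-8)
  }
})

test_that("PageRank agrees with igraph on a random graph", {
  skip_if_not_installed("igraph")
  set.seed(12)
  g <- random_connected_graph(30)
  seeds <- sample(g$nodes$id, 3)
  s <- personalized_pagerank(g, seeds)
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = g$nodes$id)
  pers <- stats::setNames(numeric(30), g$nodes$id)
  pers[seeds] <- 1 / 3
  ref <- igraph::page_rank(ig, personalized = pers, damping = 0.85)$vector
  expect_equal(unname(s[g$nodes$id]), unname(ref[g$nodes$id]),
               tolerance = 1e-6)
})

test_that("p-scores are bounded, seeded and node-label invariant", {
  cfg <- tiny_config(seed = 14)
  g <- simulate_knowledge_graph(cfg)
  lib <- simulate_compound_library(cfg)
  seeds <- lib$planted_compound_ids
  cfg_e <- enrichment_config(n_null = 100, seed = 3)
  ps <- empirical_p_scores(g, seeds, cfg_e)
  expect_true(all(ps$p_score > 0 & ps$p_score <= 1))
  ps2 <- empirical_p_scores(g, seeds, cfg_e)
  expect_identical(ps, ps2)
  # planted pathway scores best among pathways
  pw <- ps[ps$type == "pathway", ]
  expect_equal(pw$node[1], "PTH001")
  expect_equal(pw$p_score[1], 1 / 101)
})

test_that("a node with no compound connectivity gets p-score near 1", {
  g <- random_connected_graph(10)
  g$nodes <- rbind(g$nodes, data.frame(id = "LONER", type = "pathway",
                                       label = "LONER"))
  ps <- empirical_p_scores(g, g$nodes$id[1:2],
                           enrichment_config(n_null = 50, seed = 1))
  expect_equal(ps$p_score[ps$node == "LONER"], 1)
})

test_that("one-sided Fisher matches hand computations and enumeration", {
  expect_equal(fisher_exact_one_sided(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(fisher_exact_one_sided(1, 0, 0, 1), 0.5, tolerance = 1e-12)
  expect_equal(fisher_exact_one_sided(0, 3, 4, 5), 1)
  expect_error(fisher_exact_one_sided(-1, 0, 0, 1), "non-negative")
  set.seed(13)
  for (i in 1:30) {
    tb <- sample(0:6, 4, replace = TRUE)
    if (sum(tb) == 0) next
    expect_equal(fisher_exact_one_sided(tb[1], tb[2], tb[3], tb[4]),
                 oracle_fisher(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("structural enrichment flags a pure-class cluster first", {
  asg <- data.frame(
    feature_id = paste0("f", 1:20),
    consensus_path = c(rep("K/Flavonoids", 6), rep("K/Sugars", 7),
                       rep("K/Lipids", 5), rep("", 2)),
    stringsAsFactors = FALSE)
  bg <- asg$feature_id
  res <- structural_enrichment(paste0("f", 1:6), bg, asg, level = 2)
  expect_equal(res$label[1], "Flavonoids")
  expect_equal(res$a[1], 6)
  # features without consensus at the level are excluded from margins
  expect_equal(res$a[1] + res$b[1] + res$c[1] + res$d[1], 18)
  expect_true(all(res$q >= res$p))
  expect_error(structural_enrichment(character(), bg, asg), "empty")
  expect_error(structural_enrichment("zzz", bg, asg), "subset")
})

test_that("functional enrichment recovers the planted pathway", {
  cfg <- tiny_config(seed = 15)
  ds <- simulate_dataset(cfg)
  asg <- data.frame(
    feature_id = c("x1", "x2"),
    compound_ids = c(paste(ds$library$planted_compound_ids[1:3],
                           collapse = ","),
                     ds$library$planted_compound_ids[4]),
    stringsAsFactors = FALSE)
  res <- functional_enrichment(asg, c("x1", "x2"), ds$graph,
                               enrichment_config(n_null = 100, seed = 2))
  expect_true("PTH001" %in% res$node)
  pw <- res[res$type == "pathway", ]
  expect_equal(pw$node[1], "PTH001")  # top-ranked pathway
  expect_equal(pw$p_score[1], min(res$p_score))

  # empty seed set: warning and empty table
  asg2 <- data.frame(feature_id = "x1", compound_ids = "",
                     stringsAsFactors = FALSE)
  expect_warning(res2 <- functional_enrichment(asg2, "x1", ds$graph),
                 "no compound")
  expect_equal(nrow(res2), 0)

  # threshold 0 cannot report anything (p-scores are strictly positive)
  res3 <- functional_enrichment(asg, c("x1", "x2"), ds$graph,
                                enrichment_config(n_null = 50, seed = 2,
                                                  p_threshold = 0))
  expect_equal(nrow(res3), 0)
})
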