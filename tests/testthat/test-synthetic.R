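# Synthetic-data generators: design structure, determinism, planted-trend
# limits, library and graph construction.

test_that("design has one record per stage x replicate plus QCs", {
  cfg <- tiny_config()
  d <- simulate_design(cfg)
  non_qc <- d[!d$is_qc, ]
  expect_equal(nrow(non_qc), 6 * 3)
  expect_equal(sum(d$is_qc), cfg$n_qc)
  expect_setequal(unique(non_qc$stage), green_stages())
  expect_true(all(non_qc$dry_weight <= non_qc$fresh_weight))
  expect_true(all(non_qc$fresh_weight > 0))
})

test_that("black-tea template has seven stages with arms on the last two", {
  cfg <- sim_config_black(seed = 3, n_features = 20, n_informative = 0,
                          n_trend_clusters = 1, n_compounds = 10)
  d <- simulate_design(cfg)
  non_qc <- d[!d$is_qc, ]
  expect_setequal(unique(non_qc$stage),
                  c("picking", "wither85", "wither70", "wither60", "rolling",
                    "oxidation", "roasting"))
  armed <- non_qc[!is.na(non_qc$arm), ]
  expect_setequal(unique(armed$stage), c("oxidation", "roasting"))
  expect_setequal(unique(armed$arm), c("4h", "overnight"))
  # each armed stage x arm has the full replicate set
  expect_equal(nrow(armed), 2 * 2 * 3)
})

test_that("generators are deterministic in (config, seed)", {
  cfg <- tiny_config(seed = 11)
  expect_identical(simulate_design(cfg), simulate_design(cfg))
  s1 <- simulate_feature_matrix(cfg)
  s2 <- simulate_feature_matrix(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_compound_library(cfg),
                   simulate_compound_library(cfg))
  g1 <- simulate_knowledge_graph(cfg)
  g2 <- simulate_knowledge_graph(cfg)
  expect_identical(g1$edges, g2$edges)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(replicates_per_stage = 1), "replicates")
  expect_error(sim_config(n_features = 10, n_informative = 20), "exceeds")
  expect_error(sim_config(n_informative = 5, n_trend_clusters = 9),
               "n_trend_clusters")
  expect_error(sim_config(stages = character()), "stages")
})

test_that("zero noise reproduces trend templates exactly", {
  cfg <- tiny_config(noise_sigma = 0)
  sim <- simulate_feature_matrix(cfg)
  mat <- weight_normalise(sim$matrix, sim$design)
  means <- stage_mean_profiles(mat, sim$design, cfg$stages)
  prof <- percent_relative_abundance(means)
  for (fid in sim$truth$informative_feature_ids) {
    cl <- sim$truth$cluster_membership[[fid]]
    expect_equal(unname(prof[fid, ]),
                 unname(sim$truth$trend_templates[cl, ]), tolerance = 1e-9)
  }
})

test_that("null data shows no systematic stage effect (ANOVA calibration)", {
  cfg <- sim_config(seed = 99, n_features = 1000, n_informative = 0,
                    n_trend_clusters = 1, noise_sigma = 0.2, ppm_jitter = 0,
                    n_compounds = 10, n_pathways = 2)
  sim <- simulate_feature_matrix(cfg)
  mat <- weight_normalise(sim$matrix, sim$design)
  non_qc <- sim$design[!sim$design$is_qc, ]
  stage <- factor(non_qc$stage)
  vals <- mat$values[, non_qc$sample_id]
  pvals <- apply(vals, 1, function(v)
    summary(stats::aov(v ~ stage))[[1]][["Pr(>F)"]][1])
  frac <- mean(pvals < 0.05)
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), ci + 1e-12)
})

test_that("compound library exercises tiering and consensus edge cases", {
  cfg <- tiny_config()
  lib <- simulate_compound_library(cfg)
  cmp <- lib$compounds
  expect_equal(nrow(cmp), cfg$n_compounds)
  expect_equal(sum(cmp$tier == "primary") + sum(cmp$tier == "fallback"),
               cfg$n_compounds)
  expect_true(all(vapply(strsplit(cmp$taxonomy_path, "/"), length, 1L) >= 3))
  # planted trio: one formula, three compounds, agreement to depth 2 only
  trio <- cmp[cmp$formula == cmp$formula[nrow(cmp)], ]
  trio <- trio[utils::tail(seq_len(nrow(trio)), 3), ]
  cons <- consensus_classification(trio$taxonomy_path, 0.66)
  expect_equal(cons$depth, 2)
})

test_that("knowledge graph is layered, planted and round-trips via TSV", {
  cfg <- tiny_config()
  g <- simulate_knowledge_graph(cfg)
  expect_equal(sum(g$nodes$type == "compound"), cfg$n_compounds)
  expect_equal(sum(g$nodes$type == "pathway"), cfg$n_pathways)
  expect_true(all(c("reaction", "enzyme", "module") %in% g$nodes$type))

  # planted pathway reachable from at least 80% of planted compounds
  lib <- simulate_compound_library(cfg)
  adj <- split(c(g$edges$to, g$edges$from), c(g$edges$from, g$edges$to))
  reaches <- vapply(lib$planted_compound_ids, function(cpd) {
    seen <- cpd; frontier <- cpd
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      if (g$planted_pathway_id %in% nxt) return(TRUE)
      seen <- c(seen, nxt); frontier <- nxt
    }
    FALSE
  }, TRUE)
  expect_gte(mean(reaches), 0.8)

  path <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, path)
  g2 <- read_graph_tsv(path)
  expect_setequal(g2$nodes$id, g$nodes$id)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_equal(key(g2$edges), key(g$edges))
})

test_that("spectra partition by polarity and respect the jitter scale", {
  cfg <- tiny_config(ppm_jitter = 3)
  sim <- simulate_feature_matrix(cfg)
  scans <- suppressWarnings(simulate_spectra(sim, cfg))
  s1 <- scans[[1]]
  pos_feats <- sim$matrix$features$bin_mz[
    sim$matrix$features$polarity == "positive"]
  neg_feats <- sim$matrix$features$bin_mz[
    sim$matrix$features$polarity == "negative"]
  for (sc in s1$positive) {
    near_neg <- vapply(sc$peaks[, "mz"], function(m)
      any(abs(neg_feats - m) < 0.004) && !any(abs(pos_feats - m) < 0.004),
      TRUE)
    expect_false(any(near_neg))
  }
  # observed relative jitter is on the configured ppm scale
  fid <- sim$matrix$features$id[1]
  true_mz <- sim$truth$feature_true_mz[[fid]]
  pol <- sim$matrix$features$polarity[1]
  obs <- unlist(lapply(scans, function(sm)
    vapply(sm[[pol]], function(sc) {
      i <- which.min(abs(sc$peaks[, "mz"] - true_mz))
      sc$peaks[i, "mz"]
    }, 0)))
  rel <- (obs - true_mz) / true_mz
  expect_lt(max(abs(rel)), 6 * 3e-6)
  expect_gt(sd(rel), 1e-6)   # jitter present
  expect_lt(sd(rel), 6e-6)   # on the right scale
})

test_that("zero-jitter spectra re-bin to the input matrix exactly", {
  cfg <- tiny_config(ppm_jitter = 0)
  sim <- simulate_feature_matrix(cfg)
  scans <- simulate_spectra(sim, cfg)
  mat2 <- bin_samples(scans)
  expect_setequal(rownames(mat2$values), rownames(sim$matrix$values))
  m2 <- mat2$values[rownames(sim$matrix$values), colnames(sim$matrix$values)]
  expect_equal(m2, sim$matrix$values, tolerance = 1e-12)
})
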