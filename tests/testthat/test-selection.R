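# Stage-response encoding, random-forest selection machinery, Welch/BH
# differential testing.

test_that("stage response is an ordinal encoding with arm filtering", {
  cfg <- sim_config_black(seed = 2, n_features = 20, n_informative = 0,
                          n_trend_clusters = 1, n_compounds = 10)
  d <- simulate_design(cfg)
  resp <- encode_stage_response(d, black_stages())
  expect_equal(unname(resp[d$sample_id[d$stage == "picking" & !d$is_qc]]),
               rep(0, 3))
  expect_equal(sort(unique(resp)), 0:6)

  resp4 <- encode_stage_response(d, black_stages(), arm = "4h")
  on_samples <- d$sample_id[!is.na(d$arm) & d$arm == "overnight"]
  expect_false(any(on_samples %in% names(resp4)))
  # label-based: row order does not matter
  resp_shuf <- encode_stage_response(d[sample(nrow(d)), ], black_stages())
  expect_equal(resp_shuf[names(resp)], resp)
  d_bad <- d; d_bad$stage[1] <- "mystery"
  expect_error(encode_stage_response(d_bad, black_stages()), "mystery")
})

test_that("rf_fit finds a duplicated response and is reproducible", {
  set.seed(1)
  n <- 18
  vals <- matrix(rlnorm(50 * n), 50, n)
  y <- rep(0:5, each = 3)
  vals[1, ] <- y  # response duplicated as a feature
  rownames(vals) <- paste0("f", 1:50)
  colnames(vals) <- paste0("s", 1:n)
  feats <- data.frame(id = rownames(vals), polarity = "negative",
                      bin_mz = 1:50)
  m <- new_fiems_matrix(vals, feats)
  resp <- stats::setNames(as.numeric(y), colnames(vals))
  fit <- rf_fit(m, resp, rf_config(n_trees = 300, mtry = 50, seed = 9))
  # OOB averaging across 6 stages x 3 replicates caps R2 near 0.8 even for
  # a perfect predictor; 0.7 distinguishes it sharply from noise (R2 <= 0)
  expect_gt(fit$r2, 0.7)
  expect_equal(names(which.max(fit$importance)), "f1")
  fit2 <- rf_fit(m, resp, rf_config(n_trees = 300, mtry = 50, seed = 9))
  expect_identical(fit$r2, fit2$r2)
  expect_error(rf_fit(m, stats::setNames(rep(1, n), colnames(vals)),
                      rf_config()), "distinct")
})

test_that("permutation p-values respect the add-one floor", {
  cfg <- tiny_config(seed = 4)
  sim <- simulate_feature_matrix(cfg)
  mat <- weight_normalise(sim$matrix, sim$design)
  resp <- encode_stage_response(sim$design, green_stages())
  sel <- select_features(mat, resp,
                         rf_config(n_trees = 50, n_trees_perm = 50,
                                   n_permutations = 30, seed = 4))
  B <- 30
  expect_true(all(sel$feature_p >= 1 / (B + 1)))
  expect_true(all(sel$feature_p <= 1))
  expect_gte(sel$model_p, 1 / (B + 1))
  # strong planted trends: the stage model is significant
  expect_lt(sel$model_p, 0.05)
  expect_gt(sel$r2, 0.5)
})

test_that("Welch test matches closed form and handles degenerate input", {
  w <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  w2 <- welch_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(w2$t, -1.095445, tolerance = 1e-6)
  expect_equal(w2$df, 6, tolerance = 1e-9)
  ref <- oracle_welch(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(w2$p, ref$p, tolerance = 1e-12)
  expect_equal(w2$p, 0.3153, tolerance = 1e-3)
  w3 <- welch_test(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_equal(w3$t, -w2$t)
  expect_equal(w3$p, w2$p)
  expect_equal(welch_test(c(5, 5, 5), c(5, 5))$p, 1)
  expect_error(welch_test(c(5, 5), c(7, 7)), "degenerate")
  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("differential testing partitions significant features by sign", {
  cfg <- sim_config_black(seed = 6, n_features = 120, n_informative = 0,
                          n_trend_clusters = 1, noise_sigma = 0.05,
                          n_compounds = 10)
  sim <- simulate_feature_matrix(cfg)
  mat <- weight_normalise(sim$matrix, sim$design)
  # plant 2x fold changes at the oxidation stage of the overnight arm
  on_ids <- sim$design$sample_id[!is.na(sim$design$arm) &
                                   sim$design$arm == "overnight" &
                                   sim$design$stage == "oxidation"]
  up <- rownames(mat$values)[1:10]
  dn <- rownames(mat$values)[11:20]
  mat$values[up, on_ids] <- mat$values[up, on_ids] * 2
  mat$values[dn, on_ids] <- mat$values[dn, on_ids] / 2

  res <- differential_features(mat, sim$design, "oxidation",
                               "4h", "overnight")
  sig <- res[res$significant, ]
  # detection power >= 80% at n = 3, with no false positives expected here
  expect_gte(mean(c(up, dn) %in% sig$feature_id), 0.8)
  expect_true(all(sig$feature_id %in% c(up, dn)))
  expect_true(all(sig$feature_id[sig$direction == "increased"] %in% up))
  expect_true(all(sig$feature_id[sig$direction == "decreased"] %in% dn))
  expect_true(all(res$q >= res$p))
  expect_error(differential_features(mat, sim$design, "picking",
                                     "4h", "overnight"), "replicates")
})
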