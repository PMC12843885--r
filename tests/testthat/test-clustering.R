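# k-means trend clustering, silhouette/WCSS diagnostics and k selection.

test_that("kmeans recovers an obvious 1-D partition exactly", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
              dimnames = list(paste0("f", 1:4), "s"))
  fit <- kmeans_profiles(x, 2, seed = 1)
  a <- fit$assignment
  expect_equal(a[["f1"]], a[["f2"]])
  expect_equal(a[["f3"]], a[["f4"]])
  expect_false(a[["f1"]] == a[["f3"]])
  expect_setequal(round(as.numeric(fit$centroids), 6), c(0.05, 10.05))
  expect_equal(fit$wcss, 2 * 0.05^2 * 2, tolerance = 1e-9)
})

test_that("k = n gives singleton clusters with zero WCSS", {
  set.seed(2)
  x <- matrix(rnorm(12), 4)
  rownames(x) <- paste0("f", 1:4)
  fit <- kmeans_profiles(x, 4, seed = 1)
  expect_equal(fit$wcss, 0, tolerance = 1e-12)
  expect_error(kmeans_profiles(x, 0, seed = 1), "k must")
  expect_error(kmeans_profiles(x, 5, seed = 1), "k must")
})

test_that("cluster labels are canonical and order-invariant", {
  set.seed(3)
  x <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(8, 5, 0.1), 4, 2))
  rownames(x) <- paste0("f", 1:14)
  fit <- kmeans_profiles(x, 2, seed = 5)
  # larger cluster gets label 1
  expect_equal(sum(fit$assignment == 1), 10)
  o <- sample(nrow(x))
  fit2 <- kmeans_profiles(x[o, ], 2, seed = 5)
  expect_equal(unname(fit2$assignment[rownames(x)]),
               unname(fit$assignment))
})

test_that("silhouette behaves at its extremes and matches cluster pkg", {
  far <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
               matrix(rnorm(20, 100, 0.05), 10, 2))
  asg <- rep(1:2, each = 10)
  s <- silhouette_mean(far, asg)
  expect_gt(s, 0.95)
  expect_lte(s, 1)
  set.seed(4)
  blob <- matrix(rnorm(60), 30, 2)
  s0 <- silhouette_mean(blob, sample(1:2, 30, replace = TRUE))
  expect_lt(abs(s0), 0.25)
  expect_error(silhouette_mean(blob, rep(1, 30)), ">= 2")
  expect_error(silhouette_mean(blob[1:2, ], 1:2), "singleton")
  skip_if_not_installed("cluster")
  ref <- mean(cluster::silhouette(asg, dist(far))[, "sil_width"])
  expect_equal(s, ref, tolerance = 1e-12)
})

test_that("WCSS definition and monotonicity hold", {
  set.seed(6)
  x <- matrix(rnorm(40), 20, 2)
  rownames(x) <- paste0("f", 1:20)
  expect_equal(wcss(x, 1:20), 0)
  tss <- sum(sweep(x, 2, colMeans(x))^2)
  expect_equal(wcss(x, rep(1, 20)), tss, tolerance = 1e-9)
  prev <- Inf
  for (k in 1:6) {
    fit <- kmeans_profiles(x, k, seed = 2, n_init = 10)
    expect_lte(fit$wcss, prev + 1e-9)
    prev <- fit$wcss
    expect_equal(wcss(x, fit$assignment[rownames(x)]), fit$wcss,
                 tolerance = 1e-6)
  }
})

test_that("select_k recommends the planted number of trend templates", {
  cfg <- tiny_config(seed = 8, noise_sigma = 0.02)
  sim <- simulate_feature_matrix(cfg)
  mat <- weight_normalise(sim$matrix, sim$design)
  inf <- sim$truth$informative_feature_ids
  means <- stage_mean_profiles(
    subset_matrix <- new_fiems_matrix(mat$values[inf, , drop = FALSE],
                                      mat$features[match(inf, mat$features$id), ]),
    sim$design, cfg$stages)
  prof <- percent_relative_abundance(means)
  ks <- select_k(prof, 2:6, seed = 1, n_init = 10)
  expect_equal(ks$recommended_k, 3)
  expect_equal(ks$diagnostics$k, 2:6)
  expect_error(select_k(prof, integer(), seed = 1), "empty")
  expect_error(select_k(prof, 2:50, seed = 1), "within")
})

test_that("best-of-restarts WCSS is no worse than a single restart", {
  set.seed(9)
  x <- matrix(rnorm(60), 30, 2)
  rownames(x) <- paste0("f", 1:30)
  multi <- kmeans_profiles(x, 4, seed = 3, n_init = 20)
  single <- kmeans_profiles(x, 4, seed = 3, n_init = 1)
  expect_lte(multi$wcss, single$wcss + 1e-9)
})
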