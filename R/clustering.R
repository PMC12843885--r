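# k-means trend clustering of percentage relative abundance profiles, with
# silhouette / WCSS diagnostics for choosing k.

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2L, centers[1, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) idx <- sample.int(n, 1)
      else idx <- sample.int(n, 1, prob = d2)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
  }
  centers
}

#' k-means clustering of trend profiles
#'
#' Lloyd's algorithm with k-means++ initialisation, best of `n_init`
#' restarts by within-cluster sum of squares (WCSS), Euclidean distance on
#' the profile vectors. Cluster labels are canonicalised by descending
#' cluster size.
#'
#' @param profiles Numeric matrix, features x stages (typically percentage
#'   relative abundance profiles).
#' @param k Number of clusters, `1 <= k <= nrow(profiles)`.
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 25).
#' @param max_iter Lloyd iterations per restart (default 300).
#' @return A `cluster_result` list: `k`, `assignment` (named integer
#'   vector), `centroids` (k x stages), `wcss`, `silhouette` (mean
#'   silhouette, `NA` for k = 1), `seed`, `n_init`.
#' @export
kmeans_profiles <- function(profiles, k, seed = 1L, n_init = 25L,
                            max_iter = 300L) {
  x <- as.matrix(profiles)
  n <- nrow(x)
  if (k < 1 || k > n) stopf("k must be in [1, %d]", n)
  set.seed(derive_seed(seed, 21L))
  best <- NULL
  for (i in seq_len(n_init)) {
    init <- kmeanspp_init(x, k)
    # duplicate initial centres make stats::kmeans fail; jitter them apart
    while (anyDuplicated(init))
      init[duplicated(init), ] <- init[duplicated(init), , drop = FALSE] +
        stats::rnorm(sum(duplicated(init)) * ncol(init), 0, 1e-8)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = max_iter,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  # canonical labels: clusters numbered by descending size
  sizes <- tabulate(best$cluster, nbins = k)
  relabel <- order(order(-sizes, seq_len(k)))
  assignment <- stats::setNames(relabel[best$cluster], rownames(x))
  centroids <- best$centers[order(-sizes, seq_len(k)), , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  sil <- if (k >= 2 && k < n) silhouette_mean(x, assignment) else NA_real_
  structure(list(k = k, assignment = assignment, centroids = centroids,
                 wcss = best$tot.withinss, silhouette = sil,
                 seed = seed, n_init = n_init),
            class = "cluster_result")
}

#' Mean silhouette coefficient
#'
#' For each point, `(b - a) / max(a, b)` with `a` the mean distance to its
#' own cluster and `b` the smallest mean distance to another cluster;
#' singleton-cluster points score 0. The mean over points lies in
#' `[-1, 1]`.
#'
#' @param profiles Numeric matrix of points (rows).
#' @param assignment Integer cluster labels, one per row.
#' @return Mean silhouette value.
#' @export
silhouette_mean <- function(profiles, assignment) {
  x <- as.matrix(profiles)
  cl <- as.integer(assignment)
  ks <- sort(unique(cl))
  if (length(ks) < 2) stopf("silhouette needs >= 2 clusters")
  sizes <- table(factor(cl, levels = ks))
  if (all(sizes == 1)) stopf("silhouette undefined: all clusters singletons")
  d <- as.matrix(stats::dist(x))
  s <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    own <- cl == cl[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(ks[ks != cl[i]], function(k2)
      mean(d[i, cl == k2]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Within-cluster sum of squares
#'
#' Sum over clusters of squared Euclidean distances to the cluster centroid.
#'
#' @inheritParams silhouette_mean
#' @return Non-negative scalar.
#' @export
wcss <- function(profiles, assignment) {
  x <- as.matrix(profiles)
  cl <- as.integer(assignment)
  total <- 0
  for (k in unique(cl)) {
    xs <- x[cl == k, , drop = FALSE]
    cen <- colMeans(xs)
    total <- total + sum(sweep(xs, 2L, cen)^2)
  }
  total
}

#' k-selection diagnostics
#'
#' Runs [kmeans_profiles()] for every k in `k_range` and tabulates the mean
#' silhouette and WCSS. The recommended k is the silhouette argmax; the
#' final choice remains the analyst's (typical pipelines also weigh WCSS
#' elbows and interpretability of the resulting trends).
#'
#' @param profiles Numeric matrix, features x stages.
#' @param k_range Integer vector of candidate k, within `[2, n - 1]`.
#' @param seed Integer seed.
#' @param n_init Restarts per k (default 25).
#' @return List: `diagnostics` (data frame `k`, `silhouette`, `wcss`),
#'   `recommended_k`.
#' @export
select_k <- function(profiles, k_range, seed = 1L, n_init = 25L) {
  n <- nrow(profiles)
  if (length(k_range) == 0) stopf("empty k range")
  if (any(k_range < 2) || any(k_range > n - 1))
    stopf("k_range must lie within [2, %d]", n - 1)
  rows <- lapply(k_range, function(k) {
    fit <- kmeans_profiles(profiles, k, seed = seed, n_init = n_init)
    data.frame(k = k, silhouette = fit$silhouette, wcss = fit$wcss)
  })
  diag <- do.call(rbind, rows)
  list(diagnostics = diag, recommended_k = diag$k[which.max(diag$silhouette)])
}
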