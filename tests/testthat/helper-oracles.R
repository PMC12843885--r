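# Shared fixtures and independent oracles used across the suite.

tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_features = 60L, n_informative = 12L,
         n_trend_clusters = 3L, noise_sigma = 0.05, ppm_jitter = 0,
         n_compounds = 30L, n_pathways = 3L),
    list(...))
  do.call(sim_config, args)
}

# Brute-force spectral binning: assign every peak independently, then average
# per-scan sums. Deliberately written as the simplest possible loop.
oracle_bin <- function(scans, bin_width = 0.01, mz_range = c(55, 1200)) {
  digits <- as.integer(round(-log10(bin_width)))
  sums <- list()
  for (s in seq_along(scans)) {
    pk <- scans[[s]]$peaks
    for (i in seq_len(nrow(pk))) {
      mz <- pk[i, "mz"]
      if (mz < mz_range[1] || mz > mz_range[2]) next
      bin <- sprintf(paste0("%.", digits, "f"),
                     floor(mz * 10^digits + 0.5) / 10^digits)
      key <- bin
      if (is.null(sums[[key]])) sums[[key]] <- numeric(length(scans))
      sums[[key]][s] <- sums[[key]][s] + pk[i, "intensity"]
    }
  }
  out <- vapply(sums, mean, 0)
  out[order(names(out))]
}

# Random centroided scan list.
random_scans <- function(n_scans, n_peaks, mz_range = c(55, 1200)) {
  lapply(seq_len(n_scans), function(s) {
    mz <- sort(runif(n_peaks, mz_range[1], mz_range[2]))
    list(scan_index = s,
         peaks = cbind(mz = mz, intensity = rlnorm(n_peaks, 8, 1)))
  })
}

# Nested-loop formula enumeration over small CHNOPS ranges (no shortcuts).
oracle_enumerate <- function(neutral_mass, ppm_tol, ranges) {
  masses <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
              O = 15.9949146221, P = 30.97376151, S = 31.97207069)
  lo <- neutral_mass * (1 - ppm_tol * 1e-6)
  hi <- neutral_mass * (1 + ppm_tol * 1e-6)
  found <- character()
  for (cc in ranges$C[1]:ranges$C[2])
    for (hh in ranges$H[1]:ranges$H[2])
      for (nn in ranges$N[1]:ranges$N[2])
        for (oo in ranges$O[1]:ranges$O[2])
          for (pp in ranges$P[1]:ranges$P[2])
            for (ss in ranges$S[1]:ranges$S[2]) {
              if (cc + hh + nn + oo + pp + ss == 0) next
              m <- cc * masses["C"] + hh * masses["H"] + nn * masses["N"] +
                oo * masses["O"] + pp * masses["P"] + ss * masses["S"]
              if (m < lo || m > hi) next
              r <- cc + 1 + (nn + pp) / 2 - hh / 2
              if (r < 0 || abs(r - round(r)) > 1e-9) next
              counts <- c(C = cc, H = hh, N = nn, O = oo, P = pp, S = ss)
              found <- c(found, format_formula(counts[counts > 0]))
            }
  sort(found)
}

# Literal level-by-level consensus count, independent of the implementation.
oracle_consensus <- function(paths, threshold) {
  split_paths <- strsplit(paths, "/", fixed = TRUE)
  n <- length(split_paths)
  prefix <- character()
  lev <- 1
  repeat {
    pool <- split_paths
    if (lev > 1) {
      pool <- Filter(function(p) length(p) >= lev - 1 &&
                       identical(p[seq_len(lev - 1)], prefix), pool)
    }
    labs <- unlist(lapply(pool, function(p)
      if (length(p) >= lev) p[[lev]] else NULL))
    if (length(labs) == 0) break
    tab <- table(labs)
    best <- max(tab)
    winners <- names(tab)[tab == best]
    if (length(winners) > 1) break
    if (best / n < threshold) break
    prefix <- c(prefix, winners)
    lev <- lev + 1
  }
  prefix
}

# Step-up BH, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# One-sided Fisher p by enumeration of all tables with the given margins.
oracle_fisher <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  prob <- function(x) exp(lchoose(col1, x) + lchoose(n - col1, row1 - x) -
                            lchoose(n, row1))
  xs <- max(0, row1 + col1 - n):min(row1, col1)
  sum(vapply(xs[xs >= a], prob, 0))
}

# Personalized PageRank by dense linear solve:
# (I - d W^T) s = (1 - d) r  (no dangling nodes assumed).
oracle_pagerank <- function(graph, seed_nodes, damping) {
  ids <- graph$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in seq_len(nrow(graph$edges))) {
    A[graph$edges$from[e], graph$edges$to[e]] <- 1
    A[graph$edges$to[e], graph$edges$from[e]] <- 1
  }
  W <- A / rowSums(A)
  r <- numeric(n); names(r) <- ids
  r[seed_nodes] <- 1 / length(seed_nodes)
  s <- solve(diag(n) - damping * t(W), (1 - damping) * r)
  stats::setNames(as.numeric(s), ids)
}

# Connected random undirected graph over n nodes (ring + random chords).
random_connected_graph <- function(n, extra_edges = n) {
  ids <- sprintf("N%02d", seq_len(n))
  edges <- data.frame(from = ids, to = ids[c(2:n, 1)])
  for (i in seq_len(extra_edges)) {
    ab <- sample(ids, 2)
    edges <- rbind(edges, data.frame(from = ab[1], to = ab[2]))
  }
  edges <- edges[!duplicated(t(apply(as.matrix(edges), 1, sort))), ]
  nodes <- data.frame(id = ids, type = "compound", label = ids,
                      stringsAsFactors = FALSE)
  new_fiems_graph(nodes, edges)
}

# Closed-form Welch statistics.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
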