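# Functional enrichment by personalized-PageRank diffusion on a typed
# compound knowledge graph with empirical null p-scores, and structural
# enrichment by Fisher's-exact over-representation of consensus classes.

#' Construct a typed knowledge graph
#'
#' @param nodes Data frame `id`, `type` (compound/reaction/enzyme/module/
#'   pathway), `label`.
#' @param edges Data frame `from`, `to` (undirected; endpoints must exist).
#' @return A `fiems_graph`.
#' @export
new_fiems_graph <- function(nodes, edges) {
  if (anyDuplicated(nodes$id)) stopf("duplicate node ids")
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad)) stopf("edge endpoint(s) not in node set: %s",
                         paste(utils::head(bad, 5), collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "fiems_graph")
}

#' @export
print.fiems_graph <- function(x, ...) {
  cat(sprintf("fiems_graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(table(x$nodes$type))
  invisible(x)
}

#' Write a knowledge graph as an edge-list TSV
#'
#' Columns: `from`, `to`, `from_type`, `to_type`, `from_label`, `to_label`.
#' The node table is fully recoverable from the edge list plus isolated
#' nodes, which are written as self-loop-free rows with empty `to`.
#'
#' @param graph A `fiems_graph`.
#' @param path Output TSV path.
#' @export
write_graph_tsv <- function(graph, path) {
  ntab <- graph$nodes
  idx_f <- match(graph$edges$from, ntab$id)
  idx_t <- match(graph$edges$to, ntab$id)
  df <- data.frame(from = graph$edges$from, to = graph$edges$to,
                   from_type = ntab$type[idx_f], to_type = ntab$type[idx_t],
                   from_label = ntab$label[idx_f], to_label = ntab$label[idx_t],
                   stringsAsFactors = FALSE)
  iso <- setdiff(ntab$id, c(graph$edges$from, graph$edges$to))
  if (length(iso)) {
    i <- match(iso, ntab$id)
    df <- rbind(df, data.frame(from = iso, to = "", from_type = ntab$type[i],
                               to_type = "", from_label = ntab$label[i],
                               to_label = "", stringsAsFactors = FALSE))
  }
  write_tsv(df, path)
}

#' Read a knowledge graph from an edge-list TSV
#' @param path TSV written by [write_graph_tsv()].
#' @return A `fiems_graph`.
#' @export
read_graph_tsv <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  real <- nzchar(df$to)
  ids <- c(df$from, df$to[real])
  types <- c(df$from_type, df$to_type[real])
  labels <- c(df$from_label, df$to_label[real])
  keep <- !duplicated(ids)
  nodes <- data.frame(id = ids[keep], type = types[keep],
                      label = labels[keep], stringsAsFactors = FALSE)
  nodes <- nodes[order(match(nodes$id, ids[keep])), ]
  edges <- data.frame(from = df$from[real], to = df$to[real],
                      stringsAsFactors = FALSE)
  new_fiems_graph(nodes, edges)
}

#' Enrichment configuration
#'
#' @param damping Restart damping factor in (0, 1); default 0.85.
#' @param n_null Null seed-set resamples for empirical p-scores (default
#'   1000).
#' @param p_threshold Reporting threshold on p-scores (default 0.05).
#' @param tol Power-iteration convergence tolerance (default 1e-10).
#' @param max_iter Maximum power iterations (default 1000).
#' @param seed Integer seed for the null resampling.
#' @return An `enrichment_config` list.
#' @export
enrichment_config <- function(damping = 0.85, n_null = 1000L,
                              p_threshold = 0.05, tol = 1e-10,
                              max_iter = 1000L, seed = 1L) {
  if (damping <= 0 || damping >= 1) stopf("damping must be in (0, 1)")
  if (n_null < 1) stopf("n_null must be >= 1")
  structure(list(damping = damping, n_null = as.integer(n_null),
                 p_threshold = p_threshold, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "enrichment_config")
}

# Row-normalised adjacency (transition matrix) of the undirected graph.
transition_matrix <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  fi <- match(graph$edges$from, ids)
  ti <- match(graph$edges$to, ids)
  for (e in seq_along(fi)) {
    A[fi[e], ti[e]] <- 1
    A[ti[e], fi[e]] <- 1
  }
  deg <- rowSums(A)
  W <- A / ifelse(deg == 0, 1, deg)
  list(W = W, dangling = deg == 0)
}

# Batched power iteration: each column of R is a restart distribution;
# dangling-node mass is redistributed to the restart vector.
pagerank_iterate <- function(W, dangling, R, damping, tol, max_iter) {
  S <- R
  tW <- t(W)
  for (it in seq_len(max_iter)) {
    dangling_mass <- colSums(S[dangling, , drop = FALSE])
    S_new <- (1 - damping) * R + damping * (tW %*% S) +
      damping * sweep(R, 2L, dangling_mass, `*`)
    if (max(abs(S_new - S)) < tol) return(S_new)
    S <- S_new
  }
  S
}

#' Personalized PageRank diffusion scores
#'
#' Fixed point of `s = (1 - d) r + d W' s`, with restart vector `r` uniform
#' over the seed nodes and `W` the row-normalised adjacency of the
#' undirected graph; mass on dangling (degree-0) nodes is redistributed to
#' the restart vector. Scores are non-negative and sum to 1 over the graph.
#'
#' @param graph A `fiems_graph`.
#' @param seed_nodes Character vector of node ids to restart on.
#' @param config An [enrichment_config()].
#' @return Named numeric score vector over all nodes.
#' @export
personalized_pagerank <- function(graph, seed_nodes,
                                  config = enrichment_config()) {
  if (length(seed_nodes) == 0) stopf("seed_nodes must be non-empty")
  missing <- setdiff(seed_nodes, graph$nodes$id)
  if (length(missing))
    stopf("seed node(s) absent from graph: %s",
          paste(missing, collapse = ", "))
  tm <- transition_matrix(graph)
  r <- stats::setNames(numeric(nrow(graph$nodes)), graph$nodes$id)
  r[unique(seed_nodes)] <- 1 / length(unique(seed_nodes))
  s <- pagerank_iterate(tm$W, tm$dangling, matrix(r, ncol = 1),
                        config$damping, config$tol, config$max_iter)
  stats::setNames(as.numeric(s), graph$nodes$id)
}

#' Empirical p-scores for diffusion enrichment
#'
#' Observed personalized-PageRank scores from the compound seed set are
#' compared with `n_null` runs seeded on uniformly resampled compound-node
#' sets of the same size. Add-one empirical tail probability:
#' `p = (1 + #(null score >= observed)) / (n_null + 1)`.
#'
#' @param graph A `fiems_graph`.
#' @param seed_compounds Character vector of compound node ids.
#' @param config An [enrichment_config()].
#' @return Data frame `node`, `type`, `label`, `score`, `p_score`, sorted by
#'   `p_score`; seed compounds themselves are excluded.
#' @export
empirical_p_scores <- function(graph, seed_compounds,
                               config = enrichment_config()) {
  if (config$n_null < 1) stopf("n_null must be >= 1")
  compounds <- graph$nodes$id[graph$nodes$type == "compound"]
  if (length(compounds) < length(unique(seed_compounds)))
    stopf("graph has fewer compound nodes than seeds")
  obs <- personalized_pagerank(graph, seed_compounds, config)

  tm <- transition_matrix(graph)
  ids <- graph$nodes$id
  k <- length(unique(seed_compounds))
  set.seed(derive_seed(config$seed, 31L))
  R <- matrix(0, length(ids), config$n_null, dimnames = list(ids, NULL))
  for (b in seq_len(config$n_null)) {
    null_seeds <- sample(compounds, k)
    R[null_seeds, b] <- 1 / k
  }
  S <- pagerank_iterate(tm$W, tm$dangling, R, config$damping, config$tol,
                        config$max_iter)
  exceed <- rowSums(S >= obs[ids])
  p <- (1 + exceed) / (config$n_null + 1)
  out <- data.frame(node = ids, type = graph$nodes$type,
                    label = graph$nodes$label, score = obs[ids],
                    p_score = p, stringsAsFactors = FALSE)
  out <- out[!(out$node %in% seed_compounds), ]
  out <- out[order(out$p_score, -out$score), ]
  rownames(out) <- NULL
  out
}

#' Functional enrichment of a selected feature set
#'
#' The seed set is the union of matched compound nodes of the selected
#' features (from their assignments); pathway and module nodes whose
#' empirical p-score is at or below the threshold are reported.
#'
#' @param assignments Output of [assign_features()].
#' @param selected_features Character vector of feature ids.
#' @param graph A `fiems_graph`.
#' @param config An [enrichment_config()].
#' @return Data frame `node`, `type`, `label`, `score`, `p_score` of
#'   significant pathway/module nodes (possibly empty), sorted by p-score.
#' @export
functional_enrichment <- function(assignments, selected_features, graph,
                                  config = enrichment_config()) {
  sel <- assignments[assignments$feature_id %in% selected_features, ]
  cpds <- unique(unlist(strsplit(sel$compound_ids[nzchar(sel$compound_ids)],
                                 ",", fixed = TRUE)))
  cpds <- intersect(cpds, graph$nodes$id[graph$nodes$type == "compound"])
  if (length(cpds) == 0) {
    warnf("selected features map to no compound nodes; empty enrichment")
    return(data.frame(node = character(), type = character(),
                      label = character(), score = numeric(),
                      p_score = numeric()))
  }
  scores <- empirical_p_scores(graph, cpds, config)
  res <- scores[scores$type %in% c("pathway", "module") &
                  scores$p_score <= config$p_threshold, ]
  rownames(res) <- NULL
  res
}

#' One-sided Fisher's exact test (enrichment tail)
#'
#' Hypergeometric upper-tail probability `P(X >= a)` for the 2x2 table with
#' cells `a, b / c, d` and fixed margins.
#'
#' @param a,b,c,d Non-negative integer cell counts (`a` = in-set and
#'   in-class).
#' @return One-sided p-value.
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stopf("counts must be non-negative")
  if (a + b + c + d == 0) stopf("empty table")
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Structural enrichment of a feature cluster by consensus class
#'
#' For each taxonomy label observed at the chosen level, tests
#' over-representation in the cluster versus the background with a one-sided
#' Fisher's exact test, BH-adjusted across the labels of the run. Features
#' whose consensus does not reach the level are excluded from both margins.
#'
#' @param cluster_features Feature ids of the cluster (subset of background).
#' @param background_features Feature ids of the background set.
#' @param assignments Output of [assign_features()].
#' @param level Taxonomy level to test at (1 = kingdom, 2 = superclass, ...).
#' @return Data frame `label`, `a`, `b`, `c`, `d`, `p`, `q`, sorted by `p`.
#' @export
structural_enrichment <- function(cluster_features, background_features,
                                  assignments, level = 2L) {
  if (length(cluster_features) == 0) stopf("empty cluster")
  if (!all(cluster_features %in% background_features))
    stopf("cluster must be a subset of the background")
  idx <- match(assignments$feature_id, background_features)
  ann <- assignments[!is.na(idx), ]
  labs <- vapply(strsplit(ann$consensus_path, "/", fixed = TRUE),
                 function(p) if (length(p) >= level) p[[level]]
                 else NA_character_, "")
  ok <- !is.na(labs)
  ann <- ann[ok, ]; labs <- labs[ok]
  if (nrow(ann) == 0)
    return(data.frame(label = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p = numeric(),
                      q = numeric()))
  in_cluster <- ann$feature_id %in% cluster_features
  out <- lapply(unique(labs), function(lb) {
    in_class <- labs == lb
    a <- sum(in_cluster & in_class)
    b <- sum(in_cluster & !in_class)
    cc <- sum(!in_cluster & in_class)
    dd <- sum(!in_cluster & !in_class)
    data.frame(label = lb, a = a, b = b, c = cc, d = dd,
               p = fisher_exact_one_sided(a, b, cc, dd),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$q <- bh_adjust(res$p)
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  res
}
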