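# Stage-discriminatory feature selection: random-forest regression on the
# ordered process stages with permutation significance, plus Welch's t-test /
# BH-FDR differential analysis between process arms.

#' Random-forest configuration
#'
#' @param n_trees Trees in the main model fit (default 1000).
#' @param n_trees_perm Trees per permuted-response refit (default 200); the
#'   null distributions of model R-squared and feature importance are built
#'   from these refits.
#' @param n_permutations Number of permuted-response refits (default 3000).
#' @param alpha Selection threshold on permutation p-values (default 0.05).
#' @param mtry Features tried per split; default `floor(p / 3)` (regression
#'   convention), computed at fit time when `NULL`.
#' @param seed Integer seed (mandatory for reproducible forests).
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 1000L, n_trees_perm = 200L,
                      n_permutations = 3000L, alpha = 0.05, mtry = NULL,
                      seed = 1L) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(list(n_trees = as.integer(n_trees),
                 n_trees_perm = as.integer(n_trees_perm),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, mtry = mtry, seed = as.integer(seed)),
            class = "rf_config")
}

#' Encode process stages as a numeric regression response
#'
#' Stages are mapped to equally spaced ordinal integers starting at 0, in
#' declared temporal order. With `arm` given, samples are filtered to the
#' shared (un-armed) early stages plus that arm's branched stages.
#'
#' @param sample_table Design data frame (`sample_id`, `stage`, `arm`,
#'   `is_qc`).
#' @param stages Ordered stage labels.
#' @param arm Optional arm label (e.g. `"4h"`).
#' @return Named numeric vector (names = sample ids) of stage indices; QC
#'   samples are excluded.
#' @export
encode_stage_response <- function(sample_table, stages, arm = NULL) {
  st <- sample_table[!sample_table$is_qc, ]
  if (!is.null(arm)) st <- st[is.na(st$arm) | st$arm == arm, ]
  idx <- match(st$stage, stages)
  if (any(is.na(idx)))
    stopf("unknown stage label(s): %s",
          paste(unique(st$stage[is.na(idx)]), collapse = ", "))
  stats::setNames(as.numeric(idx - 1L), st$sample_id)
}

# Internal: one seeded ranger regression fit on samples x features.
fit_forest <- function(x, y, n_trees, mtry, seed, importance = "permutation") {
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  df <- data.frame(.y = y, x, check.names = FALSE)
  ranger::ranger(dependent.variable.name = ".y", data = df,
                 num.trees = n_trees, mtry = mtry, importance = importance,
                 seed = seed, num.threads = 1, respect.unordered.factors = FALSE)
}

#' Fit a random-forest stage-regression model
#'
#' Seeded regression forest of the numeric stage response on all features;
#' model quality is the out-of-bag R-squared
#' `1 - OOB-MSE / Var(response)`. Per-feature importance is the percentage
#' increase in OOB mean squared error when the feature is permuted
#' (%IncMSE).
#'
#' @param matrix A `fiems_matrix`.
#' @param response Named numeric response from [encode_stage_response()];
#'   only named samples are used.
#' @param config An [rf_config()].
#' @return List: `model` (ranger object), `r2`, `oob_mse`, `importance`
#'   (named %IncMSE vector).
#' @export
rf_fit <- function(matrix, response, config = rf_config()) {
  ids <- intersect(names(response), colnames(matrix$values))
  if (length(unique(response[ids])) < 2)
    stopf("response must take at least 2 distinct values")
  x <- t(matrix$values[, ids, drop = FALSE])
  y <- response[ids]
  fit <- fit_forest(x, y, config$n_trees, config$mtry, config$seed)
  oob_mse <- fit$prediction.error
  imp <- 100 * fit$variable.importance / oob_mse
  list(model = fit, r2 = fit$r.squared, oob_mse = oob_mse, importance = imp)
}

#' Permutation-based feature selection with model significance
#'
#' Fits the main forest, then refits `n_permutations` forests on permuted
#' responses (at `n_trees_perm` trees) to build null distributions of both
#' the model R-squared and every feature's importance. Add-one permutation
#' p-values:
#' `p = (1 + #(null >= observed)) / (n_permutations + 1)`.
#' For the feature-level comparison the observed importances are taken from
#' a forest of the same size as the null refits, so observed and null values
#' are exchangeable under the null.
#'
#' @inheritParams rf_fit
#' @return List: `r2`, `model_p`, `importance` (%IncMSE from the main fit),
#'   `feature_p` (named vector), `selected` (feature ids with
#'   `feature_p < alpha`), `config`.
#' @export
select_features <- function(matrix, response, config = rf_config()) {
  ids <- intersect(names(response), colnames(matrix$values))
  x <- t(matrix$values[, ids, drop = FALSE])
  y <- response[ids]
  if (length(unique(y)) < 2) stopf("response must take >= 2 distinct values")

  main <- rf_fit(matrix, response, config)

  # Observed importances for the permutation comparison, at the null refit
  # tree count (exchangeability with the null draws).
  obs_fit <- if (config$n_trees == config$n_trees_perm) main$model else
    fit_forest(x, y, config$n_trees_perm, config$mtry, config$seed)
  # Comparison happens on the %IncMSE scale: each fit's raw permutation
  # importances are normalised by that fit's own OOB MSE.
  obs_imp <- 100 * obs_fit$variable.importance / obs_fit$prediction.error

  B <- config$n_permutations
  r2_null <- numeric(B)
  exceed <- numeric(length(obs_imp))
  set.seed(derive_seed(config$seed, 11L))
  perm_seeds <- sample.int(2147483000L, B)
  for (b in seq_len(B)) {
    yp <- sample(y)
    fit <- fit_forest(x, yp, config$n_trees_perm, config$mtry, perm_seeds[b])
    r2_null[b] <- fit$r.squared
    null_imp <- 100 * fit$variable.importance / fit$prediction.error
    exceed <- exceed + (null_imp >= obs_imp)
  }
  model_p <- (1 + sum(r2_null >= main$r2)) / (B + 1)
  feature_p <- (1 + exceed) / (B + 1)
  names(feature_p) <- colnames(x)
  selected <- names(feature_p)[feature_p < config$alpha]
  list(r2 = main$r2, model_p = model_p, importance = main$importance,
       feature_p = feature_p, selected = selected, config = config)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch's t-test with Welch-Satterthwaite degrees of freedom.
#' Degenerate inputs follow the convention: both groups constant with equal
#' means gives `t = 0, p = 1`; constant groups with unequal means are flagged
#' as an error (the test statistic is undefined).
#'
#' @param group_a,group_b Numeric vectors, each with >= 2 values.
#' @return List: `t`, `df`, `p`.
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("each group needs >= 2 values")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, df = NA_real_, p = 1))
    stopf("degenerate input: zero variance with unequal means")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stopf("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Differential features between two process arms at a stage
#'
#' Per-feature Welch's t-test of arm B versus arm A at the given stage, with
#' BH adjustment across features; significant features are partitioned by
#' sign of the mean difference (`mean_b - mean_a`).
#'
#' @param matrix A `fiems_matrix`.
#' @param sample_table Design data frame.
#' @param stage Stage label at which to compare.
#' @param arm_a,arm_b Arm labels (e.g. `"4h"`, `"overnight"`).
#' @param alpha Significance threshold on q (default 0.05).
#' @return Data frame: `feature_id`, `t`, `df`, `p`, `q`, `direction`
#'   (`"increased"`/`"decreased"` in arm B vs arm A), `significant`.
#' @export
differential_features <- function(matrix, sample_table, stage, arm_a, arm_b,
                                  alpha = 0.05) {
  st <- sample_table[!sample_table$is_qc, ]
  ids_a <- st$sample_id[st$stage == stage & !is.na(st$arm) & st$arm == arm_a]
  ids_b <- st$sample_id[st$stage == stage & !is.na(st$arm) & st$arm == arm_b]
  ids_a <- intersect(ids_a, colnames(matrix$values))
  ids_b <- intersect(ids_b, colnames(matrix$values))
  if (length(ids_a) < 2 || length(ids_b) < 2)
    stopf("stage '%s' needs >= 2 replicates in both arms", stage)
  va <- matrix$values[, ids_a, drop = FALSE]
  vb <- matrix$values[, ids_b, drop = FALSE]
  n <- nrow(va)
  t_ <- df_ <- p_ <- numeric(n)
  for (i in seq_len(n)) {
    w <- welch_test(va[i, ], vb[i, ])
    t_[i] <- w$t; df_[i] <- w$df; p_[i] <- w$p
  }
  q_ <- bh_adjust(p_)
  dirn <- ifelse(rowMeans(vb) - rowMeans(va) >= 0, "increased", "decreased")
  data.frame(feature_id = rownames(va), t = t_, df = df_, p = p_, q = q_,
             direction = dirn, significant = q_ < alpha,
             stringsAsFactors = FALSE)
}
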