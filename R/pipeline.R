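# Orchestration of the full green-tea and black-tea analyses on a prepared
# dataset: binning/normalisation/filtering, stage-regression selection,
# trend clustering, formula assignment, and functional + structural
# enrichment, with paper-shaped TSV reports and a run report of counts.

#' Pipeline configuration
#'
#' Bundles a dataset (typically from [simulate_dataset()], or assembled from
#' files via the reader functions) with all module parameters.
#'
#' @param dataset List with `design`, `matrix` (or `scans`), `library`,
#'   `graph`, and optionally `truth` (see [simulate_dataset()]).
#' @param stages Ordered stage labels of the design.
#' @param arms Arm labels for branched designs (empty for green).
#' @param k Number of trend clusters (the study convention is 15; choose to
#'   suit the data size).
#' @param rf An [rf_config()].
#' @param enrich An [enrichment_config()].
#' @param occupancy_threshold,qc_max_rsd Filter thresholds.
#' @param ppm_tol Assignment tolerance (ppm).
#' @param taxonomy_level Level for structural enrichment (default 2,
#'   superclass).
#' @param alpha Significance threshold for differential tests.
#' @param out_dir Directory for TSV reports (default: none written).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dataset, stages, arms = character(), k = 15L,
                            rf = rf_config(), enrich = enrichment_config(),
                            occupancy_threshold = 2 / 3, qc_max_rsd = 0.5,
                            ppm_tol = 3, taxonomy_level = 2L, alpha = 0.05,
                            out_dir = NULL, seed = 1L) {
  structure(list(dataset = dataset, stages = stages, arms = arms,
                 k = as.integer(k), rf = rf, enrich = enrich,
                 occupancy_threshold = occupancy_threshold,
                 qc_max_rsd = qc_max_rsd, ppm_tol = ppm_tol,
                 taxonomy_level = as.integer(taxonomy_level), alpha = alpha,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Shared front end: (bin if needed) -> weight-normalise -> occupancy + QC
# filter. Returns the filtered matrix plus step counts.
prepare_matrix <- function(pc) {
  ds <- pc$dataset
  design <- ds$design
  mat <- if (!is.null(ds$matrix)) ds$matrix else bin_samples(ds$scans)
  counts <- list(features_binned = nrow(mat$values))
  mat <- weight_normalise(mat, design)
  labels <- ifelse(design$is_qc[match(colnames(mat$values),
                                      design$sample_id)],
                   "QC", design$stage[match(colnames(mat$values),
                                            design$sample_id)])
  mat <- occupancy_filter(mat, labels, pc$occupancy_threshold)
  counts$features_after_occupancy <- nrow(mat$values)
  qc_ids <- design$sample_id[design$is_qc]
  if (length(qc_ids) >= 2) {
    mat <- qc_filter(mat, qc_ids, pc$qc_max_rsd)
    counts$features_after_qc <- nrow(mat$values)
  }
  list(matrix = mat, counts = counts)
}

# One selection + clustering + enrichment pass for a stage arm (or the
# un-armed design when arm is NULL).
analyse_arm <- function(pc, mat, assignments, arm = NULL,
                        label = if (is.null(arm)) "all" else arm) {
  ds <- pc$dataset
  response <- encode_stage_response(ds$design, pc$stages, arm)
  sel <- select_features(mat, response, pc$rf)

  k <- min(pc$k, max(1L, length(sel$selected) - 1L))
  cluster <- NULL
  profiles <- NULL
  if (length(sel$selected) >= 2) {
    sub <- subset_features(mat, mat$features$id %in% sel$selected)
    means <- stage_mean_profiles(sub, ds$design, pc$stages, arm)
    profiles <- percent_relative_abundance(means)
    cluster <- kmeans_profiles(profiles, k, seed = pc$seed)
  }

  func <- list()
  struct <- list()
  if (!is.null(cluster)) {
    for (cl in seq_len(cluster$k)) {
      feats <- names(cluster$assignment)[cluster$assignment == cl]
      fe <- suppressWarnings(
        functional_enrichment(assignments, feats, ds$graph, pc$enrich))
      if (nrow(fe) > 0)
        func[[length(func) + 1L]] <- cbind(arm = label, cluster = cl, fe)
      se <- structural_enrichment(feats, mat$features$id, assignments,
                                  pc$taxonomy_level)
      se <- se[se$q < pc$alpha, , drop = FALSE]
      if (nrow(se) > 0)
        struct[[length(struct) + 1L]] <- cbind(arm = label, cluster = cl, se)
    }
  }
  list(label = label, selection = sel, cluster = cluster,
       profiles = profiles,
       functional = if (length(func)) do.call(rbind, func) else NULL,
       structural = if (length(struct)) do.call(rbind, struct) else NULL)
}

write_reports <- function(results, pc, prefix) {
  if (is.null(pc$out_dir)) return(character())
  dir.create(pc$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  put <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return()
    path <- file.path(pc$out_dir, paste0(prefix, "_", name, ".tsv"))
    df <- as.data.frame(lapply(df, function(col)
      if (is.numeric(col)) signif(col, 10) else col))
    write_tsv(df, path)
    manifest <<- c(manifest, path)
  }
  for (res in results$arms) {
    tag <- res$label
    sel_df <- data.frame(feature_id = names(res$selection$feature_p),
                         pct_inc_mse = unname(
                           res$selection$importance[names(res$selection$feature_p)]),
                         p = unname(res$selection$feature_p),
                         selected = names(res$selection$feature_p) %in%
                           res$selection$selected)
    put(sel_df, paste0(tag, "_selection"))
    if (!is.null(res$cluster)) {
      put(data.frame(feature_id = names(res$cluster$assignment),
                     cluster = unname(res$cluster$assignment)),
          paste0(tag, "_clusters"))
      put(cbind(data.frame(cluster = rownames(res$cluster$centroids)),
                as.data.frame(res$cluster$centroids)),
          paste0(tag, "_centroids"))
    }
    put(res$functional, paste0(tag, "_functional_enrichment"))
    put(res$structural, paste0(tag, "_structural_enrichment"))
  }
  put(results$assignments, "assignments")
  if (!is.null(results$differential)) {
    put(results$differential, "differential")
    put(results$differential_enrichment, "differential_enrichment")
  }
  manifest
}

#' Run the green-tea (unbranched) analysis
#'
#' Executes normalisation and filtering, random-forest stage selection,
#' trend clustering of the selected features' percentage profiles, formula
#' assignment, and per-cluster functional + structural enrichment. A report
#' in the shape cluster / pathway id / name / p-score is produced.
#'
#' @param pc A [pipeline_config()] whose design has no arms.
#' @return A `run_report` list: `counts`, `arms` (one analysis result),
#'   `assignments`, `manifest`, `seed`.
#' @export
run_green <- function(pc) {
  stopifnot(inherits(pc, "pipeline_config"))
  missing_stages <- setdiff(pc$stages,
                            unique(stats::na.omit(pc$dataset$design$stage)))
  if (length(missing_stages))
    stopf("design lacks stage(s): %s", paste(missing_stages, collapse = ", "))
  prep <- prepare_matrix(pc)
  assignments <- assign_features(prep$matrix, pc$dataset$library$compounds,
                                 ppm_tol = pc$ppm_tol)
  res <- analyse_arm(pc, prep$matrix, assignments)
  counts <- prep$counts
  counts$features_selected <- length(res$selection$selected)
  out <- list(counts = counts, arms = list(res), assignments = assignments,
              matrix = prep$matrix, seed = pc$seed)
  out$manifest <- write_reports(out, pc, "green")
  class(out) <- "run_report"
  out
}

#' Run the black-tea (two-arm) analysis
#'
#' Runs a selection + clustering + enrichment pass per oxidation arm, then
#' Welch/BH differential tests between the arms at the branched stages, with
#' functional and structural enrichment of the increased and decreased
#' feature sets (report rows in the shape comparison / trend / id / name /
#' p-score).
#'
#' @param pc A [pipeline_config()] with two arms branching at the late
#'   stages.
#' @return A `run_report` list: `counts`, `arms` (one result per arm),
#'   `assignments`, `differential`, `differential_enrichment`, `manifest`.
#' @export
run_black <- function(pc) {
  stopifnot(inherits(pc, "pipeline_config"))
  if (length(pc$arms) != 2) stopf("black design needs exactly 2 arms")
  missing_stages <- setdiff(pc$stages,
                            unique(stats::na.omit(pc$dataset$design$stage)))
  if (length(missing_stages))
    stopf("design lacks stage(s): %s", paste(missing_stages, collapse = ", "))
  prep <- prepare_matrix(pc)
  assignments <- assign_features(prep$matrix, pc$dataset$library$compounds,
                                 ppm_tol = pc$ppm_tol)
  arm_res <- lapply(pc$arms, function(a)
    analyse_arm(pc, prep$matrix, assignments, arm = a))

  arm_stages <- unique(pc$dataset$design$stage[
    !is.na(pc$dataset$design$arm)])
  diffs <- list()
  denr <- list()
  for (stg in arm_stages) {
    d <- differential_features(prep$matrix, pc$dataset$design, stg,
                               pc$arms[1], pc$arms[2], pc$alpha)
    comparison <- sprintf("%s (%s)~%s (%s)", stg, pc$arms[1], stg, pc$arms[2])
    diffs[[stg]] <- cbind(comparison = comparison, d)
    for (trend in c("increased", "decreased")) {
      feats <- d$feature_id[d$significant & d$direction == trend]
      if (length(feats) == 0) next
      fe <- suppressWarnings(
        functional_enrichment(assignments, feats, pc$dataset$graph,
                              pc$enrich))
      if (nrow(fe) > 0)
        denr[[length(denr) + 1L]] <- cbind(comparison = comparison,
                                           trend = trend, fe)
      se <- structural_enrichment(feats, prep$matrix$features$id,
                                  assignments, pc$taxonomy_level)
      se <- se[se$q < pc$alpha, , drop = FALSE]
      if (nrow(se) > 0)
        denr[[length(denr) + 1L]] <-
          cbind(comparison = comparison, trend = trend,
                data.frame(node = se$label, type = "structural class",
                           label = se$label, score = NA_real_,
                           p_score = se$q, stringsAsFactors = FALSE))
    }
  }
  counts <- prep$counts
  for (res in arm_res)
    counts[[paste0("features_selected_", res$label)]] <-
      length(res$selection$selected)
  for (stg in arm_stages)
    counts[[paste0("differential_", stg)]] <- sum(diffs[[stg]]$significant)

  out <- list(counts = counts, arms = arm_res, assignments = assignments,
              matrix = prep$matrix,
              differential = do.call(rbind, diffs),
              differential_enrichment =
                if (length(denr)) do.call(rbind, denr) else NULL,
              seed = pc$seed)
  rownames(out$differential) <- NULL
  out$manifest <- write_reports(out, pc, "black")
  class(out) <- "run_report"
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("fiemspipe run report\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Level-to-level class flow table (Sankey input)
#'
#' Counts feature flows between adjacent consensus-taxonomy levels, the
#' input needed by any Sankey renderer for a structural-class overview.
#'
#' @param assignments Output of [assign_features()].
#' @return Data frame `level_from`, `label_from`, `label_to`, `count`.
#' @export
summarise_classes <- function(assignments) {
  paths <- strsplit(assignments$consensus_path, "/", fixed = TRUE)
  paths <- Filter(function(p) length(p) > 0 && nzchar(p[1]), paths)
  rows <- list()
  for (p in paths) {
    if (length(p) < 2) next
    for (lev in seq_len(length(p) - 1L)) {
      key <- paste(lev, p[lev], p[lev + 1L], sep = "\r")
      rows[[key]] <- if (is.null(rows[[key]])) 1L else rows[[key]] + 1L
    }
  }
  if (length(rows) == 0)
    return(data.frame(level_from = integer(), label_from = character(),
                      label_to = character(), count = integer()))
  parts <- strsplit(names(rows), "\r", fixed = TRUE)
  out <- data.frame(
    level_from = as.integer(vapply(parts, `[[`, "", 1L)),
    label_from = vapply(parts, `[[`, "", 2L),
    label_to = vapply(parts, `[[`, "", 3L),
    count = unlist(rows, use.names = FALSE), stringsAsFactors = FALSE)
  out <- out[order(out$level_from, out$label_from, out$label_to), ]
  rownames(out) <- NULL
  out
}
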