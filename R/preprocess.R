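# Moisture/weight normalisation of extracts and transformation to
# stage-mean percentage relative abundance profiles.

#' Moisture content of a sample type
#'
#' `(fresh - dry) / fresh`, from the weighed and freeze-dried replicate of a
#' sample type.
#'
#' @param fresh_weight Fresh weight (mg), > 0.
#' @param dry_weight Freeze-dried weight (mg), 0 < dry <= fresh.
#' @return Moisture fraction in `[0, 1)`.
#' @export
moisture_content <- function(fresh_weight, dry_weight) {
  if (any(dry_weight <= 0) || any(fresh_weight <= 0))
    stopf("weights must be > 0")
  if (any(dry_weight > fresh_weight))
    stopf("dry weight exceeds fresh weight")
  (fresh_weight - dry_weight) / fresh_weight
}

#' Normalise extract intensities to the sample of lowest weight
#'
#' Computes each sample's dry-mass equivalent
#' `d_i = extract_weight_i * (1 - moisture_i)` (moisture measured once per
#' sample type and propagated to its replicates) and scales intensities by
#' `min(d) / d_i`, so the lowest-weight sample is unchanged and all others
#' are scaled down to it. With `mode = "raw-weight"` the extract weight is
#' used without moisture correction.
#'
#' @param matrix A `fiems_matrix`.
#' @param sample_table Design data frame (see [simulate_design()]): columns
#'   `sample_id`, `fresh_weight`, `dry_weight`, `extract_weight`, `is_qc`.
#' @param mode `"dry-mass"` (default) or `"raw-weight"`.
#' @return Normalised `fiems_matrix`; QC columns are left unchanged.
#' @export
weight_normalise <- function(matrix, sample_table, mode = c("dry-mass",
                                                            "raw-weight")) {
  mode <- match.arg(mode)
  st <- sample_table[match(colnames(matrix$values), sample_table$sample_id), ]
  if (any(is.na(st$sample_id)))
    stopf("sample(s) missing from sample table: %s",
          paste(setdiff(colnames(matrix$values), sample_table$sample_id),
                collapse = ", "))
  non_qc <- !st$is_qc
  ew <- st$extract_weight[non_qc]
  if (any(is.na(ew)))
    stopf("missing extract weight for sample(s): %s",
          paste(st$sample_id[non_qc][is.na(ew)], collapse = ", "))
  if (mode == "dry-mass") {
    moist <- moisture_content(st$fresh_weight[non_qc], st$dry_weight[non_qc])
    d <- ew * (1 - moist)
  } else {
    d <- ew
  }
  factors <- rep(1, ncol(matrix$values))
  factors[non_qc] <- min(d) / d
  values <- sweep(matrix$values, 2L, factors, `*`)
  prov <- matrix$provenance
  prov[[length(prov) + 1L]] <- list(step = "weight_normalise", mode = mode)
  new_fiems_matrix(values, matrix$features, prov)
}

#' Per-feature stage-mean intensity profiles
#'
#' Arithmetic mean over replicates within each stage, stages in declared
#' order; QC samples are excluded.
#'
#' @param matrix A `fiems_matrix`.
#' @param sample_table Design data frame with `sample_id`, `stage`, `is_qc`.
#' @param stages Ordered stage labels (default: order of first appearance in
#'   `sample_table`).
#' @param arm Optional arm filter: keeps samples whose `arm` is `NA` or
#'   equals `arm`.
#' @return Numeric matrix, features x stages.
#' @export
stage_mean_profiles <- function(matrix, sample_table, stages = NULL,
                                arm = NULL) {
  st <- sample_table[!sample_table$is_qc, ]
  if (!is.null(arm)) st <- st[is.na(st$arm) | st$arm == arm, ]
  if (is.null(stages)) stages <- unique(st$stage)
  out <- matrix(NA_real_, nrow(matrix$values), length(stages),
                dimnames = list(rownames(matrix$values), stages))
  for (s in stages) {
    ids <- intersect(st$sample_id[st$stage == s], colnames(matrix$values))
    if (length(ids) == 0) stopf("no samples for stage '%s'", s)
    out[, s] <- rowMeans(matrix$values[, ids, drop = FALSE])
  }
  out
}

#' Percentage relative abundance profiles
#'
#' Rescales each feature's per-stage means to percentages summing to 100,
#' making trends comparable across features of very different intensity.
#'
#' @param stage_means Numeric matrix (features x stages) or vector; entries
#'   >= 0, no all-zero row.
#' @return Matrix (or vector) of percentages; rows sum to 100.
#' @export
percent_relative_abundance <- function(stage_means) {
  vec <- is.null(dim(stage_means))
  m <- if (vec) matrix(stage_means, 1L) else as.matrix(stage_means)
  if (any(m < 0)) stopf("stage means must be non-negative")
  rs <- rowSums(m)
  if (any(rs == 0)) stopf("all-zero feature profile(s) cannot be rescaled")
  out <- 100 * m / rs
  if (vec) out[1L, ] else out
}
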