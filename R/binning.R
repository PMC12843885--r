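# Spectral binning: centroided flow-infusion scans -> polarity-tagged binned
# feature matrix, with infusion-window selection and occupancy/QC filters.

#' Select the infusion scan window
#'
#' Flow infusion yields a total-ion-current (TIC) profile that ramps up to a
#' plateau and decays; quantification should average the plateau. The default
#' rule retains the contiguous block of scans around the TIC maximum whose
#' TIC is at least 50% of the maximum. A fixed window can be supplied
#' instead.
#'
#' @param scans List of scans (each with a `peaks` matrix of `mz`,
#'   `intensity`).
#' @param threshold Fraction of the maximum TIC required (default 0.5).
#' @param override Optional `c(first, last)` scan indices; returned as-is
#'   (clamped to the available scans).
#' @return Integer vector of retained scan indices.
#' @export
select_scan_window <- function(scans, threshold = 0.5, override = NULL) {
  if (length(scans) == 0) stopf("no scans supplied")
  if (!is.null(override)) {
    return(seq(max(1L, override[1]), min(length(scans), override[2])))
  }
  tic <- vapply(scans, function(s) sum(s$peaks[, "intensity"]), 0)
  cut <- threshold * max(tic)
  peak <- which.max(tic)
  lo <- peak
  while (lo > 1 && tic[lo - 1] >= cut) lo <- lo - 1
  hi <- peak
  while (hi < length(tic) && tic[hi + 1] >= cut) hi <- hi + 1
  seq(lo, hi)
}

#' Bin the scans of one sample and polarity
#'
#' Peak m/z values are rounded half-up to the bin precision (2 decimals at
#' the default 0.01 Da width); intensities landing in the same bin within a
#' scan are summed, and the per-bin feature value is the mean of those
#' per-scan sums across the retained scans. Peaks outside `mz_range` are
#' dropped.
#'
#' @param scans List of retained (window-selected) scans.
#' @param bin_width Bin width in Da; default 0.01.
#' @param mz_range `c(low, high)` acquisition window; default 55-1200.
#' @return Named numeric vector of per-bin mean intensities; names are the
#'   bin m/z formatted at bin precision.
#' @export
bin_scans <- function(scans, bin_width = 0.01, mz_range = c(55, 1200)) {
  if (length(scans) == 0) stopf("no scans supplied")
  digits <- max(0L, as.integer(round(-log10(bin_width))))
  n_big <- sum(vapply(scans, function(s) nrow(s$peaks) >= 1e4, TRUE))
  if (n_big > 0)
    warnf("%d scan(s) carry >= 10^4 peaks; data may not be centroided", n_big)

  per_scan <- lapply(scans, function(s) {
    pk <- s$peaks
    keep <- pk[, "mz"] >= mz_range[1] & pk[, "mz"] <= mz_range[2]
    pk <- pk[keep, , drop = FALSE]
    if (nrow(pk) == 0) return(numeric())
    bins <- sprintf(paste0("%.", digits, "f"),
                    round_half_up(pk[, "mz"], digits))
    tapply(pk[, "intensity"], bins, sum)
  })
  all_bins <- sort(unique(unlist(lapply(per_scan, names))))
  if (length(all_bins) == 0) return(stats::setNames(numeric(), character()))
  acc <- matrix(0, length(all_bins), length(per_scan),
                dimnames = list(all_bins, NULL))
  for (i in seq_along(per_scan)) {
    v <- per_scan[[i]]
    if (length(v)) acc[names(v), i] <- v
  }
  rowMeans(acc)
}

# Intensity-weighted accurate m/z per bin across a scan list. Binning loses
# the sub-bin mass information that formula assignment at ppm tolerance
# needs; the weighted mean of the contributing peak m/z values restores it.
accurate_bin_mz <- function(scans, bin_width = 0.01, mz_range = c(55, 1200)) {
  digits <- max(0L, as.integer(round(-log10(bin_width))))
  num <- list(); den <- list()
  for (s in scans) {
    pk <- s$peaks
    keep <- pk[, "mz"] >= mz_range[1] & pk[, "mz"] <= mz_range[2]
    pk <- pk[keep, , drop = FALSE]
    if (nrow(pk) == 0) next
    bins <- sprintf(paste0("%.", digits, "f"),
                    round_half_up(pk[, "mz"], digits))
    wn <- tapply(pk[, "mz"] * pk[, "intensity"], bins, sum)
    wd <- tapply(pk[, "intensity"], bins, sum)
    for (b in names(wn)) {
      num[[b]] <- (num[[b]] %||% 0) + wn[[b]]
      den[[b]] <- (den[[b]] %||% 0) + wd[[b]]
    }
  }
  if (length(num) == 0) return(stats::setNames(numeric(), character()))
  out <- unlist(num) / unlist(den)
  out[order(names(out))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bin a set of samples into a feature matrix
#'
#' Applies [select_scan_window()] and [bin_scans()] per sample and polarity,
#' tags bins with a polarity prefix (`p`/`n`) so both ionisation modes
#' coexist in one matrix, and assembles the union of bins across samples
#' (absent bins are 0). Each feature additionally carries the
#' intensity-weighted mean m/z of its contributing peaks (`mz`), the
#' accurate mass that downstream ppm-tolerance formula assignment requires.
#'
#' @param sample_scans Named list (per sample) of lists with elements
#'   `positive` and `negative`, each a list of scans (the shape produced by
#'   [simulate_spectra()] or [read_mzml_scans()]).
#' @param bin_width,mz_range See [bin_scans()].
#' @param window_threshold,window_override See [select_scan_window()].
#' @return A `fiems_matrix`.
#' @export
bin_samples <- function(sample_scans, bin_width = 0.01, mz_range = c(55, 1200),
                        window_threshold = 0.5, window_override = NULL) {
  digits <- max(0L, as.integer(round(-log10(bin_width))))
  cols <- list()
  mz_num <- list(); mz_den <- list()
  for (sid in names(sample_scans)) {
    vals <- numeric()
    for (pol in c("positive", "negative")) {
      scans <- sample_scans[[sid]][[pol]]
      if (is.null(scans) || length(scans) == 0) next
      win <- select_scan_window(scans, window_threshold, window_override)
      binned <- bin_scans(scans[win], bin_width, mz_range)
      amz <- accurate_bin_mz(scans[win], bin_width, mz_range)
      if (length(binned)) {
        names(binned) <- paste0(substr(pol, 1, 1), names(binned))
        names(amz) <- paste0(substr(pol, 1, 1), names(amz))
        for (b in names(amz)) {
          w <- binned[[b]]
          mz_num[[b]] <- (mz_num[[b]] %||% 0) + amz[[b]] * w
          mz_den[[b]] <- (mz_den[[b]] %||% 0) + w
        }
      }
      vals <- c(vals, binned)
    }
    cols[[sid]] <- vals
  }
  ids <- sort(unique(unlist(lapply(cols, names))))
  values <- matrix(0, length(ids), length(cols),
                   dimnames = list(ids, names(cols)))
  for (sid in names(cols)) {
    v <- cols[[sid]]
    if (length(v)) values[names(v), sid] <- v
  }
  features <- data.frame(
    id = ids,
    polarity = ifelse(substr(ids, 1, 1) == "p", "positive", "negative"),
    bin_mz = as.numeric(substring(ids, 2)),
    mz = vapply(ids, function(b) mz_num[[b]] / mz_den[[b]], 0),
    stringsAsFactors = FALSE)
  rownames(features) <- NULL
  new_fiems_matrix(values, features,
                   provenance = list(bin_width = bin_width,
                                     mz_range = mz_range,
                                     window_threshold = window_threshold))
}

#' Occupancy filter
#'
#' Retains a feature iff, within at least one sample class, the fraction of
#' samples in which the feature is detected (intensity > 0) reaches
#' `threshold`.
#'
#' @param matrix A `fiems_matrix`.
#' @param class_labels Character vector of class labels, one per sample
#'   (column).
#' @param threshold Required within-class occupancy in (0, 1]; default 2/3
#'   (two of three replicates).
#' @return Filtered `fiems_matrix`.
#' @export
occupancy_filter <- function(matrix, class_labels, threshold = 2 / 3) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  if (length(class_labels) != ncol(matrix$values))
    stopf("need one class label per sample")
  classes <- unique(class_labels)
  occ <- sapply(classes, function(cl) {
    cols <- matrix$values[, class_labels == cl, drop = FALSE]
    rowMeans(cols > 0)
  })
  occ <- matrix(occ, nrow = nrow(matrix$values))
  keep <- apply(occ, 1L, max) >= threshold
  subset_features(matrix, keep,
                  note = list(filter = "occupancy", threshold = threshold,
                              dropped = sum(!keep)))
}

#' Pooled-QC filter
#'
#' Drops features whose relative standard deviation (sd/mean) across pooled
#' QC injections exceeds `max_rsd`, or whose QC occupancy falls below
#' `min_occupancy`.
#'
#' @param matrix A `fiems_matrix`.
#' @param qc_sample_ids Column names of the QC injections (>= 2).
#' @param max_rsd Maximum allowed QC RSD (default 0.5).
#' @param min_occupancy Minimum QC occupancy (default 2/3).
#' @return Filtered `fiems_matrix` (QC columns are retained; only features
#'   are dropped).
#' @export
qc_filter <- function(matrix, qc_sample_ids, max_rsd = 0.5,
                      min_occupancy = 2 / 3) {
  qc_sample_ids <- intersect(qc_sample_ids, colnames(matrix$values))
  if (length(qc_sample_ids) < 2) stopf("need at least 2 QC samples")
  qc <- matrix$values[, qc_sample_ids, drop = FALSE]
  mu <- rowMeans(qc)
  sdv <- apply(qc, 1L, stats::sd)
  rsd <- ifelse(mu > 0, sdv / mu, Inf)
  occ <- rowMeans(qc > 0)
  keep <- rsd <= max_rsd & occ >= min_occupancy
  subset_features(matrix, keep,
                  note = list(filter = "qc", max_rsd = max_rsd,
                              min_occupancy = min_occupancy,
                              dropped = sum(!keep)))
}
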