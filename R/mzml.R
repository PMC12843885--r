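# mzML I/O for centroided scan lists, via mzR. Positive and negative scans
# are stored in one file per sample (polarity-tagged), matching single-run
# dual-polarity flow-infusion acquisition.

#' Write a sample's scans to an mzML file
#'
#' @param sample_scans List with elements `positive` and `negative`, each a
#'   list of scans (`scan_index`, `peaks`).
#' @param path Output `.mzML` path.
#' @return The path, invisibly.
#' @export
write_mzml <- function(sample_scans, path) {
  pks <- list()
  pol <- integer()
  for (p in c("positive", "negative")) {
    for (s in sample_scans[[p]]) {
      pks[[length(pks) + 1L]] <- s$peaks
      pol <- c(pol, if (p == "positive") 1L else 0L)
    }
  }
  n <- length(pks)
  if (n == 0) stopf("no scans to write")
  counts <- vapply(pks, nrow, 1L)
  tic <- vapply(pks, function(m) sum(m[, "intensity"]), 0)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = pol, peaksCount = counts, totIonCurrent = tic,
    retentionTime = seq_len(n), basePeakMZ = 0, basePeakIntensity = 0,
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pks, function(m) if (nrow(m)) min(m[, "mz"]) else 0, 0),
    highMZ = vapply(pks, function(m) if (nrow(m)) max(m[, "mz"]) else 0, 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = "", spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_)
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}

#' Read polarity-tagged centroided scans from an mzML file
#'
#' @param path `.mzML` path.
#' @return List with `positive` and `negative` scan lists in the shape
#'   consumed by [bin_samples()].
#' @export
read_mzml_scans <- function(path) {
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  hdr <- mzR::header(f)
  out <- list(positive = list(), negative = list())
  for (i in seq_len(nrow(hdr))) {
    pk <- mzR::peaks(f, i)
    colnames(pk) <- c("mz", "intensity")
    pol <- if (hdr$polarity[i] == 1L) "positive" else "negative"
    out[[pol]][[length(out[[pol]]) + 1L]] <-
      list(scan_index = length(out[[pol]]) + 1L, peaks = pk)
  }
  out
}

#' Write one mzML file per sample into a directory
#'
#' @param all_scans Named list of per-sample scan lists (see
#'   [simulate_spectra()]).
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_mzml_dir <- function(all_scans, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(all_scans), function(sid) {
    p <- file.path(dir, paste0(sid, ".mzML"))
    write_mzml(all_scans[[sid]], p)
    p
  }, "")
  paths
}

#' Read every mzML file of a directory into per-sample scan lists
#'
#' @param dir Directory containing `.mzML` files; sample ids are the file
#'   names without extension.
#' @return Named list of per-sample scan lists.
#' @export
read_mzml_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.mzML$", full.names = TRUE)
  if (length(files) == 0) stopf("no mzML files in %s", dir)
  out <- lapply(files, read_mzml_scans)
  names(out) <- sub("\\.mzML$", "", basename(files))
  out
}
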