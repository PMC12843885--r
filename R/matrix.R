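# The central container: a polarity-tagged binned feature matrix.

#' Construct a binned feature matrix
#'
#' @param values Numeric matrix, features x samples; row names are feature
#'   ids, column names sample ids.
#' @param features Data frame with columns `id` (`"p<mz>"`/`"n<mz>"`),
#'   `polarity`, `bin_mz`, aligned with the rows of `values`.
#' @param provenance List of processing parameters accumulated along the
#'   pipeline (bin width, scan windows, filters applied).
#' @return A `fiems_matrix` object.
#' @export
new_fiems_matrix <- function(values, features, provenance = list()) {
  stopifnot(is.matrix(values), nrow(values) == nrow(features),
            all(rownames(values) == features$id))
  if (any(values < 0)) stopf("intensities must be non-negative")
  structure(list(values = values, features = features,
                 provenance = provenance),
            class = "fiems_matrix")
}

#' @export
print.fiems_matrix <- function(x, ...) {
  cat(sprintf("fiems_matrix: %d features x %d samples (%d positive, %d negative)\n",
              nrow(x$values), ncol(x$values),
              sum(x$features$polarity == "positive"),
              sum(x$features$polarity == "negative")))
  if (length(x$provenance))
    cat("provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.fiems_matrix <- function(x) dim(x$values)

# Subset features by logical/integer index, keeping provenance.
subset_features <- function(matrix, keep, note = NULL) {
  prov <- matrix$provenance
  if (!is.null(note)) prov[[length(prov) + 1L]] <- note
  new_fiems_matrix(matrix$values[keep, , drop = FALSE],
                   matrix$features[keep, , drop = FALSE], prov)
}

#' Write a feature matrix as TSV with a JSON provenance sidecar
#'
#' @param matrix A `fiems_matrix`.
#' @param path Output TSV path (features x samples; first columns `id`,
#'   `polarity`, `bin_mz`). A `<path>.json` sidecar records provenance.
#' @export
write_feature_matrix <- function(matrix, path) {
  df <- cbind(matrix$features,
              as.data.frame(matrix$values, check.names = FALSE))
  write_tsv(df, path)
  jsonlite::write_json(matrix$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV path.
#' @return A `fiems_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- read_tsv(path)
  meta_cols <- intersect(c("id", "polarity", "bin_mz", "mz"), names(df))
  features <- df[, meta_cols]
  values <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(values) <- features$id
  prov <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) prov <- jsonlite::read_json(sidecar)
  new_fiems_matrix(values, features, prov)
}
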