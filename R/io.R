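# Plain-text readers/writers for the remaining pipeline artefacts, so any
# step can be run standalone from files.

#' Write a sample/design table as TSV
#' @param design Data frame from [simulate_design()].
#' @param path Output path.
#' @export
write_design <- function(design, path) write_tsv(design, path)

#' Read a sample/design table written by [write_design()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_design <- function(path) {
  df <- read_tsv(path)
  df$arm <- as.character(df$arm)
  df$stage <- as.character(df$stage)
  df
}

#' Write a compound snapshot as TSV
#' @param compounds Data frame (`compound_id`, `name`, `formula`, `tier`,
#'   `taxonomy_path`).
#' @param path Output path.
#' @export
write_compound_snapshot <- function(compounds, path) write_tsv(compounds, path)

#' Read a compound snapshot TSV
#' @param path TSV path.
#' @return Data frame.
#' @export
read_compound_snapshot <- function(path) {
  df <- read_tsv(path)
  need <- c("compound_id", "formula", "tier", "taxonomy_path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("snapshot missing column(s): %s",
                          paste(miss, collapse = ", "))
  df
}
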