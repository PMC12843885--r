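#' @keywords internal
"_PACKAGE"

# Half-up rounding to `digits` decimals. base::round() rounds half to even,
# which would split peaks at bin midpoints inconsistently across platforms.
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

# Derive a stream-specific 32-bit seed from a master seed. Keeps every
# stochastic component independently reproducible from one user-facing seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 1299721L) %% 2147483562L
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "", ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
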