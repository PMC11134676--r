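# Shared helpers: strict TSV IO and small numeric utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Write a table as tab-separated text
#'
#' Deterministic TSV writer used for every file the package emits: no
#' quoting, no row names, `NA` written literally.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(as.data.table(x), path, sep = "\t", quote = FALSE,
                     na = "NA", scipen = 50)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return a `data.table`.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  if (!is.null(required)) {
    miss <- setdiff(required, names(dt))
    if (length(miss))
      stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  dt
}

# GRanges from a 0-based half-open interval table.
granges0 <- function(chrom, start0, end0, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                         strand = strand)
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop(name, " must be a single non-negative integer")
}
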