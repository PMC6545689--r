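#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by all
#' pipeline artifacts: header row, tab separator, no factor conversion, and
#' `"NA"` as the missing-value token.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a tab-separated table
#'
#' Deterministic TSV writer (fixed column order, no quoting, no row names) so
#' that identical inputs produce byte-identical files.
#'
#' @param x A `data.frame`.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Reads the first three or four columns of a BED file (0-based, half-open
#' intervals) into a `data.frame` with columns `chrom`, `start`, `end` and
#' optionally `name`.
#'
#' @param path Path to a BED file (no header).
#' @return A `data.frame` of intervals.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 3L) stop("BED file needs >= 3 columns: ", path, call. = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4L) names(x)[4] <- "name"
  x[, seq_len(min(ncol(x), 4L)), drop = FALSE]
}

#' Write genomic intervals to a BED file
#'
#' @param x A `data.frame` with columns `chrom`, `start`, `end` and optionally
#'   `name`; coordinates are 0-based half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probes-by-samples numeric matrix stored as TSV
#'
#' The first column holds the row identifiers (probe or gene ids); remaining
#' columns are samples.
#'
#' @param path Path to a matrix TSV written by [write_matrix_tsv()].
#' @return A numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  x <- read_tsv(path)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a numeric matrix as TSV with an identifier column
#'
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name of the identifier column (default `"probe_id"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}
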