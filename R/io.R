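#' Read a sample-metadata table
#'
#' Expects a tab-separated file with header columns `sample_id`, `group`,
#' `tissue`, `sex`.
#'
#' @param path path to the metadata TSV.
#' @return A validated metadata `data.frame` (see [sample_meta()]).
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character",
                            check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_meta(meta)
  meta
}

#' Read a gene-by-sample count matrix with its metadata
#'
#' The count file is tab-separated with a header row of sample ids and a
#' first column `gene_id`. Every sample in the header must appear in the
#' metadata and vice versa; columns are reordered to metadata order rather
#' than file order. Unmatched samples are an error, never silently dropped.
#' Counts must be non-negative integers: fractional quantification
#' estimates must be rounded by the caller.
#'
#' @param path path to the count TSV.
#' @param meta_path path to the metadata TSV (see [read_metadata()]).
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, meta_path) {
  meta <- read_metadata(meta_path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 1 || names(tab)[1] != "gene_id") {
    stop("count file must have 'gene_id' as its first column", call. = FALSE)
  }
  gene_ids <- as.character(tab$gene_id)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    storage.mode(mat) <- "double"
  }
  rownames(mat) <- gene_ids
  count_matrix(mat, meta)
}

#' Write a count matrix (and optionally its metadata) to TSV
#'
#' @param x a [count_matrix()].
#' @param path output path for the count TSV.
#' @param meta_path optional output path for the metadata TSV.
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts),
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
  if (!is.null(meta_path)) write_table(x$samples, meta_path)
  invisible(x)
}

#' Write a result table as deterministic TSV
#'
#' Columns are written in their current order; floating-point values are
#' rendered with a fixed precision of 12 significant digits, so repeated
#' writes of the same table are byte-identical and a write/read round trip
#' reproduces reals to well within 1e-9 relative error. Output is UTF-8
#' with LF line endings.
#'
#' @param df a `data.frame` (may have zero rows; the header is still
#'   written).
#' @param path output path.
#' @return `df`, invisibly.
#' @export
write_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      out[[j]] <- ifelse(is.na(col), "NA", sprintf("%.12g", col))
    } else {
      out[[j]] <- as.character(col)
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out) > 0) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(df)
}

#' Read a result table written by [write_table()]
#'
#' @param path path to the TSV.
#' @return A `data.frame` with column types inferred by R.
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
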