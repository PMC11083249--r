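#' Counts-per-million normalization
#'
#' Scales each sample by its total count:
#' `value(g, s) = count(g, s) / library_size(s) * 1e6`, where
#' `library_size(s)` is the column sum. Column sums of the result are
#' exactly 1e6, and multiplying a sample's raw counts by any positive
#' constant leaves its CPM column unchanged.
#'
#' @param x a [count_matrix()]; every sample must have total count > 0.
#' @return A [norm_matrix()] with `method_tag = "cpm"`.
#' @export
normalize_cpm <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  libsize <- colSums(x$counts)
  zero <- names(libsize)[libsize == 0]
  if (length(zero) > 0) {
    stop("sample(s) with zero total count: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  values <- sweep(x$counts, 2, libsize, "/") * 1e6
  norm_matrix(values, x$samples, method_tag = "cpm")
}

#' Log-transform a normalized matrix
#'
#' Applies `log2(value + pseudocount)` for variance stabilization before
#' t-testing. Strictly monotone, hence invertible given the pseudocount.
#'
#' @param norm a [norm_matrix()].
#' @param pseudocount positive offset added before the log (default 1, so
#'   zeros map to zero).
#' @return A [norm_matrix()] with `"+log2(x+c)"` appended to the method
#'   tag.
#' @export
log_transform <- function(norm, pseudocount = 1) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      !is.finite(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be a single positive number", call. = FALSE)
  }
  norm_matrix(log2(norm$values + pseudocount), norm$samples,
              method_tag = paste0(norm$method_tag, "+log2(x+c)"))
}
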