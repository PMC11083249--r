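#' Summarize inheritance-mode classifications
#'
#' Counts genes per category and computes the additive/non-additive split
#' over testable genes:
#' `fraction_nonadditive = (n_candidates - n_additive - n_not_testable) /
#' n_testable` and `fraction_additive = 1 - fraction_nonadditive`.
#'
#' @param records a `data.frame` of pattern records (output of
#'   [run_pattern_analysis()], or any table with `category`); may be
#'   empty.
#' @param tissue optional tissue label; defaults to the `tissue` attribute
#'   of `records` if present.
#' @return One-row `data.frame` with `tissue`, `n_candidates`, one
#'   `n_<category>` column per category, `fraction_additive` and
#'   `fraction_nonadditive` (both `NA` when no gene is testable).
#' @export
summarize_patterns <- function(records, tissue = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(tissue)) {
    tissue <- attr(records, "tissue")
    if (is.null(tissue)) tissue <- NA_character_
  }
  cats <- pattern_categories()
  if (nrow(records) > 0) {
    bad <- setdiff(unique(records$category), cats)
    if (length(bad) > 0) {
      stop("unknown category label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  counts <- vapply(cats, function(cc) sum(records$category == cc), integer(1))
  n <- nrow(records)
  n_testable <- n - counts[["not_testable"]]
  frac_nonadd <- if (n_testable > 0) {
    (n - counts[["additive"]] - counts[["not_testable"]]) / n_testable
  } else NA_real_
  out <- data.frame(tissue = tissue, n_candidates = n,
                    stringsAsFactors = FALSE)
  for (cc in cats) out[[paste0("n_", cc)]] <- counts[[cc]]
  out$fraction_additive <- if (n_testable > 0) 1 - frac_nonadd else NA_real_
  out$fraction_nonadditive <- frac_nonadd
  out
}

#' Render a fraction as a one-decimal percent label
#'
#' Rounds half away from zero at one decimal place, so 0.19373 renders as
#' `"19.4%"` and 0.05811 as `"5.8%"`.
#'
#' @param fraction numeric fraction(s) in \[0, 1\] (values outside are
#'   rendered as-is).
#' @return Character vector like `"80.6%"`.
#' @export
percent_label <- function(fraction) {
  pct <- fraction * 100
  rounded <- sign(pct) * floor(abs(pct) * 10 + 0.5) / 10
  sprintf("%.1f%%", rounded)
}

#' Top-N genes by summed normalized expression
#'
#' Sums each gene's normalized expression over a set of samples, sorts in
#' non-increasing order (ties broken by gene id, lexicographically) and
#' returns the first `n` genes with ranks 1..n.
#'
#' @param norm a [norm_matrix()].
#' @param sample_ids non-empty character vector of sample ids to sum over.
#' @param n number of genes to return (default 10); if larger than the
#'   number of genes, all genes are returned.
#' @return `data.frame` with `gene_id`, `total_expression`, `rank`.
#' @export
top_genes <- function(norm, sample_ids, n = 10) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (length(sample_ids) < 1) stop("sample_ids must be non-empty", call. = FALSE)
  missing <- setdiff(sample_ids, colnames(norm$values))
  if (length(missing) > 0) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  totals <- rowSums(norm$values[, sample_ids, drop = FALSE])
  ord <- order(-totals, names(totals), method = "radix")
  keep <- utils::head(ord, n)
  data.frame(gene_id = names(totals)[keep],
             total_expression = unname(totals[keep]),
             rank = seq_along(keep),
             stringsAsFactors = FALSE)
}

#' PCA quality-control projection of samples
#'
#' Principal component analysis of samples on gene-centred expression
#' values (genes as variables), returning the first two components with a
#' deterministic sign convention: each component's largest-magnitude gene
#' loading is made positive, so the decomposition is unique whenever the
#' leading eigenvalues are distinct.
#'
#' @param norm a [norm_matrix()], typically log-scale; needs >= 3 samples
#'   and >= 2 genes.
#' @return List with `coordinates` (`data.frame`: `sample_id`, `pc1`,
#'   `pc2`) and `var_explained` (length-2 numeric, fractions of total
#'   variance; their sum is <= 1).
#' @export
pca_qc <- function(norm) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (ncol(norm$values) < 3) stop("PCA needs >= 3 samples", call. = FALSE)
  if (nrow(norm$values) < 2) stop("PCA needs >= 2 genes", call. = FALSE)
  fit <- stats::prcomp(t(norm$values), center = TRUE, scale. = FALSE)
  k <- min(2, ncol(fit$rotation))
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (k < 2) scores <- cbind(scores, 0)
  total_var <- sum(fit$sdev^2)
  ve <- if (total_var > 0) fit$sdev[seq_len(k)]^2 / total_var else rep(0, k)
  if (length(ve) < 2) ve <- c(ve, 0)
  list(coordinates = data.frame(sample_id = norm$samples$sample_id,
                                pc1 = unname(scores[, 1]),
                                pc2 = unname(scores[, 2]),
                                stringsAsFactors = FALSE),
       var_explained = ve)
}
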