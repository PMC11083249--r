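#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("P1", "P2", "F1")
SEX_LEVELS <- c("M", "F", "unknown")

#' Inheritance-mode category labels
#'
#' The categories a candidate gene can receive from the pattern classifier,
#' in reporting order. `unclassified_nonadditive` collects genes that differ
#' significantly from the mid-parent value but whose parent-comparison test
#' results match none of the four named non-additive patterns.
#' `not_testable` marks genes for which a required test could not be
#' computed.
#'
#' @return Character vector of the seven category labels.
#' @export
pattern_categories <- function() {
  c("additive", "enhancing_dominance", "suppressing_dominance",
    "over_dominance", "under_dominance", "unclassified_nonadditive",
    "not_testable")
}

#' Construct a validated sample-metadata table
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group group assignment, one of `"P1"` (paternal line), `"P2"`
#'   (maternal line), `"F1"` (cross).
#' @param tissue tissue label (e.g. `"breast_muscle"`, `"liver"`).
#' @param sex `"M"`, `"F"` or `"unknown"`.
#' @return A `data.frame` with columns `sample_id`, `group`, `tissue`, `sex`.
#' @export
sample_meta <- function(sample_id, group, tissue, sex = "unknown") {
  meta <- data.frame(sample_id = as.character(sample_id),
                     group = as.character(group),
                     tissue = as.character(tissue),
                     sex = as.character(sex),
                     stringsAsFactors = FALSE)
  validate_sample_meta(meta)
  meta
}

validate_sample_meta <- function(meta) {
  required <- c("sample_id", "group", "tissue", "sex")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample_id in metadata: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(meta$group), GROUP_LEVELS)
  if (length(bad_group) > 0) {
    stop("invalid group label(s): ", paste(bad_group, collapse = ", "),
         "; must be one of ", paste(GROUP_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- setdiff(unique(meta$sex), SEX_LEVELS)
  if (length(bad_sex) > 0) {
    stop("invalid sex label(s): ", paste(bad_sex, collapse = ", "),
         "; must be one of ", paste(SEX_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  invisible(meta)
}

#' Construct a validated count matrix
#'
#' Bundles an integer gene-by-sample count matrix with its sample metadata.
#' Columns are ordered to match the metadata row order, which is the single
#' source of truth for group assignment.
#'
#' @param counts numeric matrix of non-negative integers; rownames are gene
#'   ids, colnames are sample ids.
#' @param samples sample-metadata `data.frame` as returned by
#'   [sample_meta()]; must cover exactly the columns of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix, columns in metadata order) and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  validate_sample_meta(samples)
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    stop("counts must have gene ids as rownames", call. = FALSE)
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    stop("counts must have sample ids as colnames", call. = FALSE)
  }
  extra <- setdiff(colnames(counts), samples$sample_id)
  if (length(extra) > 0) {
    stop("sample(s) in counts but not in metadata: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(samples$sample_id, colnames(counts))
  if (length(absent) > 0) {
    stop("sample(s) in metadata but not in counts: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  check_integral_counts(counts)
  storage.mode(counts) <- "double"
  obj <- structure(list(counts = counts, samples = samples),
                   class = "count_matrix")
  obj
}

check_integral_counts <- function(counts) {
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad) > 0) {
    i <- bad[1]
    g <- rownames(counts)[(i - 1) %% nrow(counts) + 1]
    s <- colnames(counts)[(i - 1) %/% nrow(counts) + 1]
    stop("counts must be non-negative integers; first offending cell: gene '",
         g, "', sample '", s, "' (value ", counts[i], ")", call. = FALSE)
  }
  invisible(counts)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$group, x$samples$tissue)
  print(tab)
  invisible(x)
}

#' Construct a normalized expression matrix
#'
#' @param values numeric matrix of finite, non-negative normalized
#'   expression values, same layout as the source counts.
#' @param samples sample metadata covering exactly the columns of `values`.
#' @param method_tag string recording the normalization applied
#'   (e.g. `"cpm"`, `"cpm+log2(x+1)"`).
#' @return An object of class `norm_matrix` with elements `values`,
#'   `samples`, `method_tag`.
#' @export
norm_matrix <- function(values, samples, method_tag) {
  if (!is.matrix(values)) values <- as.matrix(values)
  validate_sample_meta(samples)
  if (!identical(colnames(values), samples$sample_id)) {
    stop("values columns must match metadata sample order", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("normalized values must be finite and >= 0", call. = FALSE)
  }
  structure(list(values = values, samples = samples,
                 method_tag = as.character(method_tag)),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix [%s]: %d genes x %d samples\n",
              x$method_tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}

group_samples <- function(samples, group) {
  samples$sample_id[samples$group == group]
}
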