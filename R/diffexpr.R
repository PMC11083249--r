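#' Welch's unequal-variance two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] (two-sided, `var.equal = FALSE`)
#' that is total on degenerate input: if both groups are constant and
#' equal the test returns `t = 0, p = 1` (no evidence of difference); if
#' both are constant but unequal it returns an infinite statistic and
#' `p = 0`.
#'
#' @param a,b numeric vectors with at least 2 finite values each.
#' @return List with `statistic` (t, positive when `mean(a) > mean(b)`) and
#'   `p_value`.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2 || any(!is.finite(a)) || any(!is.finite(b))) {
    stop("each group needs >= 2 finite values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p_value = 1))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0))
  }
  fit <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], clipped to 1 and
#' order-preserving with the input indexing.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence: Benjamini-Hochberg
#' inflated by the harmonic factor `c(m) = sum(1/i, i = 1..m)`. Always
#' dominates [bh_adjust()] elementwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
by_adjust <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BY")
}

check_pvalues <- function(p) {
  if (length(p) > 0 && (any(!is.finite(p)) || any(p < 0) || any(p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Call differentially expressed genes between two groups
#'
#' Per-gene Welch t-tests on the supplied (log-scale) normalized values,
#' Benjamini-Hochberg FDR across all tested genes, and the significance
#' contract `fdr < fdr_threshold` AND `|log2fc| > lfc_threshold` (both
#' strict). `log2fc` is the difference of group means on the log2 scale
#' (group A minus group B), so `direction = "up"` means higher in A.
#'
#' @param norm a [norm_matrix()] on the log2 scale (see [log_transform()]).
#' @param group_a,group_b group labels (`"P1"`, `"P2"` or `"F1"`); each
#'   needs >= 2 samples.
#' @param fdr_threshold,lfc_threshold significance thresholds (defaults
#'   0.05 and 1).
#' @param genes optional character vector restricting the test to a gene
#'   subset (e.g. the output of [filter_candidates()]); default all genes.
#' @return `data.frame` with one row per tested gene: `gene_id`,
#'   `contrast`, `log2fc`, `t`, `p_value`, `fdr`, `is_deg`, `direction`
#'   (`"up"`, `"down"` or `"none"`).
#' @export
call_degs <- function(norm, group_a, group_b,
                      fdr_threshold = 0.05, lfc_threshold = 1,
                      genes = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  for (g in c(group_a, group_b)) {
    if (!g %in% norm$samples$group) {
      stop("unknown or absent group label: ", g, call. = FALSE)
    }
  }
  ids_a <- group_samples(norm$samples, group_a)
  ids_b <- group_samples(norm$samples, group_b)
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  if (is.null(genes)) genes <- rownames(norm$values)
  missing <- setdiff(genes, rownames(norm$values))
  if (length(missing) > 0) {
    stop("gene(s) not in matrix: ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  va <- norm$values[genes, ids_a, drop = FALSE]
  vb <- norm$values[genes, ids_b, drop = FALSE]
  res <- vapply(seq_along(genes), function(i) {
    w <- welch_t(va[i, ], vb[i, ])
    c(w$statistic, w$p_value)
  }, numeric(2))
  log2fc <- rowMeans(va) - rowMeans(vb)
  fdr <- bh_adjust(res[2, ])
  is_deg <- fdr < fdr_threshold & abs(log2fc) > lfc_threshold
  direction <- ifelse(!is_deg, "none", ifelse(log2fc > 0, "up", "down"))
  data.frame(gene_id = genes,
             contrast = paste0(group_a, "_vs_", group_b),
             log2fc = unname(log2fc),
             t = res[1, ],
             p_value = res[2, ],
             fdr = fdr,
             is_deg = is_deg,
             direction = direction,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Three-set Venn overlap counts
#'
#' Counts all seven regions of a three-set Venn diagram; region counts sum
#' to the size of the union.
#'
#' @param set_a,set_b,set_c character vectors of gene ids (duplicates
#'   ignored).
#' @return Named integer vector with elements `a_only`, `b_only`, `c_only`,
#'   `ab_only`, `ac_only`, `bc_only`, `abc`.
#' @export
venn_overlap <- function(set_a, set_b, set_c) {
  set_a <- unique(set_a); set_b <- unique(set_b); set_c <- unique(set_c)
  u <- union(union(set_a, set_b), set_c)
  ina <- u %in% set_a; inb <- u %in% set_b; inc <- u %in% set_c
  c(a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab_only = sum(ina & inb & !inc),
    ac_only = sum(ina & !inb & inc),
    bc_only = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
}
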