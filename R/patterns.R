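#' Filter candidate genes by expression prevalence
#'
#' A gene is a candidate for pattern analysis when it is expressed
#' (raw count > 0) in at least half of the tissue's samples, i.e. in
#' `>= ceiling(n_samples / 2)` samples (9 of 18 under the reference
#' design).
#'
#' @param x a [count_matrix()].
#' @param tissue tissue label to filter within.
#' @return Character vector of candidate gene ids (row order preserved).
#' @export
filter_candidates <- function(x, tissue) {
  stopifnot(inherits(x, "count_matrix"))
  ids <- x$samples$sample_id[x$samples$tissue == tissue]
  if (length(ids) < 2) {
    stop("unknown tissue or < 2 samples for tissue: ", tissue, call. = FALSE)
  }
  sub <- x$counts[, ids, drop = FALSE]
  n_expressed <- rowSums(sub > 0)
  rownames(sub)[n_expressed >= ceiling(length(ids) / 2)]
}

#' Mid-parent value of a gene
#'
#' The additive expectation for the F1: the mean of the two parental
#' groups' mean normalized expression,
#' `(mean(P1) + mean(P2)) / 2`, computed on the scale of `norm`.
#'
#' @param norm a [norm_matrix()].
#' @param gene gene id.
#' @return A single numeric MPV.
#' @export
mid_parent_value <- function(norm, gene) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (!gene %in% rownames(norm$values)) {
    stop("gene not in matrix: ", gene, call. = FALSE)
  }
  ids_p1 <- group_samples(norm$samples, "P1")
  ids_p2 <- group_samples(norm$samples, "P2")
  if (length(ids_p1) < 1 || length(ids_p2) < 1) {
    stop("both parental groups (P1, P2) must be present", call. = FALSE)
  }
  (mean(norm$values[gene, ids_p1]) + mean(norm$values[gene, ids_p2])) / 2
}

#' One-sample t-test of F1 values against a mid-parent value
#'
#' Two-sided one-sample t-test of the F1 replicate values against the
#' scalar MPV. Total on degenerate input: constant F1 values equal to the
#' MPV give `t = 0, p = 1`; constant values different from it give an
#' infinite statistic and `p = 0`.
#'
#' @param f1_values numeric vector of >= 2 F1 expression values.
#' @param mpv the mid-parent value on the same scale.
#' @return List with `statistic` and `p_value`.
#' @export
test_vs_mpv <- function(f1_values, mpv) {
  f1_values <- as.numeric(f1_values)
  if (length(f1_values) < 2 || any(!is.finite(f1_values))) {
    stop("need >= 2 finite F1 values", call. = FALSE)
  }
  if (!is.numeric(mpv) || length(mpv) != 1 || !is.finite(mpv)) {
    stop("mpv must be a single finite number", call. = FALSE)
  }
  if (stats::sd(f1_values) == 0) {
    if (mean(f1_values) == mpv) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(mean(f1_values) - mpv) * Inf, p_value = 0))
  }
  fit <- stats::t.test(f1_values, mu = mpv)
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Classify one gene's inheritance mode
#'
#' Decision tree over the three BY-adjusted tests (F1 vs MPV, F1 vs high
#' parent, F1 vs low parent), evaluated in order:
#' 1. `q_mpv >= alpha` -> `additive`
#' 2. `q_high < alpha` and `mean_f1 > mean_high` -> `over_dominance`
#' 3. `q_low < alpha` and `mean_f1 < mean_low` -> `under_dominance`
#' 4. `q_high >= alpha` and `q_low < alpha` -> `enhancing_dominance`
#' 5. `q_low >= alpha` and `q_high < alpha` -> `suppressing_dominance`
#' 6. otherwise -> `unclassified_nonadditive`
#'
#' Over/under-dominance precede the dominance checks because an
#' over-dominant gene typically also differs from the low parent; the
#' ordering makes the classes mutually exclusive. The four named
#' non-additive classes are not exhaustive (a gene can differ from the MPV
#' and from both parents while lying between them), hence the explicit
#' `unclassified_nonadditive` category. A tied high parent makes the
#' dominance branches unreachable: a non-additive gene with
#' `high_parent = "tie"` is `unclassified_nonadditive`. Any missing
#' q-value yields `not_testable`.
#'
#' @param q_mpv,q_high,q_low BY-adjusted p-values of the three tests.
#' @param mean_f1,mean_high,mean_low group means on the analysis scale.
#' @param high_parent `"P1"`, `"P2"` or `"tie"`.
#' @param alpha significance level on adjusted values (default 0.05,
#'   strict inequality).
#' @return A single category label (see [pattern_categories()]).
#' @export
classify_gene <- function(q_mpv, q_high, q_low, mean_f1, mean_high,
                          mean_low, high_parent = "P1", alpha = 0.05) {
  if (is.na(q_mpv) || is.na(q_high) || is.na(q_low)) return("not_testable")
  if (q_mpv >= alpha) return("additive")
  if (high_parent == "tie") return("unclassified_nonadditive")
  if (q_high < alpha && mean_f1 > mean_high) return("over_dominance")
  if (q_low < alpha && mean_f1 < mean_low) return("under_dominance")
  if (q_high >= alpha && q_low < alpha) return("enhancing_dominance")
  if (q_low >= alpha && q_high < alpha) return("suppressing_dominance")
  "unclassified_nonadditive"
}

#' Run the full inheritance-mode pattern analysis for one tissue
#'
#' The core pipeline: filter candidate genes (count > 0 in at least half
#' the tissue's samples), CPM-normalize, compute each candidate's
#' mid-parent value as the arithmetic mean of the two parental group mean
#' CPMs, t-test the F1 replicates against the MPV and against each parent,
#' apply Benjamini-Yekutieli correction separately within each of the
#' three test families across all candidates, and classify every gene with
#' [classify_gene()].
#'
#' By default the t-tests run on `log2(CPM + pseudocount)` for variance
#' stabilization, with the MPV reference transformed onto the same scale
#' (`log2(MPV + pseudocount)`); the MPV itself is always the arithmetic
#' mid-parent of normalized group means, so a truly additive gene is
#' centred on its reference under either scale. `log_scale = FALSE` runs
#' everything on the untransformed normalized values.
#'
#' Total-count CPM assumes that most genes are equally expressed across
#' samples. When a large share of the transcriptome changes in one
#' direction (as in simulations that place hundreds of over-dominant genes
#' in the F1), the F1 column totals absorb that shift and CPM biases every
#' gene's F1 value; no normalization based on the counts alone can undo
#' this. `normalization = "none"` analyzes raw counts as-is, which is the
#' unbiased choice for simulated data whose library factors are centred at
#' 1 (see [sim_config()]); real data should be CPM-normalized or supplied
#' pre-normalized.
#'
#' @param x a [count_matrix()] containing the tissue's samples with all
#'   three groups (P1, P2, F1), >= 2 samples each.
#' @param tissue tissue label to analyze.
#' @param alpha significance level applied to BY-adjusted p-values.
#' @param normalization `"cpm"` (default) scales by column totals;
#'   `"none"` uses raw counts as the normalized values (see Details).
#' @param log_scale run the t-tests on log2(value + pseudocount)
#'   (default) or on the untransformed values.
#' @param mpv_test `"one-sample"` (default): one-sample t-test of F1
#'   values against the scalar MPV reference; `"two-sample"`: Welch t-test
#'   of the F1 values against the pooled parental values recentred (per
#'   parent) to the MPV reference, which acknowledges that the MPV is an
#'   estimate.
#' @param pseudocount offset for the log transform.
#' @return `data.frame` with one row per candidate gene: `gene_id`,
#'   `mpv`, `mean_p1`, `mean_p2`, `mean_f1` (all on the normalized,
#'   untransformed scale, so `mpv == (mean_p1 + mean_p2) / 2` exactly),
#'   `high_parent`, raw and
#'   BY-adjusted p-values for the three tests (`p_mpv`, `q_mpv`, `p_high`,
#'   `q_high`, `p_low`, `q_low`) and `category`. Attributes `tissue` and
#'   `alpha` record the run.
#' @export
run_pattern_analysis <- function(x, tissue, alpha = 0.05,
                                 normalization = c("cpm", "none"),
                                 log_scale = TRUE,
                                 mpv_test = c("one-sample", "two-sample"),
                                 pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  mpv_test <- match.arg(mpv_test)
  normalization <- match.arg(normalization)
  ids <- x$samples$sample_id[x$samples$tissue == tissue]
  if (length(ids) == 0) stop("unknown tissue: ", tissue, call. = FALSE)
  meta <- x$samples[x$samples$tissue == tissue, , drop = FALSE]
  for (g in GROUP_LEVELS) {
    if (sum(meta$group == g) < 2) {
      stop("group ", g, " needs >= 2 samples in tissue ", tissue,
           call. = FALSE)
    }
  }
  sub <- count_matrix(x$counts[, ids, drop = FALSE], meta)
  candidates <- filter_candidates(sub, tissue)

  empty <- data.frame(gene_id = character(), mpv = numeric(),
                      mean_p1 = numeric(), mean_p2 = numeric(),
                      mean_f1 = numeric(), high_parent = character(),
                      p_mpv = numeric(), q_mpv = numeric(),
                      p_high = numeric(), q_high = numeric(),
                      p_low = numeric(), q_low = numeric(),
                      category = character(), stringsAsFactors = FALSE)
  if (length(candidates) == 0) {
    attr(empty, "tissue") <- tissue
    attr(empty, "alpha") <- alpha
    return(empty)
  }

  cpm <- if (normalization == "cpm") {
    normalize_cpm(sub)
  } else {
    norm_matrix(sub$counts, sub$samples, method_tag = "none")
  }
  analysis <- if (log_scale) log_transform(cpm, pseudocount) else cpm
  ids_p1 <- group_samples(meta, "P1")
  ids_p2 <- group_samples(meta, "P2")
  ids_f1 <- group_samples(meta, "F1")

  cv <- cpm$values[candidates, , drop = FALSE]
  av <- analysis$values[candidates, , drop = FALSE]
  mean_p1 <- rowMeans(cv[, ids_p1, drop = FALSE])
  mean_p2 <- rowMeans(cv[, ids_p2, drop = FALSE])
  mean_f1 <- rowMeans(cv[, ids_f1, drop = FALSE])
  mpv <- (mean_p1 + mean_p2) / 2
  mpv_ref <- if (log_scale) log2(mpv + pseudocount) else mpv

  n_g <- length(candidates)
  p_mpv <- p_high <- p_low <- rep(NA_real_, n_g)
  high_parent <- character(n_g)
  a_f1 <- av[, ids_f1, drop = FALSE]
  a_p1 <- av[, ids_p1, drop = FALSE]
  a_p2 <- av[, ids_p2, drop = FALSE]

  for (i in seq_len(n_g)) {
    f1 <- a_f1[i, ]
    if (mean_p1[i] > mean_p2[i]) {
      high_parent[i] <- "P1"; hi <- a_p1[i, ]; lo <- a_p2[i, ]
    } else if (mean_p2[i] > mean_p1[i]) {
      high_parent[i] <- "P2"; hi <- a_p2[i, ]; lo <- a_p1[i, ]
    } else {
      high_parent[i] <- "tie"; hi <- a_p1[i, ]; lo <- a_p2[i, ]
    }
    if (mpv_test == "one-sample") {
      p_mpv[i] <- test_vs_mpv(f1, mpv_ref[i])$p_value
    } else {
      ref <- c(a_p1[i, ] - mean(a_p1[i, ]) + mpv_ref[i],
               a_p2[i, ] - mean(a_p2[i, ]) + mpv_ref[i])
      p_mpv[i] <- welch_t(f1, ref)$p_value
    }
    p_high[i] <- welch_t(f1, hi)$p_value
    p_low[i] <- welch_t(f1, lo)$p_value
  }

  q_mpv <- by_adjust(p_mpv)
  q_high <- by_adjust(p_high)
  q_low <- by_adjust(p_low)

  a_mean_f1 <- rowMeans(a_f1)
  a_mean_p1 <- rowMeans(a_p1)
  a_mean_p2 <- rowMeans(a_p2)
  category <- vapply(seq_len(n_g), function(i) {
    hi_m <- switch(high_parent[i], P1 = a_mean_p1[i], P2 = a_mean_p2[i],
                   tie = a_mean_p1[i])
    lo_m <- switch(high_parent[i], P1 = a_mean_p2[i], P2 = a_mean_p1[i],
                   tie = a_mean_p2[i])
    classify_gene(q_mpv[i], q_high[i], q_low[i],
                  mean_f1 = a_mean_f1[i], mean_high = hi_m, mean_low = lo_m,
                  high_parent = high_parent[i], alpha = alpha)
  }, character(1))

  out <- data.frame(gene_id = candidates,
                    mpv = unname(mpv),
                    mean_p1 = unname(mean_p1),
                    mean_p2 = unname(mean_p2),
                    mean_f1 = unname(mean_f1),
                    high_parent = high_parent,
                    p_mpv = p_mpv, q_mpv = q_mpv,
                    p_high = p_high, q_high = q_high,
                    p_low = p_low, q_low = q_low,
                    category = category,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "tissue") <- tissue
  attr(out, "alpha") <- alpha
  out
}
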