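test_that("candidate filter keeps genes expressed in at least half the samples", {
  n <- 3  # 9 samples per tissue
  m <- matrix(0L, nrow = 4, ncol = 9,
              dimnames = list(c("g_none", "g_below", "g_at", "g_all"), NULL))
  m["g_below", 1:4] <- 1L   # 4 of 9 < ceiling(9/2) = 5
  m["g_at", 1:5] <- 1L      # exactly at threshold
  m["g_all", ] <- 2L
  x <- toy_counts(m, n = n)
  kept <- filter_candidates(x, "liver")
  expect_identical(kept, c("g_at", "g_all"))
  expect_error(filter_candidates(x, "kidney"), "kidney")
})

test_that("mid-parent value is the mean of parental group means", {
  m <- matrix(c(2L, 4L, 6L, 10L, 10L, 10L, 1L, 2L, 3L), nrow = 1,
              dimnames = list("gA", NULL))
  x <- toy_counts(m, n = 3)
  raw <- norm_matrix(x$counts, x$samples, "none")
  expect_identical(mid_parent_value(raw, "gA"), 7)  # (4 + 10) / 2

  # symmetric case: both parents at v -> MPV = v
  m2 <- matrix(c(5L, 5L, 5L, 5L, 5L, 5L, 9L, 9L, 9L), nrow = 1,
               dimnames = list("gA", NULL))
  x2 <- toy_counts(m2, n = 3)
  expect_identical(mid_parent_value(norm_matrix(x2$counts, x2$samples, "none"),
                                    "gA"), 5)
  expect_error(mid_parent_value(raw, "gZ"), "gZ")
})

test_that("by_adjust applies the harmonic-sum inflation", {
  expect_identical(by_adjust(0.04), 0.04)  # c(1) = 1
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3),
               tolerance = 1e-15)          # BH 0.03 * c(3) = 11/6
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_true(all(by_adjust(p) >= bh_adjust(p)))
  }
  expect_error(by_adjust(c(0.2, 1.5)), "\\[0, 1\\]")
})

test_that("one-sample MPV test matches the t formula and handles degeneracy", {
  # sample mean equals MPV exactly -> t = 0, p = 1
  r <- test_vs_mpv(c(10, 11, 12, 9, 10, 11), 10.5)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  # constant values equal to MPV
  expect_identical(test_vs_mpv(c(4, 4, 4), 4)$p_value, 1)
  # large shift with tiny spread
  expect_lt(test_vs_mpv(c(100.001, 100.002, 100.003), 10)$p_value, 1e-3)
  # agreement with stats::t.test on generic input
  set.seed(12)
  v <- rnorm(6, 20, 2)
  expect_equal(test_vs_mpv(v, 19)$p_value, t.test(v, mu = 19)$p.value)
  expect_error(test_vs_mpv(5, 1), ">= 2")
})

test_that("the classification decision tree covers all branches", {
  base <- list(mean_f1 = 5, mean_high = 8, mean_low = 2, high_parent = "P1")
  cl <- function(q_mpv, q_high, q_low, ...) {
    args <- utils::modifyList(base, list(...))
    do.call(classify_gene, c(list(q_mpv = q_mpv, q_high = q_high,
                                  q_low = q_low), args))
  }
  expect_identical(cl(0.40, 0.001, 0.001), "additive")
  expect_identical(cl(0.001, 0.002, 0.5, mean_f1 = 9), "over_dominance")
  expect_identical(cl(0.001, 0.5, 0.002, mean_f1 = 1), "under_dominance")
  expect_identical(cl(0.001, 0.50, 0.003), "enhancing_dominance")
  expect_identical(cl(0.001, 0.003, 0.50), "suppressing_dominance")
  # differs from both parents while lying between them
  expect_identical(cl(0.001, 0.003, 0.004), "unclassified_nonadditive")
  # tied parents block the dominance branches
  expect_identical(cl(0.001, 0.001, 0.001, high_parent = "tie"),
                   "unclassified_nonadditive")
  expect_identical(cl(0.4, 0.9, 0.9, high_parent = "tie"), "additive")
  expect_identical(cl(NA, 0.1, 0.1), "not_testable")

  # over-dominance needs the direction, not just significance vs the high
  # parent: F1 below the high parent and indistinguishable from the low
  # parent is suppressing dominance
  expect_identical(cl(0.001, 0.002, 0.5, mean_f1 = 7), "suppressing_dominance")
})

test_that("classification matches exhaustive enumeration of the decision table", {
  # independent oracle: enumerate significance x position combinations and
  # derive the expected label from the category definitions directly
  oracle <- function(sig_mpv, sig_high, sig_low, pos) {
    if (!sig_mpv) return("additive")
    if (sig_high && pos == "above_high") return("over_dominance")
    if (sig_low && pos == "below_low") return("under_dominance")
    if (!sig_high && sig_low) return("enhancing_dominance")
    if (!sig_low && sig_high) return("suppressing_dominance")
    "unclassified_nonadditive"
  }
  for (sig_mpv in c(TRUE, FALSE)) for (sig_high in c(TRUE, FALSE))
    for (sig_low in c(TRUE, FALSE))
      for (pos in c("above_high", "between", "below_low")) {
        mean_f1 <- switch(pos, above_high = 9, between = 5, below_low = 1)
        got <- classify_gene(q_mpv = if (sig_mpv) 0.01 else 0.5,
                             q_high = if (sig_high) 0.01 else 0.5,
                             q_low = if (sig_low) 0.01 else 0.5,
                             mean_f1 = mean_f1, mean_high = 8, mean_low = 2,
                             high_parent = "P1")
        expect_identical(got, oracle(sig_mpv, sig_high, sig_low, pos))
      }
})

test_that("pattern analysis partitions candidates and is label-symmetric", {
  cfg <- sim_config(n_genes_per_mode = c(additive = 40,
                                         enhancing_dominance = 15,
                                         suppressing_dominance = 15,
                                         over_dominance = 15,
                                         under_dominance = 15,
                                         null_equal = 20),
                    effect_log2 = 3, overshoot_log2 = 1.5,
                    dispersion = 0.05, seed = 17)
  sim <- simulate_cross(cfg, tissue = "breast_muscle")
  rec <- run_pattern_analysis(sim$counts, "breast_muscle",
                              normalization = "none")

  # partition: every candidate gets exactly one category
  expect_identical(sort(rec$gene_id),
                   sort(filter_candidates(sim$counts, "breast_muscle")))
  expect_true(all(rec$category %in% pattern_categories()))
  s <- summarize_patterns(rec)
  cat_cols <- paste0("n_", pattern_categories())
  expect_identical(sum(unlist(s[cat_cols])), s$n_candidates)

  # record invariants
  expect_equal(rec$mpv, (rec$mean_p1 + rec$mean_p2) / 2, tolerance = 1e-12)
  expect_true(all((rec$category == "additive") == (rec$q_mpv >= 0.05)))
  expect_true(all(rec$q_mpv >= rec$p_mpv))

  # swapping the P1/P2 labels leaves every category unchanged
  meta_sw <- sim$counts$samples
  meta_sw$group[meta_sw$group == "P1"] <- "tmp"
  meta_sw$group[meta_sw$group == "P2"] <- "P1"
  meta_sw$group[meta_sw$group == "tmp"] <- "P2"
  x_sw <- count_matrix(sim$counts$counts, meta_sw)
  rec_sw <- run_pattern_analysis(x_sw, "breast_muscle",
                                 normalization = "none")
  expect_identical(rec_sw$category[match(rec$gene_id, rec_sw$gene_id)],
                   rec$category)

  # doubling every raw count leaves CPM, hence every category, unchanged
  x2 <- count_matrix(sim$counts$counts * 2, sim$counts$samples)
  rec2 <- run_pattern_analysis(x2, "breast_muscle")
  rec1 <- run_pattern_analysis(sim$counts, "breast_muscle")
  expect_identical(rec2$category, rec1$category)
  expect_equal(rec2$mpv, rec1$mpv, tolerance = 1e-9)
})

test_that("pattern analysis handles empty candidate sets and missing groups", {
  m <- matrix(0L, nrow = 3, ncol = 6,
              dimnames = list(c("gA", "gB", "gC"), NULL))
  m[, 1] <- 1L  # every gene expressed in only 1 of 6 samples
  x <- toy_counts(m, n = 2)
  rec <- run_pattern_analysis(x, "liver", normalization = "none")
  expect_identical(nrow(rec), 0L)
  s <- summarize_patterns(rec)
  expect_identical(s$n_candidates, 0L)
  expect_true(is.na(s$fraction_nonadditive))

  meta <- toy_meta(2)
  meta$group[meta$group == "F1"] <- "P1"
  m2 <- matrix(5L, 2, 6, dimnames = list(c("gA", "gB"), meta$sample_id))
  expect_error(run_pattern_analysis(count_matrix(m2, meta), "liver"), "F1")
})
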