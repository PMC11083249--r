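# Brute-force step-up FDR oracle, O(m^2) by the textbook definition:
# adj_(k) = min(1, min_{j >= k} scale * m * p_(j) / j) on sorted p,
# mapped back to input order. scale = 1 gives Benjamini-Hochberg,
# scale = sum(1/i) gives Benjamini-Yekutieli.
step_up_oracle <- function(p, scale = 1) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  cand <- scale * m * ps / seq_len(m)
  adj_sorted <- vapply(seq_len(m), function(k) min(1, min(cand[k:m])),
                       numeric(1))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

bh_oracle <- function(p) step_up_oracle(p, scale = 1)
by_oracle <- function(p) step_up_oracle(p, scale = sum(1 / seq_along(p)))

# Small three-group count fixture: one tissue, n samples per group.
toy_meta <- function(n = 2, tissue = "liver") {
  sample_meta(
    sample_id = c(paste0("P1_", seq_len(n)), paste0("P2_", seq_len(n)),
                  paste0("F1_", seq_len(n))),
    group = rep(c("P1", "P2", "F1"), each = n),
    tissue = tissue,
    sex = "unknown")
}

toy_counts <- function(mat, n = 2, tissue = "liver") {
  meta <- toy_meta(n, tissue)
  colnames(mat) <- meta$sample_id
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  }
  count_matrix(mat, meta)
}

# Simulated cross used by several acceptance checks (strong-signal
# configuration); memoised so the suite pays for it once.
strong_signal_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_genes_per_mode = c(additive = 200, enhancing_dominance = 200,
                             suppressing_dominance = 200,
                             over_dominance = 200, under_dominance = 200,
                             null_equal = 200),
        n_per_group = 6, effect_log2 = 3, overshoot_log2 = 1.5,
        dispersion = 0.05, seed = 20240101)
      sim <- simulate_cross(cfg, tissue = "liver")
      rec <- run_pattern_analysis(sim$counts, "liver",
                                  normalization = "none")
      cache <<- list(sim = sim, records = rec)
    }
    cache
  }
})

recovery_rates <- function(sim, records) {
  truth <- sim$truth$mode[match(records$gene_id, sim$truth$gene_id)]
  modes <- c("additive", "enhancing_dominance", "suppressing_dominance",
             "over_dominance", "under_dominance")
  vapply(modes, function(m) {
    mean(records$category[truth == m] == m)
  }, numeric(1))
}
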