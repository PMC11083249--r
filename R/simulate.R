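SIM_MODES <- c("additive", "enhancing_dominance", "suppressing_dominance",
               "over_dominance", "under_dominance", "null_equal")

#' Simulation configuration for a two-parent/F1 cross
#'
#' Defines the generative model for [simulate_cross()]: per-gene negative
#' binomial counts for three groups (P1, P2, F1) whose means encode a known
#' inheritance mode. Parental means are placed symmetrically around
#' `base_mean` at a log2 distance of `effect_log2`; the F1 mean is then
#' determined by the mode (see Details).
#'
#' @details Mode-specific F1 means, with `hi`/`lo` the high/low parental
#' mean:
#' * `additive`: arithmetic mid-parent, `(mu_p1 + mu_p2) / 2`.
#' * `enhancing_dominance`: `hi`; `suppressing_dominance`: `lo`.
#' * `over_dominance`: `hi * 2^overshoot_log2`;
#'   `under_dominance`: `lo / 2^overshoot_log2`.
#' * `null_equal`: all three groups share `base_mean` (a pure null used to
#'   measure the classifier's false-non-additive rate).
#'
#' Which parent carries the high mean alternates gene-by-gene, so neither
#' line is systematically the high parent.
#'
#' @param n_genes_per_mode named integer vector giving the number of genes
#'   per mode; names must be a subset of
#'   `r paste0('"', SIM_MODES, '"', collapse = ", ")`.
#' @param n_per_group replicates per group (birds per line); must be >= 2
#'   so group variances are estimable.
#' @param base_mean expected count scale (geometric centre of the two
#'   parental means).
#' @param effect_log2 parental log2 difference (high vs low parent).
#' @param overshoot_log2 F1 log2 excess beyond the high parent
#'   (over-dominance) or below the low parent (under-dominance).
#' @param dispersion negative binomial dispersion; count variance is
#'   `mean + dispersion * mean^2`.
#' @param libsize_cv coefficient of variation of per-sample library-size
#'   factors (log-normal with mean 1); 0 gives all factors exactly 1.
#' @param seed integer seed; identical configurations with identical seeds
#'   produce byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes_per_mode = c(additive = 500,
                                            enhancing_dominance = 40,
                                            suppressing_dominance = 40,
                                            over_dominance = 40,
                                            under_dominance = 40,
                                            null_equal = 100),
                       n_per_group = 6,
                       base_mean = 200,
                       effect_log2 = 2,
                       overshoot_log2 = 1,
                       dispersion = 0.1,
                       libsize_cv = 0.1,
                       seed = 1) {
  if (is.null(names(n_genes_per_mode)) ||
      length(setdiff(names(n_genes_per_mode), SIM_MODES)) > 0) {
    stop("n_genes_per_mode must be named with modes among: ",
         paste(SIM_MODES, collapse = ", "), call. = FALSE)
  }
  nms <- names(n_genes_per_mode)
  n_genes_per_mode <- as.integer(n_genes_per_mode)
  names(n_genes_per_mode) <- nms
  if (any(n_genes_per_mode < 0)) {
    stop("gene counts per mode must be >= 0", call. = FALSE)
  }
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    stop("n_per_group must be >= 2 (tests need at least 2 replicates)",
         call. = FALSE)
  }
  for (nm in c("base_mean", "effect_log2", "overshoot_log2", "dispersion")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(nm, " must be a single positive number", call. = FALSE)
    }
  }
  if (!is.numeric(libsize_cv) || libsize_cv < 0) {
    stop("libsize_cv must be >= 0", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  structure(list(n_genes_per_mode = n_genes_per_mode,
                 n_per_group = as.integer(n_per_group),
                 base_mean = base_mean,
                 effect_log2 = effect_log2,
                 overshoot_log2 = overshoot_log2,
                 dispersion = dispersion,
                 libsize_cv = libsize_cv,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw negative binomial counts with a mean/dispersion parameterization
#'
#' Variance is `mean + dispersion * mean^2`; as `dispersion` approaches 0
#' the draw approaches Poisson(`mean`). Uses the current RNG state.
#'
#' @param n number of draws.
#' @param mean positive mean.
#' @param dispersion positive dispersion.
#' @return Integer vector of non-negative counts.
#' @export
nb_draw <- function(n, mean, dispersion) {
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    stop("mean must be positive", call. = FALSE)
  }
  if (any(!is.finite(dispersion)) || any(dispersion <= 0)) {
    stop("dispersion must be positive", call. = FALSE)
  }
  stats::rnbinom(n, mu = mean, size = 1 / dispersion)
}

#' Simulate a P1/P2/F1 count matrix with known inheritance modes
#'
#' Generates one tissue's worth of samples (`n_per_group` per group) and a
#' ground-truth table recording each gene's mode and generative means.
#' Counts are drawn from a negative binomial with mean
#' `mode-determined mu * sample library factor` and the configured
#' dispersion.
#'
#' @param config a [sim_config()].
#' @param tissue tissue label written into the sample metadata.
#' @return A list with elements:
#' * `counts`: a [count_matrix()] (genes x 3 * n_per_group samples),
#' * `truth`: `data.frame` with `gene_id`, `mode`, `mu_p1`, `mu_p2`,
#'   `mu_f1` (means before library-size scaling),
#' * `lib_factors`: named numeric vector of per-sample library factors.
#' @export
simulate_cross <- function(config, tissue = "liver") {
  if (!inherits(config, "sim_config")) {
    stop("config must be created with sim_config()", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_per_group
  modes <- rep(names(config$n_genes_per_mode), config$n_genes_per_mode)
  n_genes <- length(modes)

  sample_id <- c(paste0("P1_", seq_len(n)), paste0("P2_", seq_len(n)),
                 paste0("F1_", seq_len(n)))
  meta <- sample_meta(sample_id,
                      group = rep(GROUP_LEVELS, each = n),
                      tissue = tissue,
                      sex = rep_len(c("F", "M"), 3 * n))

  if (config$libsize_cv > 0) {
    sdlog <- sqrt(log(1 + config$libsize_cv^2))
    fac <- stats::rlnorm(3 * n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    fac <- rep(1, 3 * n)
  }
  names(fac) <- sample_id

  mu_lo <- config$base_mean * 2^(-config$effect_log2 / 2)
  mu_hi <- config$base_mean * 2^(config$effect_log2 / 2)

  gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  mu_p1 <- mu_p2 <- mu_f1 <- numeric(n_genes)
  counts <- matrix(0, nrow = n_genes, ncol = 3 * n,
                   dimnames = list(gene_id, sample_id))
  grp <- rep(GROUP_LEVELS, each = n)

  for (i in seq_len(n_genes)) {
    mode <- modes[i]
    if (mode == "null_equal") {
      p1 <- p2 <- config$base_mean
    } else if (i %% 2 == 1) {   # alternate which line is the high parent
      p1 <- mu_hi; p2 <- mu_lo
    } else {
      p1 <- mu_lo; p2 <- mu_hi
    }
    f1 <- switch(mode,
      additive = (p1 + p2) / 2,
      enhancing_dominance = max(p1, p2),
      suppressing_dominance = min(p1, p2),
      over_dominance = max(p1, p2) * 2^config$overshoot_log2,
      under_dominance = min(p1, p2) / 2^config$overshoot_log2,
      null_equal = config$base_mean)
    mu_p1[i] <- p1; mu_p2[i] <- p2; mu_f1[i] <- f1
    mu_s <- c(p1, p2, f1)[match(grp, GROUP_LEVELS)] * fac
    counts[i, ] <- nb_draw(3 * n, mean = mu_s, dispersion = config$dispersion)
  }

  truth <- data.frame(gene_id = gene_id, mode = modes,
                      mu_p1 = mu_p1, mu_p2 = mu_p2, mu_f1 = mu_f1,
                      stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, meta), truth = truth, lib_factors = fac)
}
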