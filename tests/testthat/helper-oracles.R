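# Independent oracles used across the suite. These are deliberately written
# with different algorithms than the package code paths they check.

# Exact one-sided (positive shift) signed-rank p-value by looping over all
# 2^n sign patterns with bit arithmetic.
oracle_signed_rank_greater <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(1)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0
    if (sum(r[signs]) >= W) hits <- hits + 1L
  }
  hits / 2^n
}

# Closed-form null expectation of the "exactly k concordant strains" count
# for N genes, S strains, per-strain significance probability alpha and
# symmetric up/down directions.
oracle_shared_null_mean <- function(N, S, k, alpha) {
  N * choose(S, k) * (1 - alpha)^(S - k) * 2 * (alpha / 2)^k
}

# Spearman rho by the classical rank-difference formula (no ties).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Brute-force average-linkage agglomeration on a distance matrix: returns
# sorted merge heights.
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- mean(d[clusters[[i]], clusters[[j]]])
          if (h < best_h) {
            best_h <- h
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Minimal GeneFitTable-like frame from explicit p-values and directions.
make_fit_table <- function(genes, p, log2fc) {
  data.frame(
    gene = genes, log2fc = log2fc, fc = 2^log2fc,
    t = NA_real_, p = p, fdr = stats::p.adjust(p, "BH"),
    stringsAsFactors = FALSE
  )
}

# Small two-strain, one-tissue simulated study used by several tests.
small_sim <- function(seed, n_genes = 200, effects = mouse_effect_model(), reps = 8L) {
  simulate_mouse_study(
    study_design(
      strains = c("A", "B"), tissues = "T1",
      replicates_per_cell = reps, n_genes = n_genes
    ),
    effects,
    seed = seed
  )
}
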