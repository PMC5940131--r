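# Cross-strain shared CR responses: how many genes respond in the same
# direction in exactly k strains at a nominal per-strain threshold, compared
# with a permutation null in which responses are randomly associated among
# strains.

# Align per-strain (p, direction) onto the common gene universe.
shared_response_inputs <- function(fit_tables, alpha) {
  stopifnot(is.list(fit_tables), length(fit_tables) >= 2L, !is.null(names(fit_tables)))
  assert_probability(alpha, "alpha")
  genes <- Reduce(intersect, lapply(fit_tables, `[[`, "gene"))
  if (length(genes) == 0L) {
    stop("gene universes of the fit tables are disjoint", call. = FALSE)
  }
  p <- sapply(fit_tables, function(tb) tb$p[match(genes, tb$gene)])
  up <- sapply(fit_tables, function(tb) tb$log2fc[match(genes, tb$gene)] > 0)
  list(genes = genes, p = p, up = up)
}

count_shared <- function(sig, up, n_strains) {
  k <- rowSums(sig)
  n_up <- rowSums(sig & up)
  concordant <- k > 0 & (n_up == k | n_up == 0)
  counts <- tabulate(k[concordant], nbins = n_strains)
  list(counts = counts, discordant = sum(k > 0 & !concordant))
}

#' Observed cross-strain shared-response counts
#'
#' A strain "responds" for a gene when its raw p-value is below `alpha`; the
#' gene is tallied under k = number of responding strains only when all
#' responding strains agree in fold-change direction. Genes whose responding
#' strains disagree in direction are tallied separately as discordant.
#'
#' @param fit_tables named list of per-strain `GeneFitTable`s sharing a gene
#'   universe (the intersection of genes is used).
#' @param alpha per-strain nominal p-value threshold (default 0.05).
#' @return object of class `SharedResponseTable`: data frame with columns
#'   k, observed, observed_at_least (count for >= k strains); attributes
#'   `discordant`, `alpha`, `n_genes`.
#' @export
shared_counts <- function(fit_tables, alpha = 0.05) {
  inp <- shared_response_inputs(fit_tables, alpha)
  n_strains <- ncol(inp$p)
  obs <- count_shared(inp$p < alpha, inp$up, n_strains)
  out <- data.frame(
    k = seq_len(n_strains),
    observed = obs$counts,
    observed_at_least = rev(cumsum(rev(obs$counts)))
  )
  attr(out, "discordant") <- obs$discordant
  attr(out, "alpha") <- alpha
  attr(out, "n_genes") <- length(inp$genes)
  class(out) <- c("SharedResponseTable", "data.frame")
  out
}

#' Permutation null for shared-response counts
#'
#' Each permutation independently shuffles every strain's per-gene
#' (p, direction) pairs across the common gene universe — preserving each
#' strain's marginal distribution exactly while breaking cross-strain
#' association — and recounts shared responses. The empirical p-value for
#' each k is `(1 + #{permutations with count >= observed}) / (B + 1)`.
#'
#' @inheritParams shared_counts
#' @param B number of permutations (>= 100).
#' @param seed integer seed.
#' @return `SharedResponseTable` with added columns null_mean, null_sd,
#'   p_empirical (for the "exactly k" counts) and null_mean_at_least,
#'   p_empirical_at_least (for the ">= k" counts).
#' @export
shared_null <- function(fit_tables, alpha = 0.05, B = 1000L, seed) {
  B <- assert_count(B, "B", min = 100L)
  seed <- assert_count(seed, "seed", min = 0L)
  obs_tab <- shared_counts(fit_tables, alpha)
  inp <- shared_response_inputs(fit_tables, alpha)
  n_strains <- ncol(inp$p)
  n_genes <- length(inp$genes)
  sig <- inp$p < alpha
  up <- inp$up

  set.seed(seed)
  null_counts <- matrix(0L, B, n_strains)
  null_at_least <- matrix(0L, B, n_strains)
  for (b in seq_len(B)) {
    perm_sig <- sig
    perm_up <- up
    for (s in seq_len(n_strains)) {
      ord <- sample.int(n_genes)
      perm_sig[, s] <- sig[ord, s]
      perm_up[, s] <- up[ord, s]
    }
    cnt <- count_shared(perm_sig, perm_up, n_strains)$counts
    null_counts[b, ] <- cnt
    null_at_least[b, ] <- rev(cumsum(rev(cnt)))
  }
  obs_tab$null_mean <- colMeans(null_counts)
  obs_tab$null_sd <- apply(null_counts, 2, stats::sd)
  obs_tab$p_empirical <- vapply(seq_len(n_strains), function(k) {
    (1 + sum(null_counts[, k] >= obs_tab$observed[k])) / (B + 1)
  }, numeric(1))
  obs_tab$null_mean_at_least <- colMeans(null_at_least)
  obs_tab$p_empirical_at_least <- vapply(seq_len(n_strains), function(k) {
    (1 + sum(null_at_least[, k] >= obs_tab$observed_at_least[k])) / (B + 1)
  }, numeric(1))
  attr(obs_tab, "B") <- B
  attr(obs_tab, "seed") <- seed
  obs_tab
}

#' Signature score: average fold-change over predefined gene lists
#'
#' Arithmetic mean of the linear fold-change over the members of an
#' "increased by CR" list and a "decreased by CR" list that are present in
#' the fit table.
#'
#' @param fit_table a `GeneFitTable`.
#' @param up_genes,down_genes character vectors of gene symbols.
#' @return data frame with one row per list: direction, mean_fc, n_matched.
#'   Lists with no overlap get NA mean and a warning.
#' @export
signature_score <- function(fit_table, up_genes, down_genes) {
  stopifnot(is.data.frame(fit_table), all(c("gene", "fc") %in% names(fit_table)))
  score_one <- function(genes, label) {
    fc <- fit_table$fc[fit_table$gene %in% genes]
    if (length(fc) == 0L) {
      warning("no ", label, " signature genes found in fit table", call. = FALSE)
      return(data.frame(direction = label, mean_fc = NA_real_, n_matched = 0L))
    }
    data.frame(direction = label, mean_fc = mean(fc), n_matched = length(fc))
  }
  rbind(score_one(up_genes, "up"), score_one(down_genes, "down"))
}

#' Quadrant proportions of paired fold-changes with chi-square tests
#'
#' Pairs of linear fold-changes (e.g. focal strain vs average of other
#' strains) are assigned to quadrants by the signs of their log2
#' fold-changes; pairs lying on either axis (FC = 1) are excluded. Each
#' quadrant's proportion is tested against the uniform expectation 0.25 by a
#' one-cell goodness-of-fit chi-square (df = 1, no continuity correction);
#' only quadrants exceeding 0.25 with p < 0.05 are flagged.
#'
#' @param fc_pairs two-column numeric matrix or data frame of linear
#'   fold-changes; at least 20 usable pairs required.
#' @return data frame with quadrant (I: +/+, II: -/+, III: -/-, IV: +/-),
#'   n, proportion, chisq, p, flagged.
#' @export
quadrant_proportion_test <- function(fc_pairs) {
  fc_pairs <- as.matrix(fc_pairs)
  stopifnot(ncol(fc_pairs) == 2L, is.numeric(fc_pairs))
  usable <- fc_pairs[, 1] != 1 & fc_pairs[, 2] != 1 &
    fc_pairs[, 1] > 0 & fc_pairs[, 2] > 0
  x <- log2(fc_pairs[usable, 1])
  y <- log2(fc_pairs[usable, 2])
  n <- length(x)
  if (n < 20L) stop("fewer than 20 usable fold-change pairs", call. = FALSE)
  quadrant <- ifelse(x > 0,
    ifelse(y > 0, "I", "IV"),
    ifelse(y > 0, "II", "III")
  )
  labs <- c("I", "II", "III", "IV")
  counts <- vapply(labs, function(q) sum(quadrant == q), numeric(1))
  e1 <- n / 4
  chisq <- (counts - e1)^2 / e1 + ((n - counts) - 3 * n / 4)^2 / (3 * n / 4)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  data.frame(
    quadrant = labs,
    n = counts,
    proportion = counts / n,
    chisq = chisq,
    p = p,
    flagged = counts / n > 0.25 & p < 0.05,
    row.names = NULL
  )
}
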