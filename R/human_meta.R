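# Random-effects meta-analysis of paired human CR experiments. Each
# experiment contributes a per-gene mean paired log2 difference and its
# standard error; dependent experiments (shared baseline sample sets) are
# filtered to one representative, and gene-level effects are synthesized by
# the DerSimonian-Laird estimator with inverse-variance weighting.

#' Construct a paired before/after experiment
#'
#' @param experiment_id unique identifier.
#' @param baseline,post genes x subjects log2 matrices with identical
#'   dimnames (subject-aligned columns).
#' @param baseline_set_id identifier of the baseline sample set; experiments
#'   sharing it are dependent.
#' @param sex "M", "F" or "unknown".
#' @param duration_weeks intervention duration.
#' @return object of class `PairedExperiment`.
#' @export
paired_experiment <- function(experiment_id, baseline, post, baseline_set_id,
                              sex = "unknown", duration_weeks = NA_real_) {
  stopifnot(is.matrix(baseline), is.matrix(post))
  if (!identical(dimnames(baseline), dimnames(post)) ||
    !identical(dim(baseline), dim(post))) {
    stop("baseline and post matrices must share gene and subject indexing",
      call. = FALSE
    )
  }
  if (ncol(baseline) < 2L) stop("at least 2 subjects are required", call. = FALSE)
  if (is.null(rownames(baseline))) stop("matrices must have gene rownames", call. = FALSE)
  structure(
    list(
      experiment_id = experiment_id, baseline = baseline, post = post,
      baseline_set_id = baseline_set_id, n_subjects = ncol(baseline),
      sex = sex, duration_weeks = duration_weeks
    ),
    class = "PairedExperiment"
  )
}

#' @export
print.PairedExperiment <- function(x, ...) {
  cat(sprintf(
    "PairedExperiment %s: %d genes x %d subjects (baseline set %s)\n",
    x$experiment_id, nrow(x$baseline), x$n_subjects, x$baseline_set_id
  ))
  invisible(x)
}

#' Per-subject paired log2 differences
#'
#' @param exp a `PairedExperiment`.
#' @return genes x subjects matrix of `post - baseline` differences
#'   (positive = increased by CR).
#' @export
paired_log2_differences <- function(exp) {
  stopifnot(inherits(exp, "PairedExperiment"))
  exp$post - exp$baseline
}

#' Remove the lowest-expressed genes of an experiment
#'
#' Genes are ranked by mean log2 expression over all baseline and post
#' samples; the lowest `floor(fraction * n_genes)` are removed. Ties are
#' broken by removing the lexicographically smallest gene symbols first.
#'
#' @param exp a `PairedExperiment`.
#' @param fraction fraction of genes to remove (default 0.15).
#' @return character vector of retained gene names.
#' @export
low_expression_filter <- function(exp, fraction = 0.15) {
  stopifnot(inherits(exp, "PairedExperiment"))
  if (!(fraction > 0 && fraction < 1)) stop("`fraction` must be in (0, 1)", call. = FALSE)
  genes <- rownames(exp$baseline)
  avg <- rowMeans(cbind(exp$baseline, exp$post))
  n_drop <- floor(fraction * length(genes))
  if (n_drop == 0L) {
    return(genes)
  }
  drop <- genes[order(avg, genes)][seq_len(n_drop)]
  setdiff(genes, drop)
}

#' Per-gene summary statistics of one paired experiment
#'
#' Mean and standard error of the paired log2 differences per gene, with a
#' moderated one-sample t-test (residual df = n - 1) through the
#' empirical-Bayes machinery of [moderate_variances()].
#'
#' @param differences genes x subjects matrix from
#'   [paired_log2_differences()], usually restricted to the genes retained
#'   by [low_expression_filter()].
#' @return object of class `ExperimentSummary`: data frame with gene, mean,
#'   se, t, p, degenerate; attribute `average_se` (mean se over genes, the
#'   experiment ranking statistic).
#' @export
experiment_summary <- function(differences) {
  stopifnot(is.matrix(differences), is.numeric(differences))
  n <- ncol(differences)
  if (n < 2L) stop("at least 2 subjects are required", call. = FALSE)
  m <- rowMeans(differences)
  s2 <- apply(differences, 1, stats::var)
  se <- sqrt(s2 / n)
  mv <- moderate_variances(s2, n - 1)
  tt <- moderated_t_test(m, 1 / sqrt(n), mv$s2_post, n - 1, mv$d0)
  out <- data.frame(
    gene = rownames(differences),
    mean = unname(m),
    se = unname(se),
    t = unname(tt$t),
    p = unname(tt$p),
    degenerate = unname(tt$degenerate),
    stringsAsFactors = FALSE
  )
  attr(out, "average_se") <- mean(se)
  attr(out, "d0") <- mv$d0
  class(out) <- c("ExperimentSummary", "data.frame")
  out
}

#' Baseline-sharing independence filter
#'
#' Retains exactly one experiment per baseline sample set: the one with the
#' lowest average standard error, ties broken by lexicographic experiment
#' identifier.
#'
#' @param summaries data frame with columns experiment_id, baseline_set_id,
#'   average_se.
#' @return the retained rows, ordered by experiment_id.
#' @export
independence_filter <- function(summaries) {
  stopifnot(
    is.data.frame(summaries),
    all(c("experiment_id", "baseline_set_id", "average_se") %in% names(summaries))
  )
  ord <- order(summaries$baseline_set_id, summaries$average_se, summaries$experiment_id)
  s <- summaries[ord, , drop = FALSE]
  keep <- s[!duplicated(s$baseline_set_id), , drop = FALSE]
  keep <- keep[order(keep$experiment_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Gene inclusion filter for the meta-analysis
#'
#' @param presence logical genes x experiments matrix (TRUE when the gene is
#'   measured, i.e. present and retained, in that experiment).
#' @param min_experiments minimum number of experiments (default 6).
#' @return character vector of retained gene names.
#' @export
gene_inclusion_filter <- function(presence, min_experiments = 6L) {
  stopifnot(is.matrix(presence), is.logical(presence))
  min_experiments <- assert_count(min_experiments, "min_experiments")
  rownames(presence)[rowSums(presence) >= min_experiments]
}

#' DerSimonian-Laird random-effects synthesis for one gene
#'
#' Fixed-effect weights `w_i = 1/se_i^2` give Cochran's
#' `Q = sum w_i (y_i - ybar_w)^2`; the between-experiment variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `w*_i = 1/(se_i^2 + tau2)` give the pooled effect
#' `mu = sum w* y / sum w*` with `se(mu) = (sum w*)^(-1/2)` and a two-sided
#' normal p-value for `z = mu / se(mu)`.
#'
#' @param y numeric vector of per-experiment effects (mean log2 differences).
#' @param se positive standard errors, same length as `y` (k >= 2).
#' @return list with mu, se_mu, tau2, Q, z, p, k.
#' @export
dersimonian_laird <- function(y, se) {
  stopifnot(is.numeric(y), is.numeric(se), length(y) == length(se))
  k <- length(y)
  if (k < 2L) stop("at least 2 contributing experiments are required", call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("all standard errors must be positive and finite", call. = FALSE)
  }
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wstar <- 1 / (se^2 + tau2)
  mu <- sum(wstar * y) / sum(wstar)
  se_mu <- 1 / sqrt(sum(wstar))
  z <- mu / se_mu
  list(
    mu = mu, se_mu = se_mu, tau2 = tau2, Q = Q, z = z,
    p = 2 * stats::pnorm(-abs(z)), k = k
  )
}

# Vectorized DL over a genes x experiments effect/se pair of matrices
# (NA where a gene is absent from an experiment). Returns a data frame.
dersimonian_laird_matrix <- function(y_mat, se_mat) {
  ok <- is.finite(y_mat) & is.finite(se_mat) & se_mat > 0
  k <- rowSums(ok)
  w <- ifelse(ok, 1 / se_mat^2, 0)
  y0 <- ifelse(ok, y_mat, 0)
  sw <- rowSums(w)
  ybar <- rowSums(w * y0) / sw
  Q <- rowSums(w * (y0 - ybar)^2 * ok)
  denom <- sw - rowSums(w^2) / sw
  tau2 <- pmax(0, (Q - (k - 1)) / denom)
  wstar <- ifelse(ok, 1 / (se_mat^2 + tau2), 0)
  sws <- rowSums(wstar)
  mu <- rowSums(wstar * y0) / sws
  se_mu <- 1 / sqrt(sws)
  z <- mu / se_mu
  data.frame(
    gene = rownames(y_mat),
    meta_log2fc = unname(mu),
    meta_fc = unname(2^mu),
    se = unname(se_mu),
    tau2 = unname(tau2),
    q_cochran = unname(Q),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    k_experiments = unname(k),
    stringsAsFactors = FALSE
  )
}

#' Human CR meta-signature from paired experiments
#'
#' Full composition: per-experiment low-expression filtering, paired log2
#' differences and summaries, baseline-sharing independence filtering,
#' gene-inclusion filtering, per-gene DerSimonian-Laird synthesis, and a
#' single Benjamini-Hochberg adjustment over the final gene set. A gene with
#' zero standard error in an experiment has that experiment's se floored at
#' the 1st percentile of the experiment's positive se values (avoiding
#' infinite weight from degenerate genes).
#'
#' @param experiments list of `PairedExperiment`s (>= 2).
#' @param low_expr_fraction per-experiment low-expression fraction removed.
#' @param min_experiments gene-inclusion minimum.
#' @return object of class `MetaSignature`: data frame with gene,
#'   meta_log2fc, meta_fc, se, tau2, q_cochran, z, p, fdr, k_experiments;
#'   attributes `retained_experiments` and `n_input_experiments`.
#' @export
meta_signature <- function(experiments, low_expr_fraction = 0.15,
                           min_experiments = 6L) {
  stopifnot(is.list(experiments), length(experiments) >= 2L)
  summaries <- lapply(experiments, function(e) {
    keep <- low_expression_filter(e, low_expr_fraction)
    diffs <- paired_log2_differences(e)[keep, , drop = FALSE]
    experiment_summary(diffs)
  })
  manifest <- data.frame(
    experiment_id = vapply(experiments, `[[`, "", "experiment_id"),
    baseline_set_id = vapply(experiments, function(e) as.character(e$baseline_set_id), ""),
    average_se = vapply(summaries, function(s) attr(s, "average_se"), numeric(1)),
    stringsAsFactors = FALSE
  )
  retained <- independence_filter(manifest)
  if (nrow(retained) < 2L) {
    stop("fewer than 2 independent experiments after baseline-sharing filter",
      call. = FALSE
    )
  }
  idx <- match(retained$experiment_id, manifest$experiment_id)
  summaries <- summaries[idx]
  genes <- sort(Reduce(union, lapply(summaries, `[[`, "gene")))
  presence <- sapply(summaries, function(s) genes %in% s$gene)
  rownames(presence) <- genes
  colnames(presence) <- retained$experiment_id
  keep_genes <- gene_inclusion_filter(presence, min_experiments)

  y_mat <- sapply(summaries, function(s) s$mean[match(keep_genes, s$gene)])
  se_mat <- sapply(summaries, function(s) s$se[match(keep_genes, s$gene)])
  rownames(y_mat) <- rownames(se_mat) <- keep_genes
  # floor degenerate (zero) standard errors per experiment
  for (j in seq_len(ncol(se_mat))) {
    pos <- se_mat[, j][is.finite(se_mat[, j]) & se_mat[, j] > 0]
    if (length(pos)) {
      floor_j <- stats::quantile(pos, 0.01, names = FALSE)
      zero <- !is.na(se_mat[, j]) & se_mat[, j] == 0
      se_mat[zero, j] <- floor_j
    }
  }
  out <- dersimonian_laird_matrix(y_mat, se_mat)
  out <- out[out$k_experiments >= 2L, , drop = FALSE]
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  attr(out, "retained_experiments") <- retained
  attr(out, "n_input_experiments") <- length(experiments)
  class(out) <- c("MetaSignature", "data.frame")
  out
}
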