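# Genome-scale structure of CR responses: which factor (strain or diet)
# dominates each gene's expression variation, principal-component response
# vectors per strain, fold-change correlation matrices, and strain
# clustering.

#' Factor dominance of strain versus diet per gene
#'
#' For each gene, the full model `expression ~ strain + diet` is compared
#' against each reduced model by a Gaussian likelihood-ratio test with
#' statistic `n * ln(RSS_reduced / RSS_full)` referred to a chi-square
#' distribution with degrees of freedom equal to the number of dropped
#' parameters. The factor with the larger `-log10 p` (Log10P) is dominant;
#' ties break toward strain (which carries more parameters; exact ties are
#' measure-zero in practice).
#'
#' @param matrix genes x samples log2 matrix (one tissue).
#' @param strain,diet character vectors per sample.
#' @return list with `per_gene` (gene, log10p_diet, log10p_strain,
#'   dominant_factor) and `summary` (percent of genes per dominant factor).
#' @export
factor_dominance <- function(matrix, strain, diet) {
  stopifnot(length(strain) == ncol(matrix), length(diet) == ncol(matrix))
  if (length(unique(strain)) < 2L) {
    stop("factor dominance requires at least two strains", call. = FALSE)
  }
  if (length(unique(diet)) < 2L) stop("both diets must be present", call. = FALSE)
  n <- ncol(matrix)
  strain_f <- factor(strain)
  diet_f <- factor(diet)
  rss <- function(design) {
    qrd <- qr(design)
    colSums(qr.resid(qrd, t(matrix))^2)
  }
  x_full <- stats::model.matrix(~ strain_f + diet_f)
  x_nodiet <- stats::model.matrix(~strain_f)
  x_nostrain <- stats::model.matrix(~diet_f)
  rss_full <- rss(x_full)
  lrt_diet <- n * log(rss(x_nodiet) / rss_full)
  lrt_strain <- n * log(rss(x_nostrain) / rss_full)
  df_diet <- nlevels(diet_f) - 1L
  df_strain <- nlevels(strain_f) - 1L
  log10p_diet <- -stats::pchisq(lrt_diet, df_diet, lower.tail = FALSE, log.p = TRUE) / log(10)
  log10p_strain <- -stats::pchisq(lrt_strain, df_strain, lower.tail = FALSE, log.p = TRUE) / log(10)
  dominant <- ifelse(log10p_strain >= log10p_diet, "strain", "diet")
  per_gene <- data.frame(
    gene = rownames(matrix),
    log10p_diet = unname(log10p_diet),
    log10p_strain = unname(log10p_strain),
    dominant_factor = dominant,
    stringsAsFactors = FALSE
  )
  pct_strain <- 100 * mean(dominant == "strain")
  list(
    per_gene = per_gene,
    summary = data.frame(
      factor = c("strain", "diet"),
      percent_dominant = c(pct_strain, 100 - pct_strain)
    )
  )
}

#' Principal-component CR response vectors per strain
#'
#' Samples are projected onto the first two principal components of the
#' gene-centered expression matrix (covariance PCA, no gene standardization;
#' each PC's loadings are sign-fixed to sum positive). Each strain's arrow
#' begins at the bivariate mean of its control samples and ends at the
#' bivariate mean of its CR samples.
#'
#' @param matrix genes x samples log2 matrix (one tissue).
#' @param strain,diet character vectors per sample.
#' @param cr_label label identifying CR samples.
#' @return list with `vectors` (strain, x0, y0, x1, y1, length, angle),
#'   `scores` (samples x 2), `loadings`, and `explained_variance`
#'   (fractions for all components).
#' @export
pc_response_vectors <- function(matrix, strain, diet, cr_label = "CR") {
  stopifnot(length(strain) == ncol(matrix), length(diet) == ncol(matrix))
  if (ncol(matrix) < 2L) stop("at least two samples are required", call. = FALSE)
  pca <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  flip <- ifelse(colSums(pca$rotation[, 1:2, drop = FALSE]) < 0, -1, 1)
  scores <- sweep(pca$x[, 1:2, drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pca$rotation[, 1:2, drop = FALSE], 2, flip, `*`)
  strains <- unique(strain)
  vec <- do.call(rbind, lapply(strains, function(s) {
    ctl <- scores[strain == s & diet != cr_label, , drop = FALSE]
    cr <- scores[strain == s & diet == cr_label, , drop = FALSE]
    start <- colMeans(ctl)
    end <- colMeans(cr)
    data.frame(
      strain = s, x0 = start[1], y0 = start[2], x1 = end[1], y1 = end[2],
      length = sqrt(sum((end - start)^2)),
      angle = atan2(end[2] - start[2], end[1] - start[1]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(vec) <- NULL
  list(
    vectors = vec,
    scores = scores,
    loadings = loadings,
    explained_variance = pca$sdev^2 / sum(pca$sdev^2)
  )
}

#' Spearman correlation matrix of fold-change estimates across strains
#'
#' @param fit_tables named list of `GeneFitTable`s (one per strain).
#' @param gene_universe optional character vector restricting the genes used;
#'   by default the union of genes across tables, with each pairwise
#'   correlation computed on the pair's complete cases.
#' @return symmetric strains x strains Spearman correlation matrix; entries
#'   with fewer than 3 complete pairs are NA.
#' @export
fc_correlation_matrix <- function(fit_tables, gene_universe = NULL) {
  stopifnot(is.list(fit_tables), length(fit_tables) >= 2L, !is.null(names(fit_tables)))
  genes <- gene_universe %||% Reduce(union, lapply(fit_tables, `[[`, "gene"))
  if (length(genes) < 3L) stop("fewer than 3 genes in the shared universe", call. = FALSE)
  fc <- sapply(fit_tables, function(tb) tb$log2fc[match(genes, tb$gene)])
  rownames(fc) <- genes
  rho <- stats::cor(fc, method = "spearman", use = "pairwise.complete.obs")
  # blank out entries supported by fewer than 3 complete pairs
  n_pairs <- crossprod(!is.na(fc))
  rho[n_pairs < 3L] <- NA_real_
  diag(rho) <- 1
  rho
}

#' Hierarchical clustering of strains from a correlation matrix
#'
#' Agglomerative average-linkage clustering with distance `1 - rho`.
#'
#' @param correlation_matrix symmetric correlation matrix with dimnames.
#' @return list with `hclust` (the merge tree) and `newick` (Newick string
#'   with merge heights as branch lengths).
#' @export
strain_cluster <- function(correlation_matrix) {
  stopifnot(is.matrix(correlation_matrix))
  if (!isSymmetric(unname(correlation_matrix), tol = 1e-8)) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  d <- stats::as.dist(1 - correlation_matrix)
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)))
}
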