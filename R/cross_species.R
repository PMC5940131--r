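# Ortholog-mapped comparison of mouse CR fold-changes against human
# experiment fold-changes and the human meta-signature: Spearman correlation
# grids, top-N cumulative-overlap enrichment with a permutation p-value, and
# directional median fold-change tests.

#' Join mouse and human fold-change tables through an ortholog map
#'
#' @param mouse_fit `GeneFitTable` with mouse gene symbols.
#' @param human_table data frame with columns `gene` (human symbols) and a
#'   log2 fold-change column named `log2fc` or `meta_log2fc`.
#' @param map data frame with columns mouse_symbol, human_symbol; must be
#'   one-to-one (no duplicated symbol on either side).
#' @return data frame with mouse_symbol, human_symbol, mouse_log2fc,
#'   mouse_fc, human_log2fc, human_fc; attribute `n_unmapped` counts mouse
#'   genes dropped by the join.
#' @export
map_orthologs <- function(mouse_fit, human_table, map) {
  stopifnot(
    is.data.frame(map),
    all(c("mouse_symbol", "human_symbol") %in% names(map))
  )
  if (anyDuplicated(map$mouse_symbol) || anyDuplicated(map$human_symbol)) {
    stop("ortholog map must be one-to-one (duplicate symbols found)", call. = FALSE)
  }
  hcol <- intersect(c("log2fc", "meta_log2fc"), names(human_table))[1]
  if (is.na(hcol)) stop("human table needs a log2fc or meta_log2fc column", call. = FALSE)
  m <- merge(
    data.frame(
      mouse_symbol = mouse_fit$gene, mouse_log2fc = mouse_fit$log2fc,
      stringsAsFactors = FALSE
    ),
    map,
    by = "mouse_symbol"
  )
  out <- merge(
    m,
    data.frame(
      human_symbol = human_table$gene, human_log2fc = human_table[[hcol]],
      stringsAsFactors = FALSE
    ),
    by = "human_symbol"
  )
  out <- out[order(out$mouse_symbol), c(
    "mouse_symbol", "human_symbol",
    "mouse_log2fc", "human_log2fc"
  )]
  out$mouse_fc <- 2^out$mouse_log2fc
  out$human_fc <- 2^out$human_log2fc
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no orthologous genes in common", call. = FALSE)
  attr(out, "n_unmapped") <- nrow(mouse_fit) - nrow(out)
  out
}

#' Mouse-strain by human-experiment Spearman correlation grid
#'
#' For every (strain, experiment) cell, the Spearman rank correlation of
#' log2 fold-changes over the orthologous genes present in both tables.
#'
#' @param mouse_fits named list of per-strain `GeneFitTable`s.
#' @param human_tables named list of per-experiment data frames with `gene`
#'   and `log2fc` columns (human symbols).
#' @param map one-to-one ortholog map (see [map_orthologs()]).
#' @param meta optional `MetaSignature`; adds a per-strain correlation with
#'   the meta-signature average response.
#' @return object of class `ConcordanceGrid`: list with `rho` (strains x
#'   experiments matrix; cells with fewer than 3 joined genes are NA),
#'   `per_strain` (median and middle-50% interval of each strain's row),
#'   and optionally `meta_rho`.
#' @export
species_correlations <- function(mouse_fits, human_tables, map, meta = NULL) {
  stopifnot(
    is.list(mouse_fits), !is.null(names(mouse_fits)),
    is.list(human_tables), !is.null(names(human_tables))
  )
  rho <- matrix(NA_real_, length(mouse_fits), length(human_tables),
    dimnames = list(names(mouse_fits), names(human_tables))
  )
  for (s in names(mouse_fits)) {
    for (e in names(human_tables)) {
      joined <- map_orthologs(mouse_fits[[s]], human_tables[[e]], map)
      if (nrow(joined) >= 3L) {
        rho[s, e] <- stats::cor(joined$mouse_log2fc, joined$human_log2fc,
          method = "spearman"
        )
      }
    }
  }
  per_strain <- data.frame(
    strain = rownames(rho),
    median = apply(rho, 1, stats::median, na.rm = TRUE),
    q25 = apply(rho, 1, stats::quantile, 0.25, na.rm = TRUE),
    q75 = apply(rho, 1, stats::quantile, 0.75, na.rm = TRUE),
    mean = rowMeans(rho, na.rm = TRUE),
    row.names = NULL
  )
  out <- list(rho = rho, per_strain = per_strain)
  if (!is.null(meta)) {
    out$meta_rho <- vapply(mouse_fits, function(fit) {
      joined <- map_orthologs(fit, meta, map)
      if (nrow(joined) < 3L) {
        return(NA_real_)
      }
      stats::cor(joined$mouse_log2fc, joined$human_log2fc, method = "spearman")
    }, numeric(1))
  }
  class(out) <- "ConcordanceGrid"
  out
}

#' @export
print.ConcordanceGrid <- function(x, ...) {
  cat(sprintf(
    "ConcordanceGrid: %d strains x %d experiments (grand mean rho = %.3f)\n",
    nrow(x$rho), ncol(x$rho), mean(x$rho, na.rm = TRUE)
  ))
  invisible(x)
}

#' Top-n genes of a fit table by fold-change
#'
#' @param fit a `GeneFitTable`.
#' @param n number of genes (default 100).
#' @param direction "up" (largest log2fc first) or "down" (smallest first).
#' @return character vector of gene symbols; ties broken by smaller p then
#'   lexicographic symbol. If fewer than `n` genes are available all are
#'   returned with a warning.
#' @export
top_n_genes <- function(fit, n = 100L, direction = c("up", "down")) {
  direction <- match.arg(direction)
  n <- assert_count(n, "n")
  key <- if (direction == "up") -fit$log2fc else fit$log2fc
  ord <- order(key, fit$p, fit$gene)
  if (nrow(fit) < n) {
    warning("fewer than ", n, " genes available; returning all", call. = FALSE)
    n <- nrow(fit)
  }
  fit$gene[ord][seq_len(n)]
}

# Signed supremum-deviation statistic of the cumulative overlap curve.
overlap_statistic <- function(in_set, m, H) {
  o <- cumsum(in_set)
  e <- m * seq_len(H) / H
  dev <- o - e
  (max(dev) - max(-dev)) / m
}

#' Cumulative-overlap gene-set enrichment with a permutation p-value
#'
#' Genes are ranked (most CR-increased in human first) and the running
#' overlap `O(i)` of the query set with the top-i genes is compared against
#' the uniform expectation `E(i) = m i / H`. The statistic is the signed,
#' set-size-normalized supremum deviation `(D+ - D-)/m` where
#' `D+ = max(O - E)` and `D- = max(E - O)`: positive values indicate
#' concentration of the set among CR-increased genes, negative among
#' CR-decreased genes. The p-value is a two-sided permutation tail over `B`
#' random same-size sets: `(1 + #{|stat*| >= |stat|}) / (B + 1)`.
#'
#' This running-overlap statistic is a package-defined Kolmogorov-style
#' definition; outputs label it accordingly.
#'
#' @param ranking character vector of the full gene universe, ordered by
#'   decreasing meta fold-change.
#' @param gene_set character vector, subset of `ranking`, size >= 5.
#' @param B number of random sets (default 10000).
#' @param seed integer seed.
#' @return list with statistic, p, d_plus, d_minus, m, universe_size, B.
#' @export
cumulative_overlap_gsea <- function(ranking, gene_set, B = 10000L, seed) {
  stopifnot(is.character(ranking), is.character(gene_set))
  if (anyDuplicated(ranking)) stop("ranking must not contain duplicates", call. = FALSE)
  missing <- setdiff(gene_set, ranking)
  if (length(missing)) {
    stop(
      "gene set members absent from ranking: ",
      paste(utils::head(missing, 5), collapse = ", "), call. = FALSE
    )
  }
  m <- length(unique(gene_set))
  if (m < 5L) stop("gene set must contain at least 5 genes", call. = FALSE)
  B <- assert_count(B, "B", min = 10L)
  seed <- assert_count(seed, "seed", min = 0L)
  H <- length(ranking)
  in_set <- ranking %in% gene_set
  o <- cumsum(in_set)
  e <- m * seq_len(H) / H
  dev <- o - e
  d_plus <- max(dev)
  d_minus <- max(-dev)
  stat <- (d_plus - d_minus) / m
  set.seed(seed)
  null_stats <- vapply(seq_len(B), function(b) {
    idx <- logical(H)
    idx[sample.int(H, m)] <- TRUE
    overlap_statistic(idx, m, H)
  }, numeric(1))
  p <- (1 + sum(abs(null_stats) >= abs(stat))) / (B + 1)
  list(
    statistic = stat, p = p, d_plus = d_plus, d_minus = d_minus,
    m = m, universe_size = H, B = B
  )
}

#' Median fold-change test against no change
#'
#' Two-sided one-sample signed-rank test of the log2 fold-changes against
#' zero, i.e. of the hypothesis that the median linear fold-change is 1.00.
#'
#' @param human_fcs numeric vector of positive linear fold-changes (>= 5).
#' @return list with median_fc, q25, q75, p, n; all fold-changes equal to 1
#'   give p = 1 and `degenerate = TRUE`.
#' @export
median_fc_test <- function(human_fcs) {
  stopifnot(is.numeric(human_fcs), all(human_fcs > 0))
  if (length(human_fcs) < 5L) stop("at least 5 fold-changes are required", call. = FALSE)
  l <- log2(human_fcs)
  res <- signed_rank_test(l, alternative = "two.sided")
  list(
    median_fc = stats::median(human_fcs),
    q25 = stats::quantile(human_fcs, 0.25, names = FALSE),
    q75 = stats::quantile(human_fcs, 0.75, names = FALSE),
    p = res$p.value,
    n = length(human_fcs),
    degenerate = res$n == 0L
  )
}
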