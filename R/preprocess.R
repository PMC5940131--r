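# Detection calling, probe collapsing, expression filtering and QC exclusion.
# These stages consume RMA-style gene- or probe-level log2 intensities; raw
# array normalization and probe-level QC are upstream of this package and QC
# flags arrive as sample metadata.

#' Construct an ExpressionStudy
#'
#' A log2 gene-by-sample expression matrix with per-sample metadata and an
#' optional per-gene detection matrix.
#'
#' @param matrix numeric genes x samples matrix, log2 scale, with unique
#'   rownames (gene symbols) and colnames matching `sample_meta$sample_id`.
#' @param sample_meta data frame with columns sample_id, strain, diet,
#'   tissue, qc_flag (one row per sample, same order as matrix columns).
#' @param detection optional logical genes x samples matrix.
#' @param seed optional seed recorded from the generating simulation.
#' @return object of class `ExpressionStudy`.
#' @export
expression_study <- function(matrix, sample_meta, detection = NULL, seed = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix), is.data.frame(sample_meta))
  req <- c("sample_id", "strain", "diet", "tissue", "qc_flag")
  if (!all(req %in% names(sample_meta))) {
    stop(
      "`sample_meta` must contain columns: ",
      paste(setdiff(req, names(sample_meta)), collapse = ", "), call. = FALSE
    )
  }
  if (ncol(matrix) != nrow(sample_meta) ||
    !identical(colnames(matrix), sample_meta$sample_id)) {
    stop("matrix columns must match sample_meta$sample_id one-to-one", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    stop("matrix must have unique gene rownames", call. = FALSE)
  }
  if (anyNA(matrix)) stop("expression matrix must not contain missing values", call. = FALSE)
  if (!is.null(detection)) {
    stopifnot(
      is.matrix(detection), is.logical(detection),
      identical(dim(detection), dim(matrix))
    )
  }
  structure(
    list(
      matrix = matrix, sample_meta = sample_meta,
      detection = detection, seed = seed
    ),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf(
    "ExpressionStudy: %d genes x %d samples (%d strains, %d tissues, diets: %s)\n",
    nrow(x$matrix), ncol(x$matrix),
    length(unique(x$sample_meta$strain)),
    length(unique(x$sample_meta$tissue)),
    paste(unique(x$sample_meta$diet), collapse = "/")
  ))
  invisible(x)
}

#' Subset an ExpressionStudy by samples
#'
#' @param study an `ExpressionStudy`.
#' @param samples logical or character index of samples to keep.
#' @return the subsetted `ExpressionStudy`.
#' @export
subset_study <- function(study, samples) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (is.character(samples)) samples <- match(samples, study$sample_meta$sample_id)
  expression_study(
    study$matrix[, samples, drop = FALSE],
    study$sample_meta[samples, , drop = FALSE],
    detection = if (!is.null(study$detection)) study$detection[, samples, drop = FALSE],
    seed = study$seed
  )
}

#' Above-background detection call for one probe set
#'
#' One-sided Wilcoxon signed-rank test that perfect-match (PM) intensities
#' exceed mismatch (MM) intensities. Zero PM-MM differences are dropped; if
#' all differences are zero the probe set is undetected (p = 1). The exact
#' null distribution is used for up to 25 pairs, a continuity-corrected
#' normal approximation above.
#'
#' @param pm,mm positive numeric vectors of equal length >= 5.
#' @return one-sided p-value in (0, 1].
#' @examples
#' detection_call(pm = 2^(6 + 1:11 / 10), mm = rep(2^6, 11)) # 2^-11
#' @export
detection_call <- function(pm, mm) {
  stopifnot(is.numeric(pm), is.numeric(mm))
  if (length(pm) != length(mm)) stop("`pm` and `mm` must have equal length", call. = FALSE)
  if (length(pm) < 5L) stop("at least 5 probe pairs are required", call. = FALSE)
  if (any(pm <= 0) || any(mm <= 0)) stop("intensities must be positive", call. = FALSE)
  signed_rank_test(pm - mm, alternative = "greater")$p.value
}

#' Per-sample gene detectability from probe-set p-values
#'
#' A gene is detectable in a sample when at least 50% of its probe sets are
#' called above background at p < 0.05.
#'
#' @param probeset_pvalues numeric vector of detection p-values.
#' @return logical.
#' @export
gene_detectable <- function(probeset_pvalues) {
  stopifnot(is.numeric(probeset_pvalues), length(probeset_pvalues) >= 1L)
  mean(probeset_pvalues < 0.05) >= 0.5
}

#' Expression filter for a CR-vs-control comparison
#'
#' Retains genes detectable in at least one third (exact fraction 1/3) of the
#' samples entering a given comparison.
#'
#' @param detection logical genes x samples matrix.
#' @param comparison_samples character or integer index of the samples in the
#'   comparison.
#' @param min_fraction required detectable fraction (default 1/3).
#' @return character vector of retained gene names.
#' @export
expression_filter <- function(detection, comparison_samples, min_fraction = 1 / 3) {
  stopifnot(is.matrix(detection), is.logical(detection))
  if (nrow(detection) == 0L || ncol(detection) == 0L) {
    stop("detection matrix must be non-empty", call. = FALSE)
  }
  sub <- detection[, comparison_samples, drop = FALSE]
  if (ncol(sub) == 0L) stop("`comparison_samples` must be non-empty", call. = FALSE)
  rownames(detection)[rowMeans(sub) >= min_fraction]
}

#' Collapse probes to genes by highest average expression
#'
#' When several probes map to one gene, the probe with the highest mean
#' intensity across all samples represents the gene; ties are broken toward
#' the lexicographically smallest probe identifier.
#'
#' @param probe_matrix numeric probes x samples matrix with probe rownames.
#' @param probe_map data frame with columns probe_id, gene_symbol covering
#'   every probe in `probe_matrix`.
#' @return gene-level matrix (rownames are gene symbols) with attribute
#'   `representative_probe`.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  stopifnot(
    is.matrix(probe_matrix), !is.null(rownames(probe_matrix)),
    is.data.frame(probe_map),
    all(c("probe_id", "gene_symbol") %in% names(probe_map))
  )
  unmapped <- setdiff(rownames(probe_matrix), probe_map$probe_id)
  if (length(unmapped)) {
    stop(
      "unmapped probes: ", paste(utils::head(unmapped, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(probe_map$probe_id)) {
    stop("each probe must map to exactly one gene", call. = FALSE)
  }
  map <- probe_map[match(rownames(probe_matrix), probe_map$probe_id), ]
  avg <- rowMeans(probe_matrix)
  ord <- order(map$gene_symbol, -avg, map$probe_id)
  keep <- ord[!duplicated(map$gene_symbol[ord])]
  out <- probe_matrix[keep, , drop = FALSE]
  reps <- rownames(out)
  rownames(out) <- map$gene_symbol[keep]
  if (anyDuplicated(rownames(out))) {
    stop("collapsing produced duplicate gene symbols", call. = FALSE)
  }
  attr(out, "representative_probe") <- stats::setNames(reps, rownames(out))
  out
}

#' Remove QC-flagged samples from a study
#'
#' Drops samples whose `qc_flag` is `"fail"` from the matrix, metadata and
#' detection matrix. Additional sample IDs to exclude can be supplied in
#' `flag_ids`; IDs absent from the study are an error.
#'
#' @param study an `ExpressionStudy`.
#' @param flag_ids optional character vector of extra sample IDs to flag.
#' @return the filtered `ExpressionStudy` with attribute `n_removed`.
#' @export
exclude_flagged_samples <- function(study, flag_ids = NULL) {
  stopifnot(inherits(study, "ExpressionStudy"))
  fail <- study$sample_meta$qc_flag == "fail"
  if (!is.null(flag_ids)) {
    unknown <- setdiff(flag_ids, study$sample_meta$sample_id)
    if (length(unknown)) {
      stop(
        "flagged sample IDs not present in study: ",
        paste(unknown, collapse = ", "), call. = FALSE
      )
    }
    fail <- fail | study$sample_meta$sample_id %in% flag_ids
  }
  if (all(fail)) stop("all samples are QC-flagged; nothing to analyze", call. = FALSE)
  out <- subset_study(study, !fail)
  attr(out, "n_removed") <- sum(fail)
  out
}
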