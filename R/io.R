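# Plain TSV readers and writers for the package's containers. All tables are
# tab-separated with a header row; expression matrices carry gene symbols in
# the first column.

write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an ExpressionStudy as TSV files
#'
#' Writes `<prefix>_matrix.tsv` (first column `gene`, one column per sample)
#' and `<prefix>_samples.tsv` (sample metadata).
#'
#' @param study an `ExpressionStudy`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_expression_study <- function(study, prefix) {
  stopifnot(inherits(study, "ExpressionStudy"))
  mat_path <- paste0(prefix, "_matrix.tsv")
  meta_path <- paste0(prefix, "_samples.tsv")
  df <- data.frame(gene = rownames(study$matrix), study$matrix, check.names = FALSE)
  write_tsv(df, mat_path)
  write_tsv(study$sample_meta, meta_path)
  invisible(c(matrix = mat_path, samples = meta_path))
}

#' Read an ExpressionStudy from TSV files
#'
#' @param prefix path prefix used by [write_expression_study()].
#' @return an `ExpressionStudy`.
#' @export
read_expression_study <- function(prefix) {
  df <- read_tsv(paste0(prefix, "_matrix.tsv"))
  meta <- read_tsv(paste0(prefix, "_samples.tsv"))
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  expression_study(mat, meta)
}

#' Write a gene fit table, truth table, or other result table as TSV
#'
#' @param table a data frame result (e.g. `GeneFitTable`, `MetaSignature`).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_result_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}

#' Read an ortholog map TSV
#'
#' @param path TSV with columns mouse_symbol, human_symbol.
#' @return validated one-to-one map data frame.
#' @export
read_ortholog_map <- function(path) {
  map <- read_tsv(path)
  if (!all(c("mouse_symbol", "human_symbol") %in% names(map))) {
    stop("ortholog map must have columns mouse_symbol, human_symbol", call. = FALSE)
  }
  if (anyDuplicated(map$mouse_symbol) || anyDuplicated(map$human_symbol)) {
    stop("ortholog map must be one-to-one", call. = FALSE)
  }
  map
}

#' Write paired human experiments as per-experiment TSV pairs plus manifest
#'
#' Each experiment produces `<dir>/<id>_baseline.tsv` and
#' `<dir>/<id>_post.tsv`; the manifest (`<dir>/manifest.tsv`) records
#' experiment_id, baseline_set_id, n_subjects, sex, duration_weeks.
#'
#' @param experiments list of `PairedExperiment`s.
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_paired_experiments <- function(experiments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in experiments) {
    for (part in c("baseline", "post")) {
      df <- data.frame(gene = rownames(e[[part]]), e[[part]], check.names = FALSE)
      write_tsv(df, file.path(dir, sprintf("%s_%s.tsv", e$experiment_id, part)))
    }
  }
  manifest <- data.frame(
    experiment_id = vapply(experiments, `[[`, "", "experiment_id"),
    baseline_set_id = vapply(experiments, function(e) as.character(e$baseline_set_id), ""),
    n_subjects = vapply(experiments, `[[`, 0L, "n_subjects"),
    sex = vapply(experiments, `[[`, "", "sex"),
    duration_weeks = vapply(experiments, function(e) as.numeric(e$duration_weeks), numeric(1))
  )
  path <- file.path(dir, "manifest.tsv")
  write_tsv(manifest, path)
  invisible(path)
}

#' Read paired human experiments written by [write_paired_experiments()]
#'
#' @param dir directory containing the per-experiment TSVs and manifest.
#' @return list of `PairedExperiment`s.
#' @export
read_paired_experiments <- function(dir) {
  manifest <- read_tsv(file.path(dir, "manifest.tsv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$experiment_id[i]
    read_part <- function(part) {
      df <- read_tsv(file.path(dir, sprintf("%s_%s.tsv", id, part)))
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df$gene
      m
    }
    paired_experiment(
      experiment_id = id,
      baseline = read_part("baseline"),
      post = read_part("post"),
      baseline_set_id = manifest$baseline_set_id[i],
      sex = manifest$sex[i],
      duration_weeks = manifest$duration_weeks[i]
    )
  })
}
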