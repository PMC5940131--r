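# End-to-end orchestration: simulate (or load) a multi-strain mouse study and
# paired human experiments, run preprocessing, differential expression,
# interaction scans, global structure, shared-response, human meta-analysis
# and cross-species concordance, and write TSV/JSON outputs plus a run
# manifest. Reruns with an identical configuration reproduce identical
# outputs.

#' Default pipeline configuration
#'
#' Thresholds follow the package's differential-expression conventions
#' (FDR < 0.10 with linear FC > 1.50 or < 0.67; interaction scans also
#' reported at FDR < 0.15; shared-response nominal alpha 0.05). Simulation
#' sizes default to desk scale.
#'
#' @param seed integer seed for all stochastic stages.
#' @param out_dir output directory.
#' @param n_genes simulated gene count.
#' @param replicates_per_cell mice per strain-tissue-diet cell.
#' @param tissues tissue labels to simulate and analyze.
#' @param n_qc_fail samples to flag as QC failures in the simulation.
#' @param alpha nominal per-strain p-value threshold (shared responses).
#' @param q_max,fc_up,fc_down DEG thresholds.
#' @param q_interaction interaction-scan FDR thresholds reported.
#' @param shared_B shared-response permutation count.
#' @param gsea_B enrichment permutation count.
#' @param min_experiments meta-analysis gene-inclusion minimum.
#' @return named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("strainCR_run_"),
                            n_genes = 1000L,
                            replicates_per_cell = 8L,
                            tissues = c("eWAT", "muscle", "heart", "cortex"),
                            n_qc_fail = 12L,
                            alpha = 0.05,
                            q_max = 0.10,
                            fc_up = 1.50,
                            fc_down = 0.67,
                            q_interaction = c(0.10, 0.15),
                            shared_B = 200L,
                            gsea_B = 500L,
                            min_experiments = 6L) {
  cfg <- list(
    seed = assert_count(seed, "seed", min = 0L),
    out_dir = out_dir,
    n_genes = assert_count(n_genes, "n_genes"),
    replicates_per_cell = assert_count(replicates_per_cell, "replicates_per_cell"),
    tissues = tissues,
    n_qc_fail = assert_count(n_qc_fail, "n_qc_fail", min = 0L),
    alpha = assert_probability(alpha, "alpha"),
    q_max = assert_probability(q_max, "q_max"),
    fc_up = assert_scalar_number(fc_up, "fc_up", lower = 1),
    fc_down = assert_scalar_number(fc_down, "fc_down", lower = 0, upper = 1),
    q_interaction = q_interaction,
    shared_B = assert_count(shared_B, "shared_B", min = 100L),
    gsea_B = assert_count(gsea_B, "gsea_B", min = 10L),
    min_experiments = assert_count(min_experiments, "min_experiments")
  )
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are an error; omitted keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full strain-resolved CR analysis pipeline
#'
#' Simulates a multi-strain mouse study and paired human experiments, then
#' executes preprocessing (QC exclusion), per-strain CR contrasts and DEG
#' calls per tissue, strain-by-diet interaction scans, factor dominance, PC
#' response vectors, fold-change correlation and strain clustering,
#' cross-strain shared-response permutation tests, the human meta-signature,
#' and mouse-human concordance for the first tissue. All tables are written
#' as TSV under `config$out_dir` together with `manifest.json` (config,
#' seed, package version, per-stage counts). Outputs contain no timestamps;
#' rerunning with an identical configuration reproduces identical files.
#'
#' @param config a `PipelineConfig` (or YAML path accepted by
#'   [read_pipeline_config()]).
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))

  design <- study_design(
    tissues = config$tissues,
    replicates_per_cell = config$replicates_per_cell,
    n_genes = config$n_genes
  )
  effects <- mouse_effect_model()
  sim <- simulate_mouse_study(design, effects, seed = config$seed, n_qc_fail = config$n_qc_fail)
  log_msg("simulate: %d genes x %d samples", nrow(sim$study$matrix), ncol(sim$study$matrix))
  write_expression_study(sim$study, file.path(out_dir, "mouse"))
  write_result_table(sim$truth, file.path(out_dir, "truth.tsv"))

  study <- exclude_flagged_samples(sim$study)
  n_removed <- attr(study, "n_removed")
  log_msg("preprocess: removed %d QC-flagged samples (%d retained)", n_removed, ncol(study$matrix))

  strains <- design$strains
  meta <- study$sample_meta
  counts <- list()
  fits_by_tissue <- list()
  for (tis in config$tissues) {
    fits <- list()
    for (s in strains) {
      sel <- meta$tissue == tis & meta$strain == s
      fits[[s]] <- cr_contrast_fit(study$matrix[, sel, drop = FALSE], meta$diet[sel])
      write_result_table(
        fits[[s]],
        file.path(out_dir, sprintf("de_%s_%s.tsv", tis, s))
      )
    }
    fits_by_tissue[[tis]] <- fits
    degs <- lapply(fits, call_degs,
      q_max = config$q_max, fc_up = config$fc_up,
      fc_down = config$fc_down
    )
    counts[[paste0("degs_", tis)]] <- vapply(degs, nrow, integer(1))

    sel_t <- meta$tissue == tis
    dom <- factor_dominance(study$matrix[, sel_t, drop = FALSE], meta$strain[sel_t], meta$diet[sel_t])
    write_result_table(dom$per_gene, file.path(out_dir, sprintf("dominance_%s.tsv", tis)))
    write_result_table(dom$summary, file.path(out_dir, sprintf("dominance_summary_%s.tsv", tis)))

    pcv <- pc_response_vectors(study$matrix[, sel_t, drop = FALSE], meta$strain[sel_t], meta$diet[sel_t])
    write_result_table(pcv$vectors, file.path(out_dir, sprintf("pc_vectors_%s.tsv", tis)))

    rho <- fc_correlation_matrix(fits)
    write_result_table(
      data.frame(strain = rownames(rho), rho, check.names = FALSE),
      file.path(out_dir, sprintf("fc_correlation_%s.tsv", tis))
    )
    cl <- strain_cluster(rho)
    writeLines(cl$newick, file.path(out_dir, sprintf("strain_cluster_%s.nwk", tis)))

    shr <- shared_null(fits,
      alpha = config$alpha, B = config$shared_B,
      seed = config$seed + match(tis, config$tissues)
    )
    write_result_table(shr, file.path(out_dir, sprintf("shared_%s.tsv", tis)))

    inter <- interaction_scan(
      study$matrix[, sel_t, drop = FALSE],
      meta$strain[sel_t], meta$diet[sel_t],
      focal_strain = strains[1]
    )
    write_result_table(inter, file.path(out_dir, sprintf("interaction_%s_%s.tsv", tis, strains[1])))
    counts[[paste0("interaction_", tis)]] <- vapply(
      config$q_interaction,
      function(q) sum(inter$fdr < q, na.rm = TRUE), integer(1)
    )
    log_msg("tissue %s: DE, dominance, vectors, shared-response, interaction done", tis)
  }

  hsim <- simulate_human_experiments(human_meta_config(), sim$truth, seed = config$seed + 100L)
  write_paired_experiments(hsim$experiments, file.path(out_dir, "human"))
  msig <- meta_signature(hsim$experiments, min_experiments = config$min_experiments)
  write_result_table(msig, file.path(out_dir, "meta_signature.tsv"))
  log_msg(
    "human meta: %d/%d experiments retained, %d genes",
    nrow(attr(msig, "retained_experiments")), length(hsim$experiments), nrow(msig)
  )

  map <- data.frame(
    mouse_symbol = sim$truth$gene,
    human_symbol = toupper(sim$truth$gene),
    stringsAsFactors = FALSE
  )
  write_result_table(map, file.path(out_dir, "ortholog_map.tsv"))
  human_tables <- lapply(hsim$experiments, function(e) {
    keep <- low_expression_filter(e)
    s <- experiment_summary(paired_log2_differences(e)[keep, , drop = FALSE])
    data.frame(gene = s$gene, log2fc = s$mean, stringsAsFactors = FALSE)
  })
  names(human_tables) <- vapply(hsim$experiments, `[[`, "", "experiment_id")
  tissue1 <- config$tissues[1]
  grid <- species_correlations(fits_by_tissue[[tissue1]], human_tables, map, meta = msig)
  write_result_table(
    data.frame(strain = rownames(grid$rho), grid$rho, check.names = FALSE),
    file.path(out_dir, "species_correlations.tsv")
  )
  write_result_table(grid$per_strain, file.path(out_dir, "species_correlations_by_strain.tsv"))

  ranking_tab <- msig[order(-msig$meta_log2fc, msig$p, msig$gene), ]
  ranking <- ranking_tab$gene
  gsea <- lapply(fits_by_tissue[[tissue1]], function(fit) {
    top_up <- top_n_genes(fit, n = min(100L, nrow(fit)), direction = "up")
    set <- map$human_symbol[match(top_up, map$mouse_symbol)]
    set <- intersect(set, ranking)
    if (length(set) < 5L) {
      return(list(statistic = NA_real_, p = NA_real_))
    }
    cumulative_overlap_gsea(ranking, set, B = config$gsea_B, seed = config$seed + 200L)
  })
  write_result_table(
    data.frame(
      strain = names(gsea),
      statistic = vapply(gsea, `[[`, numeric(1), "statistic"),
      p = vapply(gsea, `[[`, numeric(1), "p"),
      statistic_definition = "signed supremum deviation of cumulative overlap (package definition)"
    ),
    file.path(out_dir, "gsea_top100_up.tsv")
  )
  log_msg("cross-species: correlation grid and enrichment done")

  cfg_plain <- unclass(config)
  cfg_plain$out_dir <- NULL # location is not part of the scientific configuration
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg_plain, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("strainCR")),
    config = cfg_plain,
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    n_samples_simulated = ncol(sim$study$matrix),
    n_samples_removed_qc = n_removed,
    n_samples_analyzed = ncol(study$matrix),
    n_genes = nrow(study$matrix),
    n_human_experiments = length(hsim$experiments),
    n_independent_experiments = nrow(attr(msig, "retained_experiments")),
    n_meta_genes = nrow(msig),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}
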