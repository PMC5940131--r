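# Synthetic-data generators with planted ground truth. The mouse generator
# emulates a full-factorial multi-strain CR feeding study (strains x tissues x
# diets x replicates on a log2 expression scale); the human generator emulates
# a collection of paired before/after weight-loss experiments, some of which
# share baseline sample sets and are therefore statistically dependent.

#' Study design for a full-factorial mouse CR experiment
#'
#' Defaults describe the multi-strain design analyzed by the package: 7
#' strains, 4 tissues, 2 diets (ad libitum control vs caloric restriction)
#' and 8 replicate mice per strain-tissue-diet cell, i.e. 448 samples.
#'
#' @param strains character vector of unique strain labels.
#' @param tissues character vector of unique tissue labels.
#' @param diets length-2 character vector, control first then CR.
#' @param replicates_per_cell mice per strain-tissue-diet cell.
#' @param n_genes number of simulated genes.
#' @return object of class `StudyDesign`.
#' @examples
#' d <- study_design()
#' d$n_samples # 448
#' @export
study_design <- function(strains = c("B6", "BALB", "C3H", "129", "CBA", "DBA", "F1"),
                         tissues = c("eWAT", "muscle", "heart", "cortex"),
                         diets = c("CTL", "CR"),
                         replicates_per_cell = 8L,
                         n_genes = 2000L) {
  stopifnot(is.character(strains), is.character(tissues), is.character(diets))
  if (anyDuplicated(c(strains, tissues, diets))) {
    stop("strain, tissue and diet labels must all be unique", call. = FALSE)
  }
  if (length(diets) != 2L) stop("`diets` must have exactly two labels", call. = FALSE)
  replicates_per_cell <- assert_count(replicates_per_cell, "replicates_per_cell")
  n_genes <- assert_count(n_genes, "n_genes")
  out <- list(
    strains = strains, tissues = tissues, diets = diets,
    replicates_per_cell = replicates_per_cell, n_genes = n_genes,
    n_samples = length(strains) * length(tissues) * 2L * replicates_per_cell
  )
  class(out) <- "StudyDesign"
  out
}

#' Effect model for the mouse generator
#'
#' Planted effects on the log2 scale. A `fraction_shared` of genes receives a
#' CR effect common to all strains; a `fraction_strain_specific` of genes
#' receives a CR effect in a single focal strain only (drawn from
#' `interaction_strains`), which is what a strain-by-diet interaction scan
#' should detect. Every gene receives strain baseline offsets
#' (`strain_offset_sd`) and a gene-specific residual variance drawn from a
#' scaled inverse-chi-square prior with scale `residual_sd^2` and
#' `var_prior_df` degrees of freedom, so empirical-Bayes variance moderation
#' has a correctly specified target.
#'
#' @param shared_effect_sd sd of shared CR effects (log2 units).
#' @param strain_specific_effect_sd sd of strain-specific CR effects.
#' @param fraction_shared proportion of genes with a shared CR effect.
#' @param fraction_strain_specific proportion with a strain-specific effect.
#' @param interaction_strains strains eligible to carry strain-specific
#'   effects; `NULL` means all strains in the design.
#' @param residual_sd prior scale of the per-gene residual sd.
#' @param baseline_mean_sd sd of per-gene baseline means around 7 (log2).
#' @param strain_offset_sd sd of per-gene strain baseline offsets.
#' @param var_prior_df degrees of freedom of the residual-variance prior;
#'   `Inf` gives a constant variance `residual_sd^2`.
#' @return object of class `MouseEffectModel`.
#' @export
mouse_effect_model <- function(shared_effect_sd = 0.5,
                               strain_specific_effect_sd = 0.5,
                               fraction_shared = 0.10,
                               fraction_strain_specific = 0.05,
                               interaction_strains = NULL,
                               residual_sd = 0.5,
                               baseline_mean_sd = 1.5,
                               strain_offset_sd = 0.5,
                               var_prior_df = 4) {
  for (nm in c(
    "shared_effect_sd", "strain_specific_effect_sd", "residual_sd",
    "baseline_mean_sd", "strain_offset_sd"
  )) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  assert_probability(fraction_shared, "fraction_shared")
  assert_probability(fraction_strain_specific, "fraction_strain_specific")
  if (fraction_shared + fraction_strain_specific > 1) {
    stop("fraction_shared + fraction_strain_specific must be <= 1", call. = FALSE)
  }
  if (!(is.infinite(var_prior_df) || var_prior_df > 0)) {
    stop("`var_prior_df` must be positive or Inf", call. = FALSE)
  }
  out <- list(
    shared_effect_sd = shared_effect_sd,
    strain_specific_effect_sd = strain_specific_effect_sd,
    fraction_shared = fraction_shared,
    fraction_strain_specific = fraction_strain_specific,
    interaction_strains = interaction_strains,
    residual_sd = residual_sd,
    baseline_mean_sd = baseline_mean_sd,
    strain_offset_sd = strain_offset_sd,
    var_prior_df = var_prior_df
  )
  class(out) <- "MouseEffectModel"
  out
}

#' Configuration of the simulated human paired-experiment collection
#'
#' Defaults emulate the structure of the analyzed human subcutaneous WAT
#' collection: 28 paired before/after experiments grouped into 18 distinct
#' baseline sample sets, with subject counts drawn log-uniformly on
#' `subjects_range` (geometric mean about 11 subjects).
#'
#' @param n_experiments number of paired experiments.
#' @param subjects_range integer interval for per-experiment subject counts;
#'   lower bound must be at least 2.
#' @param n_baseline_sets number of distinct baseline sample sets
#'   (<= `n_experiments`); each set is shared by all experiments assigned to
#'   it, making those experiments dependent.
#' @param concordance_rho target rank correlation in `[-1, 1]` between true
#'   human effects and the mouse shared CR effects.
#' @param missing_gene_fraction fraction of genes absent per experiment.
#' @param residual_sd per-subject noise sd of paired log2 differences.
#' @param tau2 between-experiment variance of the true per-experiment effect
#'   around the gene-level human effect (log2^2 units).
#' @param human_effect_sd sd to which true human effects are rescaled;
#'   `NULL` (default) inherits the spread of the mouse shared effects, and 0
#'   gives a fully null human collection.
#' @return object of class `HumanMetaConfig`.
#' @export
human_meta_config <- function(n_experiments = 28L,
                              subjects_range = c(3L, 40L),
                              n_baseline_sets = 18L,
                              concordance_rho = -0.3,
                              missing_gene_fraction = 0.2,
                              residual_sd = 0.5,
                              tau2 = 0.05,
                              human_effect_sd = NULL) {
  n_experiments <- assert_count(n_experiments, "n_experiments")
  n_baseline_sets <- assert_count(n_baseline_sets, "n_baseline_sets")
  if (n_baseline_sets > n_experiments) {
    stop("`n_baseline_sets` must not exceed `n_experiments`", call. = FALSE)
  }
  stopifnot(length(subjects_range) == 2L, subjects_range[1] >= 2L,
            subjects_range[2] >= subjects_range[1])
  assert_scalar_number(concordance_rho, "concordance_rho", -1, 1)
  assert_probability(missing_gene_fraction, "missing_gene_fraction")
  assert_scalar_number(residual_sd, "residual_sd", lower = 0)
  assert_scalar_number(tau2, "tau2", lower = 0)
  if (!is.null(human_effect_sd)) {
    assert_scalar_number(human_effect_sd, "human_effect_sd", lower = 0)
  }
  out <- list(
    n_experiments = n_experiments,
    subjects_range = as.integer(subjects_range),
    n_baseline_sets = n_baseline_sets,
    concordance_rho = concordance_rho,
    missing_gene_fraction = missing_gene_fraction,
    residual_sd = residual_sd,
    tau2 = tau2,
    human_effect_sd = human_effect_sd
  )
  class(out) <- "HumanMetaConfig"
  out
}

#' Simulate a full-factorial multi-strain mouse CR study
#'
#' Expression for gene g in a sample of strain s under diet d is
#' `baseline_g + strain_offset_{g,s} + diet_indicator * effect_{g,s} + noise`,
#' all on the log2 scale, with gene-specific residual variances drawn from a
#' scaled inverse-chi-square prior. Planted CR effects are common to all
#' tissues of a strain. Identical `(design, effects, seed)` triples reproduce
#' identical output.
#'
#' @param design a [study_design()].
#' @param effects a [mouse_effect_model()].
#' @param seed integer seed for the study's random-number stream.
#' @param n_qc_fail number of randomly chosen samples flagged as QC failures.
#' @return list with `study` (an `ExpressionStudy`: `matrix` genes x samples,
#'   `sample_meta`, optional `detection`, `seed`) and `truth` (a `TruthTable`
#'   data frame: per-gene flags, focal strain, and true log2 CR effect per
#'   strain, applying to every tissue).
#' @examples
#' sim <- simulate_mouse_study(study_design(n_genes = 50), seed = 1)
#' ncol(sim$study$matrix) # 448
#' @export
simulate_mouse_study <- function(design = study_design(),
                                 effects = mouse_effect_model(),
                                 seed,
                                 n_qc_fail = 0L) {
  stopifnot(inherits(design, "StudyDesign"), inherits(effects, "MouseEffectModel"))
  seed <- assert_count(seed, "seed", min = 0L)
  n_qc_fail <- assert_count(n_qc_fail, "n_qc_fail", min = 0L)
  interaction_strains <- effects$interaction_strains %||% design$strains
  if (!all(interaction_strains %in% design$strains)) {
    stop("`interaction_strains` must be a subset of the design's strains", call. = FALSE)
  }

  set.seed(seed)
  n_genes <- design$n_genes
  strains <- design$strains
  genes <- sprintf("Gene%04d", seq_len(n_genes))

  # planted truth
  n_shared <- round(effects$fraction_shared * n_genes)
  n_spec <- round(effects$fraction_strain_specific * n_genes)
  flag <- rep("null", n_genes)
  flag[seq_len(n_shared)] <- "shared"
  flag[seq_len(n_spec) + n_shared] <- "strain_specific"
  effect_mat <- matrix(0, n_genes, length(strains),
    dimnames = list(genes, strains)
  )
  shared_effects <- stats::rnorm(n_shared, 0, effects$shared_effect_sd)
  effect_mat[flag == "shared", ] <- shared_effects
  focal <- rep(NA_character_, n_genes)
  if (n_spec > 0) {
    idx <- which(flag == "strain_specific")
    focal[idx] <- sample(interaction_strains, n_spec, replace = TRUE)
    spec_effects <- stats::rnorm(n_spec, 0, effects$strain_specific_effect_sd)
    effect_mat[cbind(idx, match(focal[idx], strains))] <- spec_effects
  }
  truth <- data.frame(
    gene = genes,
    shared = flag == "shared",
    strain_specific = flag == "strain_specific",
    interaction = flag == "strain_specific",
    focal_strain = focal,
    stringsAsFactors = FALSE
  )
  truth <- cbind(truth, as.data.frame(effect_mat))
  names(truth)[-(1:5)] <- paste0("effect_", strains)
  class(truth) <- c("TruthTable", "data.frame")

  baseline <- stats::rnorm(n_genes, 7, effects$baseline_mean_sd)
  strain_offsets <- matrix(stats::rnorm(n_genes * length(strains), 0, effects$strain_offset_sd),
    n_genes, length(strains),
    dimnames = list(genes, strains)
  )
  if (is.infinite(effects$var_prior_df)) {
    gene_sd <- rep(effects$residual_sd, n_genes)
  } else {
    d0 <- effects$var_prior_df
    gene_sd <- sqrt(effects$residual_sd^2 * d0 / stats::rchisq(n_genes, d0))
  }

  sample_meta <- expand.grid(
    replicate = seq_len(design$replicates_per_cell),
    diet = design$diets,
    strain = strains,
    tissue = design$tissues,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  sample_meta$sample_id <- sprintf(
    "S%03d_%s_%s_%s_r%d",
    seq_len(nrow(sample_meta)), sample_meta$tissue, sample_meta$strain,
    sample_meta$diet, sample_meta$replicate
  )
  sample_meta$qc_flag <- "pass"
  if (n_qc_fail > 0) {
    if (n_qc_fail >= nrow(sample_meta)) {
      stop("cannot flag every sample as a QC failure", call. = FALSE)
    }
    sample_meta$qc_flag[sample.int(nrow(sample_meta), n_qc_fail)] <- "fail"
  }
  sample_meta <- sample_meta[, c("sample_id", "strain", "diet", "tissue", "qc_flag")]

  is_cr <- as.numeric(sample_meta$diet == design$diets[2])
  s_idx <- match(sample_meta$strain, strains)
  mu <- baseline + strain_offsets[, s_idx] +
    effect_mat[, s_idx] * rep(is_cr, each = n_genes)
  noise <- matrix(stats::rnorm(n_genes * nrow(sample_meta)), n_genes) * gene_sd
  mat <- mu + noise
  dimnames(mat) <- list(genes, sample_meta$sample_id)

  study <- expression_study(mat, sample_meta, seed = seed)
  study$gene_sd <- gene_sd
  list(study = study, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate paired human CR experiments linked to mouse ground truth
#'
#' True human effects are built as
#' `rho * standardized mouse shared effect + sqrt(1 - rho^2) * noise`,
#' rescaled to the spread of the mouse shared effects, so the rank
#' correlation between true human and mouse shared effects approximates
#' `config$concordance_rho`. Experiments assigned to the same baseline set
#' share identical baseline samples (and subject count); each experiment has
#' a per-experiment true effect `human_effect + N(0, tau2)` and drops a
#' random `missing_gene_fraction` of genes.
#'
#' @param config a [human_meta_config()].
#' @param truth `TruthTable` from [simulate_mouse_study()].
#' @param seed integer seed.
#' @return list with `experiments` (list of `PairedExperiment`), `truth`
#'   (input truth with a `human_effect` column added), and `manifest`
#'   (experiment_id, baseline_set_id, n_subjects, sex, duration_weeks).
#' @export
simulate_human_experiments <- function(config = human_meta_config(), truth, seed) {
  stopifnot(inherits(config, "HumanMetaConfig"), is.data.frame(truth))
  seed <- assert_count(seed, "seed", min = 0L)
  set.seed(seed)

  n_genes <- nrow(truth)
  genes <- toupper(truth$gene)
  mouse_shared <- ifelse(truth$shared, truth[[grep("^effect_", names(truth))[1]]], 0)
  # shared genes carry the same effect in every strain; use the first column
  sd_m <- stats::sd(mouse_shared)
  if (sd_m == 0) {
    z <- rep(0, n_genes)
    scale_to <- config$human_effect_sd %||% 0.25
  } else {
    z <- (mouse_shared - mean(mouse_shared)) / sd_m
    scale_to <- config$human_effect_sd %||% sd_m
  }
  rho <- config$concordance_rho
  eps <- stats::rnorm(n_genes)
  human_z <- rho * z + sqrt(1 - rho^2) * eps
  human_effect <- human_z * scale_to
  truth$human_effect <- human_effect

  # baseline sets: every set used at least once, extras assigned at random
  set_ids <- sprintf("BS%02d", seq_len(config$n_baseline_sets))
  assign_sets <- c(
    set_ids,
    if (config$n_experiments > config$n_baseline_sets) {
      sample(set_ids, config$n_experiments - config$n_baseline_sets, replace = TRUE)
    }
  )
  lo <- log(config$subjects_range[1])
  hi <- log(config$subjects_range[2])
  set_n <- stats::setNames(
    pmax(config$subjects_range[1], round(exp(stats::runif(length(set_ids), lo, hi)))),
    set_ids
  )
  baseline_by_set <- lapply(set_ids, function(sid) {
    n <- set_n[[sid]]
    b <- matrix(stats::rnorm(n_genes * n, 7, 1.5), n_genes, n)
    dimnames(b) <- list(genes, sprintf("%s_subj%02d", sid, seq_len(n)))
    b
  })
  names(baseline_by_set) <- set_ids

  sexes <- sample(c("M", "F", "unknown"), config$n_experiments,
    replace = TRUE, prob = c(10, 15, 3) / 28
  )
  durations <- sample(4:52, config$n_experiments, replace = TRUE)

  experiments <- vector("list", config$n_experiments)
  for (i in seq_len(config$n_experiments)) {
    sid <- assign_sets[i]
    base <- baseline_by_set[[sid]]
    n <- ncol(base)
    exp_effect <- human_effect + stats::rnorm(n_genes, 0, sqrt(config$tau2))
    post <- base + exp_effect +
      matrix(stats::rnorm(n_genes * n, 0, config$residual_sd), n_genes, n)
    dimnames(post) <- dimnames(base)
    keep <- rep(TRUE, n_genes)
    n_drop <- round(config$missing_gene_fraction * n_genes)
    if (n_drop > 0) keep[sample.int(n_genes, n_drop)] <- FALSE
    experiments[[i]] <- paired_experiment(
      experiment_id = sprintf("EXP%02d", i),
      baseline = base[keep, , drop = FALSE],
      post = post[keep, , drop = FALSE],
      baseline_set_id = sid,
      sex = sexes[i],
      duration_weeks = durations[i]
    )
  }
  manifest <- data.frame(
    experiment_id = vapply(experiments, `[[`, "", "experiment_id"),
    baseline_set_id = assign_sets,
    n_subjects = vapply(experiments, `[[`, 0L, "n_subjects"),
    sex = sexes,
    duration_weeks = durations,
    stringsAsFactors = FALSE
  )
  list(experiments = experiments, truth = truth, manifest = manifest)
}

#' Simulate probe-level perfect-match/mismatch intensity pairs
#'
#' Emulates the probe-pair input of above-background detection calls. A
#' `detect_fraction` of probe sets have perfect-match (PM) intensities
#' stochastically dominating mismatch (MM) intensities; the rest have PM and
#' MM drawn from the same distribution.
#'
#' @param truth `TruthTable` (one probe set is generated per gene).
#' @param probes_per_gene probe pairs per probe set (>= 5).
#' @param detect_fraction fraction of probe sets that are truly detected.
#' @param seed integer seed.
#' @param shift log2 PM excess over MM for detected probe sets.
#' @return data frame with columns gene, probe, pm, mm, detected.
#' @export
simulate_probe_level <- function(truth, probes_per_gene = 11L, detect_fraction = 0.8,
                                 seed, shift = 2) {
  stopifnot(is.data.frame(truth))
  probes_per_gene <- assert_count(probes_per_gene, "probes_per_gene", min = 5L)
  assert_probability(detect_fraction, "detect_fraction")
  seed <- assert_count(seed, "seed", min = 0L)
  set.seed(seed)
  genes <- truth$gene
  n_genes <- length(genes)
  detected <- rep(FALSE, n_genes)
  n_det <- round(detect_fraction * n_genes)
  if (n_det > 0) detected[sample.int(n_genes, n_det)] <- TRUE
  k <- probes_per_gene
  mm <- 2^stats::rnorm(n_genes * k, 6, 1)
  pm_log <- log2(mm) + rep(ifelse(detected, shift, 0), each = k) +
    stats::rnorm(n_genes * k, 0, 1)
  data.frame(
    gene = rep(genes, each = k),
    probe = rep(seq_len(k), times = n_genes),
    pm = 2^pm_log,
    mm = mm,
    detected = rep(detected, each = k),
    stringsAsFactors = FALSE
  )
}
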