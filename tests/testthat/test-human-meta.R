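make_paired <- function(id, set, base, post) {
  paired_experiment(id, base, post, baseline_set_id = set)
}

test_that("paired differences and experiment summaries follow definitions", {
  genes <- paste0("g", 1:6)
  base <- matrix(8, 6, 4, dimnames = list(genes, paste0("s", 1:4)))
  post <- base + 1
  e <- make_paired("E1", "B1", base, post)
  expect_true(all(paired_log2_differences(e) == 1))
  # post identical to baseline -> all zeros
  e0 <- make_paired("E0", "B1", base, base)
  expect_true(all(paired_log2_differences(e0) == 0))
  # misaligned subjects rejected
  post_bad <- post
  colnames(post_bad) <- paste0("x", 1:4)
  expect_error(paired_experiment("E", base, post_bad, "B"), "indexing")
  # two-point summary: diffs (1, -1) per gene -> mean 0, se 1
  genes12 <- paste0("g", 1:12)
  set.seed(80)
  d2 <- matrix(c(1, -1), 12, 2, byrow = TRUE, dimnames = list(genes12, c("a", "b")))
  d2 <- d2 + matrix(rnorm(24, 0, 1e-9), 12, 2) # break exact variance ties
  s <- experiment_summary(d2)
  expect_equal(s$mean, rep(0, 12), tolerance = 1e-8)
  expect_equal(s$se, rep(1, 12), tolerance = 1e-6)
  # planted effect recovered within Monte-Carlo error
  set.seed(81)
  d <- matrix(0.5 + rnorm(600 * 10, 0, 0.2), 600, 10,
    dimnames = list(sprintf("g%03d", 1:600), paste0("s", 1:10))
  )
  s2 <- experiment_summary(d)
  expect_lt(abs(mean(s2$mean) - 0.5), 3 * 0.2 / sqrt(10 * 600))
  expect_gt(mean(abs(s2$mean - 0.5) < 3 * 0.2 / sqrt(10)), 0.99)
  expect_error(experiment_summary(d[, 1, drop = FALSE]), "2 subjects")
})

test_that("low-expression filter removes the floor(fraction * n) lowest genes", {
  genes <- sprintf("g%03d", 1:100)
  base <- matrix(seq_len(100), 100, 3, dimnames = list(genes, paste0("s", 1:3)))
  post <- base
  e <- make_paired("E1", "B1", base, post)
  kept <- low_expression_filter(e, 0.15)
  expect_length(kept, 85)
  expect_false(any(genes[1:15] %in% kept))
  # floor convention at n = 10
  e10 <- make_paired("E2", "B1", base[1:10, ], post[1:10, ])
  expect_length(low_expression_filter(e10, 0.15), 9)
  # all means equal: lexicographic tie-break removes smallest symbols
  basec <- matrix(5, 10, 3, dimnames = list(genes[10:1], paste0("s", 1:3)))
  ec <- make_paired("E3", "B1", basec, basec)
  expect_false("g001" %in% low_expression_filter(ec, 0.15))
})

test_that("independence filter keeps the lowest-average-se experiment per baseline set", {
  s <- data.frame(
    experiment_id = c("E1", "E2", "E3"),
    baseline_set_id = c("A", "A", "B"),
    average_se = c(0.2, 0.3, 0.5)
  )
  keep <- independence_filter(s)
  expect_setequal(keep$experiment_id, c("E1", "E3"))
  # all-distinct sets: identity
  s2 <- data.frame(
    experiment_id = paste0("E", 1:4),
    baseline_set_id = paste0("B", 1:4), average_se = runif(4)
  )
  expect_equal(nrow(independence_filter(s2)), 4L)
  # tie on average_se broken by lexicographic experiment_id
  s3 <- data.frame(
    experiment_id = c("E2", "E1"), baseline_set_id = c("A", "A"),
    average_se = c(0.2, 0.2)
  )
  expect_equal(independence_filter(s3)$experiment_id, "E1")
  # output size always equals number of distinct baseline sets
  set.seed(82)
  s4 <- data.frame(
    experiment_id = sprintf("E%02d", 1:28),
    baseline_set_id = sample(sprintf("B%02d", 1:18), 28, replace = TRUE),
    average_se = runif(28)
  )
  expect_equal(
    nrow(independence_filter(s4)),
    length(unique(s4$baseline_set_id))
  )
})

test_that("gene inclusion filter applies the >= 6 experiments boundary", {
  presence <- matrix(FALSE, 3, 18,
    dimnames = list(c("six", "five", "all"), NULL)
  )
  presence["six", 1:6] <- TRUE
  presence["five", 1:5] <- TRUE
  presence["all", ] <- TRUE
  expect_setequal(gene_inclusion_filter(presence), c("six", "all"))
})

test_that("DerSimonian-Laird matches hand-evaluated formulas and metafor", {
  # symmetry: equal weights force the midpoint
  dl <- dersimonian_laird(c(0.2, 0.6), c(0.1, 0.1))
  expect_equal(dl$mu, 0.4)
  # hand-evaluated: w = 100 each, Q = 8, tau2 = 7/100, wstar = 12.5
  expect_equal(dl$Q, 8)
  expect_equal(dl$tau2, 0.07)
  expect_equal(dl$se_mu, 1 / sqrt(2 * 12.5))
  # homogeneous limit
  dl0 <- dersimonian_laird(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(dl0$tau2, 0)
  expect_equal(dl0$mu, 0.3)
  # pooled estimate within the convex hull of the inputs
  set.seed(83)
  for (i in 1:20) {
    y <- rnorm(5)
    se <- runif(5, 0.05, 0.5)
    dli <- dersimonian_laird(y, se)
    expect_gte(dli$mu, min(y))
    expect_lte(dli$mu, max(y))
    expect_true(dli$tau2 == 0 || dli$Q > length(y) - 1)
  }
  skip_if_not_installed("metafor")
  y <- c(0.2, 0.6, 0.1, -0.3, 0.4)
  se <- c(0.1, 0.15, 0.2, 0.12, 0.3)
  dl2 <- dersimonian_laird(y, se)
  rm <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(dl2$mu, as.numeric(rm$b), tolerance = 1e-10)
  expect_equal(dl2$tau2, rm$tau2, tolerance = 1e-10)
  expect_equal(dl2$se_mu, rm$se, tolerance = 1e-10)
  expect_equal(dl2$p, rm$pval, tolerance = 1e-10)
  expect_error(dersimonian_laird(0.5, 0.1), "2 contributing")
  expect_error(dersimonian_laird(c(0.5, 0.2), c(0, 0.1)), "positive")
})

test_that("meta-signature recovers a common planted effect", {
  sim <- small_sim(84,
    n_genes = 300,
    effects = mouse_effect_model(fraction_shared = 0, fraction_strain_specific = 0)
  )
  truth <- sim$truth
  truth$human_effect_target <- 0.5
  mus <- vapply(1:5, function(seed) {
    cfg <- human_meta_config(
      n_experiments = 8, n_baseline_sets = 8,
      concordance_rho = 0, missing_gene_fraction = 0, tau2 = 0,
      residual_sd = 0.3, subjects_range = c(8L, 12L), human_effect_sd = 0
    )
    hs <- simulate_human_experiments(cfg, truth, seed = 100 + seed)
    # shift every post matrix by the common planted effect
    exps <- lapply(hs$experiments, function(e) {
      e$post <- e$post + 0.5
      e
    })
    mean(meta_signature(exps, min_experiments = 2)$meta_log2fc)
  }, numeric(1))
  mc_se <- sd(mus) / sqrt(length(mus))
  expect_lt(abs(mean(mus) - 0.5), 3 * mc_se + 0.01)
})

test_that("meta-signature composition filters dependent experiments and sparse genes", {
  sim <- small_sim(85, n_genes = 120)
  cfg <- human_meta_config(
    n_experiments = 10, n_baseline_sets = 4,
    missing_gene_fraction = 0.5, subjects_range = c(4L, 6L)
  )
  hs <- simulate_human_experiments(cfg, sim$truth, seed = 86)
  ms <- meta_signature(hs$experiments, min_experiments = 2)
  expect_equal(nrow(attr(ms, "retained_experiments")), 4L)
  expect_true(all(ms$k_experiments >= 2))
  expect_true(all(ms$tau2 >= 0))
  expect_true(all(ms$fdr >= ms$p - 1e-12))
  expect_equal(ms$meta_fc, 2^ms$meta_log2fc)
  # all experiments sharing one baseline set cannot be meta-analyzed
  cfg1 <- human_meta_config(
    n_experiments = 3, n_baseline_sets = 1,
    missing_gene_fraction = 0
  )
  hs1 <- simulate_human_experiments(cfg1, sim$truth, seed = 87)
  expect_error(meta_signature(hs1$experiments), "fewer than 2 independent")
})

test_that("planted between-experiment heterogeneity is recovered", {
  sim <- small_sim(88,
    n_genes = 1500,
    effects = mouse_effect_model(fraction_shared = 0, fraction_strain_specific = 0)
  )
  cfg <- human_meta_config(
    n_experiments = 18, n_baseline_sets = 18,
    concordance_rho = 0, missing_gene_fraction = 0, tau2 = 0.1,
    residual_sd = 0.2, subjects_range = c(10L, 12L), human_effect_sd = 0
  )
  hs <- simulate_human_experiments(cfg, sim$truth, seed = 89)
  ms <- meta_signature(hs$experiments, min_experiments = 6)
  expect_lt(abs(median(ms$tau2) - 0.1) / 0.1, 0.30)
})
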