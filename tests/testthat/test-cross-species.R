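id_map <- function(genes) {
  data.frame(
    mouse_symbol = genes, human_symbol = toupper(genes),
    stringsAsFactors = FALSE
  )
}

test_that("ortholog joins are one-to-one inner joins with dropout accounting", {
  genes <- sprintf("g%03d", 1:50)
  mfit <- make_fit_table(genes, runif(50), rnorm(50, 0, 0.5))
  htab <- data.frame(gene = toupper(genes), log2fc = rnorm(50))
  joined <- map_orthologs(mfit, htab, id_map(genes))
  expect_equal(nrow(joined), 50L)
  expect_equal(attr(joined, "n_unmapped"), 0L)
  # 10% dropout in the map drops exactly those genes
  joined2 <- map_orthologs(mfit, htab, id_map(genes)[1:45, ])
  expect_equal(nrow(joined2), 45L)
  expect_equal(attr(joined2, "n_unmapped"), 5L)
  # duplicate map entries rejected
  bad <- rbind(id_map(genes), id_map(genes)[1, ])
  expect_error(map_orthologs(mfit, htab, bad), "one-to-one")
  # empty intersection flagged
  expect_warning(
    j0 <- map_orthologs(mfit, data.frame(gene = "NOPE", log2fc = 1), id_map(genes)),
    "no orthologous"
  )
  expect_equal(nrow(j0), 0L)
})

test_that("species correlation grid reproduces copied and reversed rankings", {
  genes <- sprintf("g%03d", 1:60)
  set.seed(91)
  mfit <- make_fit_table(genes, runif(60), rnorm(60, 0, 0.5))
  same <- data.frame(gene = toupper(genes), log2fc = mfit$log2fc)
  reversed <- data.frame(gene = toupper(genes), log2fc = -mfit$log2fc)
  grid <- species_correlations(
    list(S1 = mfit),
    list(copy = same, mirror = reversed),
    id_map(genes)
  )
  expect_equal(grid$rho["S1", "copy"], 1)
  expect_equal(grid$rho["S1", "mirror"], -1)
  expect_true(grid$per_strain$q25 <= grid$per_strain$median)
  expect_true(grid$per_strain$median <= grid$per_strain$q75)
  # symmetry: swapping the two vectors of a cell leaves rho unchanged
  hfit <- make_fit_table(toupper(genes), runif(60), rnorm(60))
  mtab <- data.frame(gene = genes, log2fc = mfit$log2fc)
  swap_map <- data.frame(mouse_symbol = toupper(genes), human_symbol = genes)
  g1 <- species_correlations(
    list(S = mfit), list(E = data.frame(gene = toupper(genes), log2fc = hfit$log2fc)),
    id_map(genes)
  )
  g2 <- species_correlations(
    list(S = hfit), list(E = mtab), swap_map
  )
  expect_equal(g1$rho["S", "E"], g2$rho["S", "E"])
})

test_that("generator concordance propagates to the correlation grid", {
  effects <- mouse_effect_model(
    fraction_shared = 1, shared_effect_sd = 0.5,
    fraction_strain_specific = 0, residual_sd = 0.1, var_prior_df = Inf
  )
  res <- vapply(1:8, function(seed) {
    sim <- small_sim(seed, n_genes = 300, effects = effects)
    cfg <- human_meta_config(
      n_experiments = 4, n_baseline_sets = 4,
      concordance_rho = -0.5, missing_gene_fraction = 0, tau2 = 0,
      residual_sd = 0.1, subjects_range = c(15L, 20L)
    )
    hs <- simulate_human_experiments(cfg, sim$truth, seed = 500 + seed)
    m <- sim$study$sample_meta
    fits <- lapply(c("A", "B"), function(s) {
      sel <- m$strain == s
      cr_contrast_fit(sim$study$matrix[, sel], m$diet[sel])
    })
    names(fits) <- c("A", "B")
    human_tables <- lapply(hs$experiments, function(e) {
      s <- experiment_summary(paired_log2_differences(e))
      data.frame(gene = s$gene, log2fc = s$mean)
    })
    names(human_tables) <- vapply(hs$experiments, `[[`, "", "experiment_id")
    grid <- species_correlations(fits, human_tables, id_map(sim$truth$gene))
    truth_rho <- cor(hs$truth$human_effect, hs$truth$effect_A, method = "spearman")
    c(observed = mean(grid$rho), truth = truth_rho)
  }, numeric(2))
  # sign always recovered
  expect_true(all(res["observed", ] < 0))
  diffs <- res["observed", ] - res["truth", ]
  mc_se <- sd(diffs) / sqrt(ncol(res))
  expect_lt(abs(mean(diffs)), 3 * mc_se + 0.02)
})

test_that("top-n selection is deterministic with documented tie-breaks", {
  genes <- c("b", "a", "c", "d", "e")
  fit <- make_fit_table(genes, c(0.5, 0.5, 0.1, 0.5, 0.5), c(1, 1, 1, 0.2, -2))
  expect_equal(top_n_genes(fit, 1, "up"), "c") # tie on log2fc, smaller p wins
  expect_equal(top_n_genes(fit, 3, "up"), c("c", "a", "b")) # then symbol
  expect_equal(top_n_genes(fit, 1, "down"), "e")
  expect_warning(all5 <- top_n_genes(fit, 10, "up"), "fewer than 10")
  expect_length(all5, 5)
})

test_that("cumulative-overlap statistic attains its extremes and mirrors", {
  set.seed(92)
  H <- 200
  m <- 20
  ranking <- sprintf("h%03d", sample(H))
  top <- ranking[1:m]
  bottom <- ranking[(H - m + 1):H]
  g_top <- cumulative_overlap_gsea(ranking, top, B = 200, seed = 93)
  expect_equal(g_top$statistic, (m - m^2 / H) / m)
  expect_equal(g_top$p, 1 / 201)
  g_bot <- cumulative_overlap_gsea(ranking, bottom, B = 200, seed = 93)
  expect_equal(g_bot$statistic, -(m - m^2 / H) / m)
  # mirror symmetry: reversed ranking negates the statistic of any set
  some <- sample(ranking, m)
  g_f <- cumulative_overlap_gsea(ranking, some, B = 50, seed = 94)
  g_r <- cumulative_overlap_gsea(rev(ranking), some, B = 50, seed = 94)
  expect_equal(g_f$statistic, -g_r$statistic, tolerance = 1e-12)
  # invariance under relabeling genes outside the set
  ranking2 <- ranking
  outside <- !(ranking2 %in% some)
  ranking2[outside] <- paste0("x", ranking2[outside])
  g_2 <- cumulative_overlap_gsea(ranking2, some, B = 50, seed = 94)
  expect_equal(g_2$statistic, g_f$statistic)
  expect_error(cumulative_overlap_gsea(ranking, c(top, "absent")), "absent")
  expect_error(cumulative_overlap_gsea(ranking, ranking[1:3], B = 50, seed = 1), "at least 5")
})

test_that("random gene sets give calibrated enrichment p-values", {
  set.seed(95)
  H <- 300
  ranking <- sprintf("h%03d", 1:H)
  ps <- vapply(1:60, function(i) {
    cumulative_overlap_gsea(ranking, sample(ranking, 15), B = 200, seed = 1000 + i)$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.0)
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("median fold-change test matches exact signed-rank enumeration", {
  expect_equal(median_fc_test(rep(1, 10))$p, 1)
  res2 <- median_fc_test(rep(2, 10))
  expect_equal(res2$median_fc, 2)
  expect_equal(res2$p, 2^-9)
  # symmetric on the log scale: p near 1
  sym <- c(2, 1 / 2, 4, 1 / 4, 1.5, 1 / 1.5)
  expect_gt(median_fc_test(sym)$p, 0.5)
  # general case vs the enumeration oracle (two-sided from one-sided tails)
  set.seed(96)
  for (i in 1:5) {
    fc <- 2^rnorm(8, 0.3, 0.5)
    got <- median_fc_test(fc)$p
    d <- log2(fc)
    # oracle two-sided: 2 * min(tails), capped at 1
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    n <- length(d)
    all_w <- vapply(0:(2^n - 1), function(mask) {
      signs <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0
      sum(r[signs])
    }, numeric(1))
    oracle_p <- min(1, 2 * min(mean(all_w >= W), mean(all_w <= W)))
    expect_equal(got, oracle_p, tolerance = 1e-12)
  }
  expect_error(median_fc_test(c(1, 2)), "at least 5")
})
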