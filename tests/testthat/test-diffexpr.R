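test_that("per-gene OLS matches direct residual computation", {
  set.seed(21)
  n <- 16
  mat <- matrix(rnorm(100 * n), 100, n, dimnames = list(sprintf("g%03d", 1:100), NULL))
  diet <- rep(c(0, 1), each = 8)
  design <- cbind(intercept = 1, diet = diet)
  fit <- fit_gene_linear_models(mat, design)
  expect_equal(fit$df_residual, 14L)
  # direct two-group oracle for one gene
  g <- mat[7, ]
  expect_equal(unname(fit$coefficients[7, "diet"]), mean(g[diet == 1]) - mean(g[diet == 0]))
  res <- g - ifelse(diet == 1, mean(g[diet == 1]), mean(g[diet == 0]))
  expect_equal(fit$sigma2[7], sum(res^2) / 14)
  # group means 9 vs 8 give log2fc 1, FC 2
  mat2 <- matrix(rep(c(8, 9), each = 8), 1, n, dimnames = list("g", NULL))
  fit2 <- fit_gene_linear_models(mat2, design)
  expect_equal(unname(fit2$coefficients[1, "diet"]), 1)
  expect_equal(fit2$sigma2[1], 0) # residuals all zero, degenerate
  expect_error(
    fit_gene_linear_models(mat, cbind(a = 1, b = diet, c = diet)),
    "collinear columns: c"
  )
})

test_that("variance prior recovery from a known scaled inverse-chi-square", {
  set.seed(22)
  d0 <- 4
  s02 <- 0.25
  d <- 14
  sigma2 <- s02 * d0 / rchisq(5000, d0)
  s2 <- sigma2 * rchisq(5000, d) / d
  mv <- moderate_variances(s2, d)
  expect_lt(abs(mv$d0 - d0) / d0, 0.20)
  expect_lt(abs(mv$s02 - s02) / s02, 0.05)
  # shrinkage formula
  expect_equal(mv$s2_post, (mv$d0 * mv$s02 + d * s2) / (mv$d0 + d))
})

test_that("identical variances give infinite prior df and constant posterior", {
  mv <- moderate_variances(rep(0.5, 100), 14)
  expect_identical(mv$d0, Inf)
  expect_true(all(mv$s2_post == mv$s02))
  # the log-scale bias correction implies s02 = s2 * (d/2)/exp(digamma(d/2))
  expect_equal(mv$s02, 0.5 * (14 / 2) / exp(digamma(7)))
})

test_that("variance moderation agrees with the limma empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  set.seed(23)
  s2 <- 0.3 * 3 / rchisq(2000, 3) * rchisq(2000, 10) / 10
  mv <- moderate_variances(s2, 10)
  sq <- limma::squeezeVar(s2, df = 10)
  expect_equal(mv$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mv$s02, sq$var.prior, tolerance = 1e-6)
  expect_equal(mv$s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("moderated t collapses to classical t at d0 = 0 and z at d0 = Inf", {
  set.seed(24)
  n <- 10
  mat <- matrix(rnorm(50 * n), 50, n, dimnames = list(sprintf("g%02d", 1:50), NULL))
  diet <- rep(c(0, 1), each = 5)
  fit <- fit_gene_linear_models(mat, cbind(i = 1, diet = diet))
  tt0 <- moderated_t_test(
    fit$coefficients[, "diet"], fit$stdev_unscaled["diet"],
    fit$sigma2, fit$df_residual, 0
  )
  classical <- apply(mat, 1, function(g) {
    t.test(g[diet == 1], g[diet == 0], var.equal = TRUE)$p.value
  })
  expect_equal(unname(tt0$p), unname(classical), tolerance = 1e-10)
  ttinf <- moderated_t_test(
    fit$coefficients[, "diet"], fit$stdev_unscaled["diet"],
    rep(1, 50), fit$df_residual, Inf
  )
  z <- fit$coefficients[, "diet"] / fit$stdev_unscaled["diet"]
  expect_equal(unname(ttinf$p), unname(2 * pnorm(-abs(z))), tolerance = 1e-10)
  # beta = 0 -> t = 0, p = 1
  tt <- moderated_t_test(0, 0.5, 0.2, 10, 4)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
})

test_that("moderated test is calibrated under the null", {
  sim <- small_sim(101,
    n_genes = 5000,
    effects = mouse_effect_model(
      fraction_shared = 0, fraction_strain_specific = 0,
      strain_offset_sd = 0
    )
  )
  m <- sim$study$sample_meta
  sel <- m$strain == "A"
  fit <- cr_contrast_fit(sim$study$matrix[, sel], m$diet[sel])
  typeI <- mean(fit$p < 0.05)
  expect_gte(typeI, 0.04)
  expect_lte(typeI, 0.06)
})

test_that("BH adjustment: step-up values, idempotence, permutation equivariance", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  set.seed(25)
  p <- runif(200)^2
  q <- bh_adjust(p)
  # re-adjusting can only push q-values up, never below the first pass
  expect_true(all(bh_adjust(q) >= q - 1e-12))
  # constant vectors (fully tied q-values) are fixed points
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), q[perm]) # order-equivariant
  expect_true(all(q >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calls apply both FDR and fold-change thresholds", {
  fit <- data.frame(
    gene = c("a", "b", "c", "d"),
    fc = c(1.6, 1.2, 2.0, 0.5),
    fdr = c(0.05, 0.05, 0.20, 0.01)
  )
  degs <- call_degs(fit)
  expect_setequal(degs$gene, c("a", "d"))
  expect_equal(degs$direction[degs$gene == "a"], "up")
  expect_equal(degs$direction[degs$gene == "d"], "down")
  # invariant to gene ordering
  degs_rev <- call_degs(fit[4:1, ])
  expect_setequal(degs_rev$gene, degs$gene)
})

test_that("interaction scan detects a planted focal-strain response", {
  sim <- simulate_mouse_study(
    study_design(
      strains = c("F", paste0("O", 1:6)), tissues = "T1",
      replicates_per_cell = 8, n_genes = 600
    ),
    mouse_effect_model(
      fraction_shared = 0, fraction_strain_specific = 0,
      strain_offset_sd = 0, residual_sd = 0.5, var_prior_df = Inf
    ),
    seed = 55
  )
  m <- sim$study$sample_meta
  mat <- sim$study$matrix
  planted <- 1:100
  mat[planted, m$strain == "F" & m$diet == "CR"] <-
    mat[planted, m$strain == "F" & m$diet == "CR"] + 1
  scan <- interaction_scan(mat, m$strain, m$diet, focal_strain = "F")
  expect_equal(mean(scan$log2fc[planted]), 1, tolerance = 0.1)
  power <- mean(scan$fdr[planted] < 0.10)
  expect_gt(power, 0.8)
  # null genes keep approximately nominal raw type-I error
  null_typeI <- mean(scan$p[-planted] < 0.05)
  expect_lt(abs(null_typeI - 0.05), 0.025)
  expect_error(
    interaction_scan(mat, rep("F", ncol(mat)), m$diet, "F"),
    "two strains"
  )
  # determinism: identical input reproduces identical output
  expect_identical(scan, interaction_scan(mat, m$strain, m$diet, focal_strain = "F"))
})

test_that("moderated pipeline agrees with limma on a shared fixture", {
  skip_if_not_installed("limma")
  sim <- small_sim(77, n_genes = 300)
  m <- sim$study$sample_meta
  sel <- m$strain == "A"
  mat <- sim$study$matrix[, sel]
  diet <- as.numeric(m$diet[sel] == "CR")
  fit <- cr_contrast_fit(mat, m$diet[sel])
  lf <- limma::eBayes(limma::lmFit(mat, cbind(1, diet = diet)))
  expect_equal(fit$log2fc, unname(lf$coefficients[, "diet"]), tolerance = 1e-10)
  expect_equal(fit$t, unname(lf$t[, "diet"]), tolerance = 1e-6)
  expect_equal(fit$p, unname(lf$p.value[, "diet"]), tolerance = 1e-6)
})
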