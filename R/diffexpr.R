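# Per-gene linear models with empirical-Bayes variance moderation. The
# moderated t-statistic shrinks each gene's residual variance toward a prior
# (d0, s0^2) estimated across genes by moment matching on the log residual
# variances, gaining d0 degrees of freedom per gene.

#' Ordinary least squares fits for every gene
#'
#' Fits the same linear model to each gene (row) of a log2 expression matrix.
#'
#' @param matrix numeric genes x samples matrix.
#' @param design numeric samples x p design matrix with column names; must be
#'   full rank with at least p + 1 samples.
#' @return list with `coefficients` (genes x p), `sigma2` (residual
#'   variances), `df_residual`, `stdev_unscaled` (per-coefficient unscaled
#'   standard deviations, i.e. sqrt of the diagonal of (X'X)^-1), and
#'   `design`.
#' @export
fit_gene_linear_models <- function(matrix, design) {
  stopifnot(is.matrix(matrix), is.numeric(matrix), is.matrix(design))
  n <- ncol(matrix)
  if (nrow(design) != n) stop("design rows must match matrix columns", call. = FALSE)
  p <- ncol(design)
  if (n < p + 1L) stop("need at least p + 1 samples for p coefficients", call. = FALSE)
  qrd <- qr(design)
  if (qrd$rank < p) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):p]]
    stop("design matrix is rank-deficient; collinear columns: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  y <- t(matrix)
  beta <- qr.coef(qrd, y) # p x genes
  res <- qr.resid(qrd, y)
  df_residual <- n - p
  sigma2 <- colSums(res^2) / df_residual
  xtxinv <- chol2inv(chol(crossprod(design)))
  stdev_unscaled <- sqrt(diag(xtxinv))
  names(stdev_unscaled) <- colnames(design)
  list(
    coefficients = t(beta),
    sigma2 = unname(sigma2),
    df_residual = df_residual,
    stdev_unscaled = stdev_unscaled,
    design = design
  )
}

#' Estimate the variance prior and moderate per-gene variances
#'
#' Moment estimator of the scaled inverse-chi-square prior (d0, s0^2) of the
#' gene residual variances, based on
#' `e_g = log s2_g - digamma(d_g/2) + log(d_g/2)` (an unbiased estimator of
#' `log sigma2_g` under the chi-square sampling distribution): the excess of
#' `var(e)` over `mean(trigamma(d_g/2))` is matched to `trigamma(d0/2)` via
#' Newton iteration on the trigamma inverse; non-positive excess gives
#' d0 = Inf (no excess dispersion, full shrinkage to s0^2). Posterior
#' variances are `(d0 s0^2 + d_g s2_g) / (d0 + d_g)`.
#'
#' Genes with zero residual variance are excluded from prior estimation but
#' still moderated.
#'
#' @param s2 numeric vector of per-gene residual variances (>= 10 genes).
#' @param df residual degrees of freedom (scalar or per-gene vector).
#' @return list with `d0`, `s02`, and `s2_post` (moderated variances).
#' @export
moderate_variances <- function(s2, df) {
  stopifnot(is.numeric(s2), is.numeric(df), all(df > 0), all(s2 >= 0))
  if (length(s2) < 10L) {
    stop("at least 10 genes are required to estimate the variance prior", call. = FALSE)
  }
  if (length(df) == 1L) df <- rep(df, length(s2))
  ok <- s2 > 0
  if (sum(ok) < 10L) {
    stop("fewer than 10 genes with positive residual variance", call. = FALSE)
  }
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  excess <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  } else {
    d0 <- Inf
    s02 <- exp(emean)
    s2_post <- rep(s02, length(s2))
  }
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Moderated t-test for one coefficient
#'
#' @param beta per-gene coefficient estimates (log2 scale).
#' @param stdev_unscaled scalar unscaled standard deviation of the
#'   coefficient (from the design matrix).
#' @param s2_post moderated variances from [moderate_variances()].
#' @param df residual degrees of freedom (scalar or vector).
#' @param d0 prior degrees of freedom; `Inf` gives a normal reference.
#' @return list with `t` and two-sided `p` vectors; genes with zero
#'   moderated variance get NA and are reported in `degenerate`.
#' @export
moderated_t_test <- function(beta, stdev_unscaled, s2_post, df, d0) {
  stopifnot(length(stdev_unscaled) == 1L, stdev_unscaled > 0)
  degenerate <- !is.na(s2_post) & s2_post == 0
  t <- beta / (stdev_unscaled * sqrt(s2_post))
  t[degenerate] <- NA_real_
  if (is.infinite(d0)) {
    p <- 2 * stats::pnorm(-abs(t))
  } else {
    p <- 2 * stats::pt(-abs(t), df = df + d0)
  }
  list(t = t, p = p, degenerate = degenerate)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q_i = min_{p_j >= p_i} (m p_j / rank_j)`
#' capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Assemble a per-gene fit table for one contrast
#'
#' Runs the OLS + moderation + moderated-t pipeline for one coefficient of a
#' design matrix and returns a `GeneFitTable` data frame.
#'
#' @param matrix genes x samples log2 matrix with gene rownames.
#' @param design samples x p design matrix.
#' @param coef name or index of the coefficient to test.
#' @return data frame with columns gene, log2fc, fc, sigma2, s2_post, df,
#'   df_total, t, p, fdr.
#' @export
gene_fit_table <- function(matrix, design, coef) {
  fit <- fit_gene_linear_models(matrix, design)
  mv <- moderate_variances(fit$sigma2, fit$df_residual)
  if (is.character(coef)) coef <- match(coef, colnames(design))
  tt <- moderated_t_test(
    fit$coefficients[, coef], fit$stdev_unscaled[coef],
    mv$s2_post, fit$df_residual, mv$d0
  )
  log2fc <- unname(fit$coefficients[, coef])
  out <- data.frame(
    gene = rownames(matrix),
    log2fc = log2fc,
    fc = 2^log2fc,
    sigma2 = fit$sigma2,
    s2_post = mv$s2_post,
    df = fit$df_residual,
    df_total = fit$df_residual + mv$d0,
    t = unname(tt$t),
    p = unname(tt$p),
    fdr = bh_adjust(unname(tt$p)),
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- mv$d0
  attr(out, "s02") <- mv$s02
  class(out) <- c("GeneFitTable", "data.frame")
  out
}

#' CR-versus-control contrast for one strain-tissue comparison
#'
#' Two-group moderated-t comparison; positive log2 fold-changes mean higher
#' expression under caloric restriction.
#'
#' @param matrix genes x samples log2 matrix.
#' @param diet character vector per sample; values must include both diet
#'   labels.
#' @param cr_label label identifying CR samples (default "CR").
#' @return a `GeneFitTable` (see [gene_fit_table()]).
#' @export
cr_contrast_fit <- function(matrix, diet, cr_label = "CR") {
  stopifnot(length(diet) == ncol(matrix))
  is_cr <- as.numeric(diet == cr_label)
  if (all(is_cr == 0) || all(is_cr == 1)) {
    stop("both diet groups must be present", call. = FALSE)
  }
  design <- cbind(intercept = 1, diet = is_cr)
  gene_fit_table(matrix, design, coef = "diet")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when its FDR is below `q_max` and its linear fold-change
#' exceeds `fc_up` or falls below `fc_down`.
#'
#' @param fit a `GeneFitTable`.
#' @param q_max FDR threshold (default 0.10).
#' @param fc_up,fc_down linear fold-change thresholds (defaults 1.50, 0.67).
#' @return data frame of DEGs with a `direction` column ("up"/"down").
#' @export
call_degs <- function(fit, q_max = 0.10, fc_up = 1.50, fc_down = 0.67) {
  stopifnot(is.data.frame(fit), all(c("fdr", "fc") %in% names(fit)))
  assert_probability(q_max, "q_max")
  sel <- !is.na(fit$fdr) & fit$fdr < q_max & (fit$fc > fc_up | fit$fc < fc_down)
  out <- fit[sel, , drop = FALSE]
  out$direction <- ifelse(out$fc > 1, "up", "down")
  rownames(out) <- NULL
  out
}

#' Strain-by-diet interaction scan for one focal strain
#'
#' Per-gene model `expression = diet + strain + diet:strain` where diet is
#' 1 for CR samples and strain is 1 for the focal strain, 0 for all other
#' strains pooled. The moderated test is applied to the interaction
#' coefficient; FDR is controlled within the scan.
#'
#' @param matrix genes x samples log2 matrix (one tissue).
#' @param strain character vector of strain labels per sample.
#' @param diet character vector of diet labels per sample.
#' @param focal_strain the strain whose CR response is contrasted against the
#'   pooled remaining strains.
#' @param cr_label label identifying CR samples.
#' @return a `GeneFitTable` for the interaction coefficient (log2fc is the
#'   focal-strain excess CR response).
#' @export
interaction_scan <- function(matrix, strain, diet, focal_strain, cr_label = "CR") {
  stopifnot(length(strain) == ncol(matrix), length(diet) == ncol(matrix))
  if (!focal_strain %in% strain) stop("focal strain absent from data", call. = FALSE)
  if (length(unique(strain)) < 2L) {
    stop("interaction scan requires at least two strains", call. = FALSE)
  }
  is_cr <- as.numeric(diet == cr_label)
  is_focal <- as.numeric(strain == focal_strain)
  for (grp in list(is_focal == 1, is_focal == 0)) {
    if (length(unique(is_cr[grp])) < 2L) {
      stop("both diets must be present inside and outside the focal strain",
        call. = FALSE
      )
    }
  }
  design <- cbind(
    intercept = 1, diet = is_cr, strain = is_focal,
    interaction = is_cr * is_focal
  )
  gene_fit_table(matrix, design, coef = "interaction")
}
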