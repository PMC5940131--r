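#' @keywords internal
"_PACKAGE"

# Internal numeric and statistical helpers shared across modules.

#' One-sample signed-rank test
#'
#' Wilcoxon signed-rank test of the hypothesis that the differences `d` are
#' symmetric about zero. Zero differences are dropped before ranking
#' (standard signed-rank convention). The null distribution is exact
#' (`psignrank`) for up to `exact_max_n` untied differences, an exhaustive
#' sign-flip enumeration when tied absolute differences are present and
#' n <= 15, and a tie-corrected normal approximation with continuity
#' correction otherwise.
#'
#' @param d numeric vector of differences.
#' @param alternative "greater" (positive shift), "less", or "two.sided".
#' @param exact_max_n largest n for which the exact untied null is used.
#' @return list with `statistic` (W, rank sum of positive differences),
#'   `p.value`, `n` (non-zero differences used), and `method`.
#' @examples
#' signed_rank_test(c(1, 2, 3, 4, 5), alternative = "greater")
#' @export
signed_rank_test <- function(d, alternative = c("greater", "two.sided", "less"),
                             exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(d), length(d) >= 1L)
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p.value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0L
  if (!ties && n <= exact_max_n) {
    p_greater <- stats::psignrank(W - 1, n, lower.tail = FALSE)
    p_less <- stats::psignrank(W, n)
    method <- "exact"
  } else if (ties && n <= 15L) {
    # exhaustive sign-flip null: exact permutation distribution even with ties
    flips <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(flips %*% r)
    p_greater <- mean(w_all >= W)
    p_less <- mean(w_all <= W)
    method <- "enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    p_greater <- stats::pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    p_less <- stats::pnorm((W - mu + 0.5) / sqrt(sigma2))
    method <- "normal"
  }
  p <- switch(alternative,
    greater = p_greater,
    less = p_less,
    two.sided = min(1, 2 * min(p_greater, p_less))
  )
  list(statistic = W, p.value = min(1, max(p, 0)), n = n, method = method)
}

# Inverse of the trigamma function by monotone Newton iteration.
# Solves trigamma(y) = x for y > 0; vectorized over x.
trigamma_inverse <- function(x, tol = 1e-8, maxit = 50L) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) {
      return(NA_real_)
    }
    if (xi > 1e7) {
      return(1 / sqrt(xi))
    }
    if (xi < 1e-6) {
      return(1 / xi)
    }
    y <- 0.5 + 1 / xi
    for (i in seq_len(maxit)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < tol) break
    }
    y
  }, numeric(1))
}

# validation helpers ---------------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
      call. = FALSE
    )
  }
  invisible(x)
}

assert_probability <- function(x, name) assert_scalar_number(x, name, 0, 1)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
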