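#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon test of a marker between, e.g., the
#' responder and non-responder groups. The exact null distribution is used
#' when both groups have at most 25 observations and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A test-result list: `statistic` (rank-sum W), `p_value`, `method`,
#'   `n_used`, `estimate` (`NA`; no effect size reported).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L) {
    mp_stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) <= 25L && length(group_b) <= 25L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  test_result(statistic = unname(wt$statistic), p_value = wt$p.value,
              method = if (exact) "wilcoxon_exact" else "wilcoxon_normal_approx",
              n_used = length(group_a) + length(group_b))
}

#' Spearman rank correlation
#'
#' Rank correlation of two paired vectors (average ranks for ties), with a
#' two-sided p-value from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom, which is
#' deterministic at every n (no permutation).
#'
#' @param x,y Paired numeric vectors; at least 3 complete pairs.
#' @return A test-result list with `estimate` = rho. A constant input yields
#'   `estimate = NA` and `method = "spearman_degenerate"` instead of an
#'   error, so screening loops can continue.
#' @export
spearman_corr <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) mp_stop("need at least 3 complete pairs")
  if (n_distinct_nonmiss(x) < 2L || n_distinct_nonmiss(y) < 2L) {
    return(test_result(statistic = NA_real_, p_value = NA_real_,
                       method = "spearman_degenerate", n_used = n,
                       estimate = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE,
                    alternative = "two.sided")
  )
  test_result(statistic = unname(ct$statistic), p_value = ct$p.value,
              method = "spearman_t_approx", n_used = n,
              estimate = unname(ct$estimate))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test of independence: the p-value sums, over all tables
#' with the observed margins, the hypergeometric probabilities no larger
#' than that of the observed table. The reported effect size is the sample
#' odds ratio, with the Haldane-Anscombe +0.5 correction when any cell is
#' zero.
#'
#' @param counts 2x2 matrix of non-negative integers.
#' @return A test-result list with `estimate` = odds ratio. A zero margin is
#'   degenerate: p = 1 with `method = "fisher_degenerate"`.
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0) ||
      any(counts != round(counts))) {
    mp_stop("`counts` must be a 2x2 matrix of non-negative integers")
  }
  n_used <- sum(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    return(test_result(statistic = NA_real_, p_value = 1,
                       method = "fisher_degenerate", n_used = n_used,
                       estimate = NA_real_))
  }
  ft <- stats::fisher.test(counts, alternative = "two.sided")
  or <- if (any(counts == 0)) {
    cc <- counts + 0.5
    (cc[1, 1] * cc[2, 2]) / (cc[1, 2] * cc[2, 1])
  } else {
    (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  }
  test_result(statistic = NA_real_, p_value = ft$p.value,
              method = "fisher_exact", n_used = n_used, estimate = or)
}

#' Exact (Clopper-Pearson) confidence interval for a response rate
#'
#' The default interval inverts the exact binomial test via beta-distribution
#' quantiles; `method = "wilson"` gives the Wilson score interval instead.
#'
#' @param successes,n Integer counts, `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return A list: `successes`, `n`, `rate`, `ci_low`, `ci_high`, `level`,
#'   `method`.
#' @export
binomial_ci <- function(successes, n, level = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (n < 1L || successes < 0L || successes > n) {
    mp_stop("need 0 <= successes <= n and n >= 1")
  }
  a <- (1 - level) / 2
  rate <- successes / n
  if (method == "clopper-pearson") {
    lo <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
    hi <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  } else {
    z <- stats::qnorm(1 - a)
    centre <- (rate + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(rate * (1 - rate) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  }
  list(successes = as.integer(successes), n = as.integer(n), rate = rate,
       ci_low = lo, ci_high = hi, level = level, method = method)
}

#' Bonferroni adjustment of a single p-value
#'
#' @param p A p-value in \[0, 1\].
#' @param m Family size, `m >= 1`.
#' @return `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) mp_stop("p must be in [0, 1]")
  if (m < 1) mp_stop("family size m must be >= 1")
  pmin(1, m * p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Vector of p-values in \[0, 1\] (`NA` allowed; preserved).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    mp_stop("p-values must be in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# flat record shared by the univariate tests; serializes directly to JSON
test_result <- function(statistic, p_value, method, n_used, estimate = NA_real_) {
  list(statistic = statistic, p_value = p_value, method = method,
       n_used = as.integer(n_used), estimate = estimate)
}
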