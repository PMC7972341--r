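test_that("rank-sum test matches full enumeration on small groups", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "wilcoxon_exact")

  # identical multisets: p = 1 under the approximation too
  r2 <- wilcoxon_rank_sum(c(1, 5, 9), c(1, 5, 9))
  expect_gt(r2$p_value, 0.99)

  # tied data routes to the tie-corrected normal approximation and stays
  # close to the enumeration p
  r3 <- wilcoxon_rank_sum(c(1, 1, 2), c(2, 3, 3))
  expect_equal(r3$method, "wilcoxon_normal_approx")
  expect_lt(abs(r3$p_value - enum_wilcoxon_p(c(1, 1, 2), c(2, 3, 3))), 0.15)

  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(4 + i); b <- rnorm(5)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, enum_wilcoxon_p(a, b))
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("spearman correlation equals rank-then-pearson with t-approx p", {
  expect_equal(spearman_corr(1:6, (1:6)^2)$estimate, 1)
  expect_equal(spearman_corr(1:6, -(1:6)^3)$estimate, -1)

  set.seed(7)
  x <- rnorm(5); y <- rnorm(5)
  r <- spearman_corr(x, y)
  rho <- cor(rank(x), rank(y))
  expect_equal(r$estimate, rho, tolerance = 1e-12)
  tstat <- rho * sqrt((5 - 2) / (1 - rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-9)

  flat <- spearman_corr(rep(1, 5), rnorm(5))
  expect_equal(flat$method, "spearman_degenerate")
  expect_true(is.na(flat$estimate))
})

test_that("fisher exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / choose(20, 10))
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact_2x2(tab)$p_value, enum_fisher_p(tab))

  set.seed(3)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    r <- fisher_exact_2x2(tab)
    expect_equal(r$p_value, enum_fisher_p(tab), tolerance = 1e-9)
    # invariant to simultaneous row and column swap
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p_value, r$p_value)
  }

  expect_equal(fisher_exact_2x2(matrix(c(3, 2, 6, 4), 2))$estimate,
               (3 * 4) / (2 * 6))
  zero <- fisher_exact_2x2(matrix(c(4, 0, 2, 3), 2))
  expect_equal(zero$estimate, (4.5 * 3.5) / (0.5 * 2.5))
  degen <- fisher_exact_2x2(matrix(c(0, 0, 5, 5), 2))
  expect_equal(degen$p_value, 1)
  expect_equal(degen$method, "fisher_degenerate")
})

test_that("exact binomial intervals match the beta closed forms", {
  z <- binomial_ci(0, 10)
  expect_equal(z$ci_low, 0)
  expect_equal(z$ci_high, 1 - 0.025^(1 / 10))
  expect_equal(binomial_ci(10, 10)$ci_high, 1)

  ci <- binomial_ci(7, 20)
  bt <- binom.test(7, 20)$conf.int
  expect_equal(ci$ci_low, bt[1], tolerance = 1e-10)
  expect_equal(ci$ci_high, bt[2], tolerance = 1e-10)
  expect_true(ci$ci_low <= ci$rate && ci$rate <= ci$ci_high)

  w <- binomial_ci(7, 20, method = "wilson")
  expect_true(w$ci_low > 0 && w$ci_high < 1 && w$ci_low < ci$rate)
  expect_error(binomial_ci(3, 0), "n >= 1")
})

test_that("p-value adjustments follow the step-up/cap arithmetic", {
  expect_equal(bonferroni_adjust(0.012, 4), 0.048)
  expect_equal(bonferroni_adjust(0.5, 4), 1)
  expect_equal(bonferroni_adjust(0.01, 1), 0.01)

  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)

  set.seed(9)
  p <- runif(25)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_false(is.unsorted(q[order(p)]))  # rank-preserving
  expect_true(all(bonferroni_adjust(p, length(p)) >= q))
})
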