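test_that("the product-limit estimate matches hand computation", {
  km <- km_estimate(c(1, 2, 3, 4, 5), rep(1, 5))
  expect_equal(km$curve$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)
  expect_equal(km$curve$survival[1], 1 - 1 / 5)

  # all-event data: KM equals the empirical survival function
  set.seed(2)
  t <- rexp(40)
  km2 <- km_estimate(t, rep(1, 40))
  ecdf_surv <- vapply(km2$curve$time, function(x) mean(t > x), numeric(1))
  expect_equal(km2$curve$survival, ecdf_surv, tolerance = 1e-12)

  # no events: survival stays 1, median undefined
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$curve$survival == 1) || nrow(km3$curve) == 0)
  expect_true(is.na(km3$median))

  expect_error(km_estimate(numeric(0), numeric(0)), "no observations")
})

test_that("log-rank test matches the risk-set oracle and df contract", {
  t <- c(1, 3, 5, 2, 4, 6)
  e <- c(1, 1, 1, 0, 1, 1)
  g <- rep(c("A", "B"), each = 3)
  r <- logrank_test(t, e, g)
  expect_equal(r$chi2, enum_logrank_chi2(t, e, g), tolerance = 1e-9)
  expect_equal(r$df, 1)
  # label swap leaves the statistic unchanged
  expect_equal(logrank_test(t, e, rev(g))$chi2,
               logrank_test(t, e, ifelse(rev(g) == "A", "B", "A"))$chi2)

  # identical data in both groups: no signal
  r0 <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("A", "B"), 3))
  expect_lt(r0$chi2, 1e-9)

  ch <- sim_both(n = 120, seed = 5)
  d <- ch$data
  q <- assign_quadrants(dichotomize(d$m1, marker_spec("m1"))$levels,
                        dichotomize(d$m2, marker_spec("m2"))$levels)
  r4 <- logrank_test(d$os_time, d$os_event, q$assignment$quadrant)
  expect_equal(r4$df, 3)
  expect_error(logrank_test(1:3, c(1, 1, 1), rep("A", 3)), "two")
})

test_that("Cox fitting recovers known hazard ratios and handles ties", {
  set.seed(31)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = 0.1 * exp(log(2) * x))
  f <- fit_cox(t, rep(1, n), data.frame(x = x))
  expect_lt(abs(f$coefficients["x"] - log(2)), 3 * f$se["x"])

  # regressor identically 0: null model likelihood
  f0 <- fit_cox(t[1:50], rep(1, 50), data.frame(x = rep(0, 50)))
  fnull <- fit_cox(t[1:50], rep(1, 50))
  expect_equal(unname(f0$coefficients["x"]), 0)
  expect_equal(f0$loglik, fnull$loglik, tolerance = 1e-9)

  # tied event times: Efron and Breslow differ; untied data agree
  tt <- rep(1:5, each = 4)
  xx <- rnorm(20)
  fe <- fit_cox(tt, rep(1, 20), data.frame(x = xx), ties = "efron")
  fb <- fit_cox(tt, rep(1, 20), data.frame(x = xx), ties = "breslow")
  expect_false(isTRUE(all.equal(fe$coefficients, fb$coefficients)))
  tu <- seq_len(20)
  expect_equal(fit_cox(tu, rep(1, 20), data.frame(x = xx))$coefficients,
               fit_cox(tu, rep(1, 20), data.frame(x = xx),
                       ties = "breslow")$coefficients,
               tolerance = 1e-8)

  expect_error(fit_cox(1:5, rep(0, 5), data.frame(x = 1:5)), "no events")
})

test_that("monotone likelihood is flagged", {
  t <- 1:12
  x <- 12:1  # perfectly orders the events
  f <- fit_cox(t, rep(1, 12), data.frame(x = x))
  expect_false(is.null(f$flag))
})

test_that("the concordance probability estimate matches brute force", {
  expect_equal(cpe(c(0, 0, 0))$cpe, 0.5)
  expect_equal(cpe(c(0, log(3)))$cpe, 0.75)
  expect_equal(cpe(c(0, 0, log(3)))$cpe, (0.5 + 0.75 + 0.75) / 3)

  set.seed(8)
  for (n in c(20, 200)) {
    eta <- rnorm(n)
    r <- cpe(eta)
    expect_equal(r$cpe, brute_cpe(eta), tolerance = 1e-12)
    expect_equal(r$n_pairs, n * (n - 1) / 2)
  }
  expect_error(cpe(1), "two samples")
})

test_that("the four-model Cox family honors its contracts", {
  ch <- sim_both(n = 200, seed = 17)
  fm <- four_model_cox(ch, "m1", "m2")
  expect_equal(fm$status, "evaluated")
  cmp <- fm$comparisons
  expect_true(all(cmp$stat >= 0))
  expect_equal(cmp$df[cmp$comparison == "dual_int_vs_dual_add"], 1L)
  expect_true(all(vapply(fm$performance, function(p) p$cpe, numeric(1)) >= 0.5 - 1e-9))

  few_events <- simulate_cohort(sim_config(n = 30, seed = 2,
                                           censor_rate = 5))
  expect_equal(four_model_cox(few_events, "m1", "m2")$status, "skipped")
})

test_that("conditional KM tests equal independent log-rank on subsets", {
  ch <- sim_both(n = 160, seed = 23)
  res <- conditional_km(ch, "m1", "m2")
  expect_equal(nrow(res), 4)
  expect_equal(res$p_adjusted, pmin(1, 4 * res$p_value))

  d <- ch$data
  l1 <- dichotomize(d$m1, marker_spec("m1"))$levels
  l2 <- dichotomize(d$m2, marker_spec("m2"))$levels
  idx <- l1 == "high"
  manual <- logrank_test(d$os_time[idx], d$os_event[idx], l2[idx])
  expect_equal(res$p_value[res$comparison == "m2_by_m1_within_high"],
               manual$p_value, tolerance = 1e-12)
  idx2 <- l2 == "low"
  manual2 <- logrank_test(d$os_time[idx2], d$os_event[idx2], l1[idx2])
  expect_equal(res$p_value[res$comparison == "m1_by_m2_within_low"],
               manual2$p_value, tolerance = 1e-12)
})

test_that("quadrant survival stats agree with per-quadrant KM and Fisher", {
  ch <- sim_both(n = 160, seed = 29)
  qs <- quadrant_survival_stats(ch, "m1", "m2")
  expect_equal(nrow(qs$quadrants), 4)

  d <- ch$data
  l1 <- dichotomize(d$m1, marker_spec("m1"))$levels
  l2 <- dichotomize(d$m2, marker_spec("m2"))$levels
  idx <- l1 == "high" & l2 == "high"
  km <- km_estimate(d$os_time[idx], d$os_event[idx])
  expect_equal(qs$quadrants$median[qs$quadrants$quadrant == "R1"], km$median)

  expect_equal(qs$independence$p_value,
               fisher_exact_2x2(as.matrix(table(l1, l2)))$p_value)
})
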