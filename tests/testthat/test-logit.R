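test_that("logistic fits reproduce closed-form estimates", {
  # intercept-only: 6 responders of 10 -> intercept = log-odds
  f0 <- fit_logistic(c(rep(1, 6), rep(0, 4)))
  expect_equal(unname(f0$coefficients["(Intercept)"]), log(6 / 4),
               tolerance = 1e-8)

  # grouped 2x2: coefficient = log of the sample odds ratio
  x <- c(rep(1, 40), rep(0, 40))
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  f1 <- fit_logistic(y, data.frame(x = x))
  expect_equal(unname(f1$coefficients["x"]), log(9), tolerance = 1e-7)

  expect_error(fit_logistic(rep(1, 10)), "constant")
})

test_that("perfect separation is flagged, not reported as a finite effect", {
  x <- c(1:10)
  y <- as.numeric(x > 5)
  f <- fit_logistic(y, data.frame(x = x))
  expect_equal(f$flag, "separation")
})

test_that("DeLong AUC equals brute-force pair counting", {
  expect_equal(roc_auc_delong(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc_delong(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(roc_auc_delong(rep(2, 8), rep(c(0, 1), 4))$auc, 0.5)

  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    r <- roc_auc_delong(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-12)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
    expect_true(r$ci_low >= 0 && r$ci_high <= 1)
  }
  expect_error(roc_auc_delong(1:4, rep(1, 4)), "both classes")
})

test_that("likelihood-ratio comparison matches the chi-square tail", {
  mk <- function(ll, k, n = 100) {
    markerpair:::new_model_fit("logit", "t", setNames(rep(0, k), paste0("b", seq_len(k))),
                               rep(1, k), ll, n, TRUE)
  }
  r <- lrt(mk(-50, 2), mk(-52, 1))
  expect_equal(r$stat, 4)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, pchisq(4, 1, lower.tail = FALSE))

  expect_equal(lrt(mk(-50, 2), mk(-50, 1))$p_value, 1)
  r2 <- lrt(mk(-50, 3), mk(-52, 1))
  expect_equal(r2$df, 2)
  expect_equal(r2$p_value, pchisq(4, 2, lower.tail = FALSE))

  expect_error(lrt(mk(-50, 2, n = 100), mk(-52, 1, n = 90)), "complete-case")
})

test_that("the four-model logistic family honors its contracts", {
  ch <- sim_both(n = 200, seed = 21)
  fm <- four_model_logit(ch, "m1", "m2")
  expect_equal(fm$status, "evaluated")
  ns <- vapply(fm$fits, function(f) f$n_used, integer(1))
  expect_true(all(ns == fm$n_used))
  cmp <- fm$comparisons
  expect_equal(cmp$df[cmp$comparison == "dual_add_vs_m1"], 1L)
  expect_equal(cmp$df[cmp$comparison == "dual_int_vs_m1"], 2L)
  expect_true(all(cmp$stat >= 0))
  # training AUC of the interaction model >= the single-marker model
  expect_gte(fm$performance$dual_int$auc, fm$performance$m1$auc - 1e-12)

  # LRT statistic is invariant to affine rescaling of a continuous marker
  d <- ch$data
  d$m1 <- 100 + 7 * d$m1
  ch2 <- cohort(d, sample_id = "sample_id", response = "response",
                time = "os_time", event = "os_event",
                markers = c("m1", "m2"), response_coding = "1")
  fm2 <- four_model_logit(ch2, "m1", "m2")
  expect_equal(fm2$comparisons$stat, fm$comparisons$stat, tolerance = 1e-6)
})

test_that("degenerate pairs are skipped with a reason", {
  ch <- sim_both(n = 100, seed = 3)
  d <- ch$data
  d$m1_copy <- d$m1
  ch2 <- cohort(d, sample_id = "sample_id", response = "response",
                markers = c("m1", "m2", "m1_copy"), response_coding = "1")
  fm <- four_model_logit(ch2, "m1", "m1_copy")
  expect_equal(fm$status, "skipped")
  expect_match(fm$reason, "collinear")

  small <- cohort(d[1:10, ], sample_id = "sample_id", response = "response",
                  markers = c("m1", "m2"), response_coding = "1")
  expect_equal(four_model_logit(small, "m1", "m2")$status, "skipped")
})

test_that("covariates enter every model additively", {
  ch <- simulate_cohort(sim_config(
    n = 300, seed = 13, b1 = 0.6,
    covariates = list(age = list(dist = "normal", mean = 60, sd = 8,
                                 b = 0.05, g = 0.01))
  ))
  fm <- four_model_cov <- four_model_logit(ch, "m1", "m2",
                                           covariates = "age")
  expect_equal(fm$status, "evaluated")
  for (f in fm$fits) expect_true("age" %in% names(f$coefficients))
})
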