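test_that("signed -log10 p encodes magnitude and direction", {
  expect_equal(signed_log10_p(0.01, "favorable"), 2)
  expect_equal(signed_log10_p(0.01, "unfavorable"), -2)
  expect_equal(signed_log10_p(1, "favorable"), 0)
  expect_equal(signed_log10_p(0, "favorable"), 300)
  expect_equal(signed_log10_p(0, "unfavorable", cap = 50), -50)
  expect_error(signed_log10_p(1.2, "favorable"), "0, 1")
})

test_that("search_m2 applies the min-p rule and BH over evaluated rows", {
  panel <- simulate_search_panel(
    sim_config(n = 250, seed = 41, b1 = 0.6, b2 = 1, n_decoy = 8),
    n_true = 1
  )
  res <- search_m2(panel$cohort, "m1",
                   panel$truth$marker, search_config("logit"))
  expect_equal(nrow(res), 9)
  ev <- res[res$status == "evaluated", ]
  expect_true(all(ev$p_dual_vs_m1 <= 1 & ev$p_dual_vs_m1 >= 0))
  # min contract: the reported p never exceeds the additive comparison's p
  for (i in seq_len(nrow(ev))) {
    fm <- four_model_logit(panel$cohort, "m1", ev$m2_name[i])
    p_add <- fm$comparisons$p_value[fm$comparisons$comparison == "dual_add_vs_m1"]
    p_int <- fm$comparisons$p_value[fm$comparisons$comparison == "dual_int_vs_m1"]
    expect_equal(ev$p_dual_vs_m1[i], min(p_add, p_int), tolerance = 1e-12)
  }
  # sorted ascending, BH columns rank-preserving and >= raw
  expect_false(is.unsorted(ev$p_dual_vs_m1))
  expect_true(all(ev$adj_p_dual_vs_m1 >= ev$p_dual_vs_m1 - 1e-15))
  expect_equal(ev$adj_p_dual_vs_m1,
               unname(bh_adjust(ev$p_dual_vs_m1)))
  # the planted partner wins
  expect_equal(ev$m2_name[1], "cand_01")
})

test_that("a candidate collinear with m1 is skipped, not scored", {
  ch <- sim_both(n = 120, seed = 9)
  d <- ch$data
  d$m1_twin <- d$m1 * 2 + 1
  ch2 <- cohort(d, sample_id = "sample_id", response = "response",
                time = "os_time", event = "os_event",
                markers = c("m1", "m2", "m1_twin"), response_coding = "1")
  res <- search_m2(ch2, "m1", c("m2", "m1_twin"), search_config("logit"))
  row <- res[res$m2_name == "m1_twin", ]
  expect_match(row$status, "skipped\\(collinear")
  expect_true(is.na(row$p_dual_vs_m1))
  expect_error(search_m2(ch2, "m1", "m1"), "no candidates")
})

test_that("comb_m enumerates unordered pairs consistently with search_m2", {
  ch <- simulate_cohort(sim_config(n = 150, seed = 51, b1 = 0.5,
                                   n_decoy = 3))
  cand <- c("m1", "m2", sprintf("decoy_%02d", 1:3))
  res <- comb_m(ch, cand, search_config("logit"))
  expect_equal(nrow(res), choose(5, 2))
  # lexicographic M1 convention
  expect_true(all(res$m1_name < res$m2_name))

  pair <- res[res$m1_name == "decoy_01" & res$m2_name == "m2", ]
  single <- search_m2(ch, "decoy_01", "m2", search_config("logit"))
  for (col in c("p_dual_vs_m1", "p_dual_vs_m2", "interaction_p",
                "perf_dual_add", "perf_dual_int")) {
    expect_equal(pair[[col]], single[[col]], tolerance = 1e-12)
  }

  # identical call -> identical table (deterministic ordering)
  res2 <- comb_m(ch, cand, search_config("logit"))
  expect_identical(res, res2)
})

test_that("the cox family search scores survival partners", {
  panel <- simulate_search_panel(
    sim_config(n = 250, seed = 61, g1 = -0.4, g2 = -0.8, n_decoy = 5),
    n_true = 1
  )
  res <- search_m2(panel$cohort, "m1", panel$truth$marker,
                   search_config("cox"))
  ev <- res[res$status == "evaluated", ]
  expect_gt(nrow(ev), 0)
  expect_equal(ev$m2_name[1], "cand_01")
  # protective marker (negative log-hazard): favorable, positive sign
  top <- ev[ev$m2_name == "cand_01", ]
  expect_equal(top$m2_single_direction, "favorable")
  expect_gt(top$signed_log10_p, 0)
  expect_true(all(ev$perf_dual_add >= 0.5 - 1e-9))
})
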