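test_that("a small table loads into a validated cohort", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("a", "b", "c"), resp = c(1, 0, 1),
                       os_time = c(3, 5, 7), os_event = c(1, 0, 1),
                       tmb = c(4, 8, 2)),
            path, row.names = FALSE)
  ch <- load_cohort(path, sample_id = "id", response = "resp",
                    time = "os_time", event = "os_event", markers = "tmb",
                    response_coding = "1")
  expect_s3_class(ch, "mp_cohort")
  expect_equal(nrow(ch$data), 3)
  expect_equal(ch$markers, "tmb")
  expect_equal(ch$data$.response, c(1, 0, 1))
  expect_true(all(c("column", "n_missing") %in% names(ch$load_report)))
})

test_that("validation rejects bad outcomes, naming the problem", {
  d <- tiny_cohort_df()
  d3 <- d; d3$resp <- c("CR", "PR", "SD", "CR", "PR", "SD")
  expect_error(
    cohort(d3, sample_id = "id", response = "resp", markers = "tmb"),
    "unsupported"
  )
  dneg <- d; dneg$os_time[4] <- -1
  expect_error(
    cohort(dneg, sample_id = "id", time = "os_time", event = "os_event",
           markers = "tmb"),
    "row.*4"
  )
  expect_error(
    cohort(d, sample_id = "id", response = "nope", markers = "tmb"),
    "nope"
  )
  expect_error(
    cohort(d, sample_id = "id", markers = "tmb"),
    "outcome"
  )
  ddup <- d; ddup$id[2] <- "a"
  expect_error(
    cohort(ddup, sample_id = "id", response = "resp", markers = "tmb",
           response_coding = "1"),
    "unique"
  )
})

test_that("median dichotomization uses strict > with a configurable tie rule", {
  d <- dichotomize(c(1, 2, 3, 4, 5), marker_spec("x"))
  expect_equal(d$cutpoint, 3)
  expect_equal(as.character(d$levels), c("low", "low", "low", "high", "high"))

  d2 <- dichotomize(c(-2, 5), marker_spec("x", cutoff = 0))
  expect_equal(as.character(d2$levels), c("low", "high"))

  expect_error(dichotomize(c(7, 7, 7, 7), marker_spec("x")), "constant")

  dge <- dichotomize(c(1, 2, 3, 4, 5), marker_spec("x", strict_gt = FALSE))
  expect_equal(as.character(dge$levels),
               c("low", "low", "high", "high", "high"))

  # odd n with distinct values: exactly floor(n/2) samples are high
  for (n in c(5, 9, 13)) {
    dd <- dichotomize(sample(seq_len(n)), marker_spec("x"))
    expect_equal(sum(dd$levels == "high"), n %/% 2)
  }
})

test_that("missing values propagate and binary markers honor positive_level", {
  d <- dichotomize(c(1, NA, 5), marker_spec("x"))
  expect_true(is.na(d$levels[2]))

  db <- dichotomize(c("mut", "wt", "wt"),
                    marker_spec("g", kind = "binary", positive_level = "mut"))
  expect_equal(as.character(db$levels), c("high", "low", "low"))
  expect_error(
    dichotomize(c("mut", "wt"),
                marker_spec("g", kind = "binary", positive_level = "amp")),
    "positive_level"
  )
  # idempotence: dichotomizing an already high/low vector reproduces it
  again <- dichotomize(as.character(db$levels),
                       marker_spec("g", kind = "binary",
                                   positive_level = "high"))
  expect_equal(as.character(again$levels), as.character(db$levels))
})

test_that("quadrant assignment follows the R1-R4 mapping and partitions", {
  qa <- assign_quadrants(c("high", "low", "low", "high"),
                         c("low", "high", "low", "high"))
  expect_equal(as.character(qa$assignment$quadrant),
               c("R4", "R2", "R3", "R1"))

  set.seed(42)
  l <- c("low", "high", NA)
  for (rep in 1:20) {
    m1 <- sample(l, 30, replace = TRUE)
    m2 <- sample(l, 30, replace = TRUE)
    qa <- assign_quadrants(m1, m2)
    expect_equal(sum(qa$counts) + qa$n_excluded, 30)
    expect_equal(sum(qa$counts), sum(!is.na(m1) & !is.na(m2)))
  }
  expect_error(assign_quadrants(c("hi"), c("low")), "levels")
  expect_error(assign_quadrants(c("high"), c("low", "high")), "length")
})
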