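#' Configuration of the synthetic-cohort generator
#'
#' Defines a cohort with known logistic and proportional-hazards structure,
#' emulating an immunotherapy-trial table (binary response plus overall
#' survival, continuous and binary markers). Response is drawn from
#' \eqn{logit P(resp) = b_0 + b_1 M_1 + b_2 M_2 + b_{12} M_1 M_2} and event
#' times from an exponential proportional-hazards model with baseline rate
#' `lambda0` and log-hazard effects `g1`, `g2`, `g12`; censoring is
#' exponential with rate `censor_rate` and/or administrative at
#' `admin_time`. Decoy markers are independent standard normals.
#'
#' Defaults describe a mid-sized checkpoint-blockade-like cohort: n = 200,
#' standard-normal markers, a ~30% responder rate (`b0 = -0.85`), median
#' baseline survival 12 time units, and exponential censoring at 3/7 of the
#' baseline hazard (about 30% censored under the null).
#'
#' @param n Cohort size.
#' @param seed Integer seed; fully determines the generated table.
#' @param m1,m2 Marker generators: list with `dist` in
#'   `"normal"`/`"lognormal"`/`"bernoulli"` and its parameters (`mean`,`sd`;
#'   `meanlog`,`sdlog`; `p`).
#' @param b0,b1,b2,b12 Logistic intercept, marker and interaction effects.
#' @param g1,g2,g12 Log-hazard marker and interaction effects.
#' @param lambda0 Baseline exponential event rate (> 0).
#' @param censor_rate Exponential censoring rate (0 disables).
#' @param admin_time Administrative censoring time (Inf disables).
#' @param covariates Named list of covariate generators, each a marker-style
#'   `dist` list plus optional `b` (logistic effect) and `g` (log-hazard
#'   effect).
#' @param n_decoy Number of null candidate markers (`decoy_01`, ...).
#' @return A list of class `mp_sim_config`.
#' @export
sim_config <- function(n = 200, seed = 1,
                       m1 = list(dist = "normal", mean = 0, sd = 1),
                       m2 = list(dist = "normal", mean = 0, sd = 1),
                       b0 = -0.85, b1 = 0, b2 = 0, b12 = 0,
                       g1 = 0, g2 = 0, g12 = 0,
                       lambda0 = log(2) / 12,
                       censor_rate = 3 / 7 * log(2) / 12,
                       admin_time = Inf,
                       covariates = list(), n_decoy = 0) {
  if (n < 1) mp_stop("n must be >= 1")
  if (lambda0 <= 0) mp_stop("lambda0 must be > 0")
  if (censor_rate < 0) mp_stop("censor_rate must be >= 0")
  structure(
    list(n = as.integer(n), seed = as.integer(seed), m1 = m1, m2 = m2,
         b0 = b0, b1 = b1, b2 = b2, b12 = b12,
         g1 = g1, g2 = g2, g12 = g12,
         lambda0 = lambda0, censor_rate = censor_rate,
         admin_time = admin_time, covariates = covariates,
         n_decoy = as.integer(n_decoy)),
    class = "mp_sim_config"
  )
}

draw_marker <- function(n, gen) {
  switch(gen$dist,
    normal = stats::rnorm(n, gen$mean %||% 0, gen$sd %||% 1),
    lognormal = stats::rlnorm(n, gen$meanlog %||% 0, gen$sdlog %||% 1),
    bernoulli = {
      p <- gen$p %||% 0.5
      if (p <= 0 || p >= 1) mp_stop("bernoulli p must be in (0, 1)")
      stats::rbinom(n, 1, p)
    },
    mp_stop(paste0("unknown marker distribution: ", gen$dist))
  )
}

#' Simulate a cohort with known dual-marker structure
#'
#' @param config An [sim_config()].
#' @return An `mp_cohort` with markers `m1`, `m2` (plus any decoys),
#'   response column `response`, survival columns `os_time`/`os_event`, and
#'   the configured covariates. The same config (including seed) always
#'   yields the identical table.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "mp_sim_config")) mp_stop("expected an mp_sim_config")
  set.seed(config$seed)
  n <- config$n
  x1 <- draw_marker(n, config$m1)
  x2 <- draw_marker(n, config$m2)
  d <- tibble::tibble(sample_id = sprintf("S%04d", seq_len(n)),
                      m1 = x1, m2 = x2)
  lp_resp <- config$b0 + config$b1 * x1 + config$b2 * x2 +
    config$b12 * x1 * x2
  lp_surv <- config$g1 * x1 + config$g2 * x2 + config$g12 * x1 * x2
  for (nm in names(config$covariates)) {
    cv <- config$covariates[[nm]]
    z <- draw_marker(n, cv)
    d[[nm]] <- z
    lp_resp <- lp_resp + (cv$b %||% 0) * z
    lp_surv <- lp_surv + (cv$g %||% 0) * z
  }
  d$response <- stats::rbinom(n, 1, stats::plogis(lp_resp))
  t_event <- stats::rexp(n, rate = config$lambda0 * exp(lp_surv))
  t_cens <- if (config$censor_rate > 0) {
    stats::rexp(n, rate = config$censor_rate)
  } else {
    rep(Inf, n)
  }
  t_cens <- pmin(t_cens, config$admin_time)
  d$os_time <- pmin(t_event, t_cens)
  d$os_event <- as.integer(t_event <= t_cens)
  if (config$n_decoy > 0) {
    for (k in seq_len(config$n_decoy)) {
      d[[sprintf("decoy_%02d", k)]] <- stats::rnorm(n)
    }
  }
  cohort(d, sample_id = "sample_id", response = "response",
         time = "os_time", event = "os_event",
         markers = c("m1", "m2",
                     if (config$n_decoy > 0) sprintf("decoy_%02d", seq_len(config$n_decoy))),
         covariates = names(config$covariates),
         response_coding = "1")
}

#' Simulate a candidate panel with known true partners
#'
#' Builds a search test bed: a fixed marker `m1` plus a candidate panel of
#' which `n_true` markers carry the configured M2 effect (`b2`/`b12` on
#' response, `g2`/`g12` on the hazard — all true partners share them) and
#' the rest are independent standard-normal decoys. Truth labels are
#' returned for ranking evaluation.
#'
#' @param config An [sim_config()]; `n_decoy` is the number of null
#'   candidates.
#' @param n_true Number of true partner markers.
#' @return A list: `cohort` (markers `m1`, `cand_01`, ...) and `truth`
#'   (tibble `marker`/`is_true`). True candidates are placed first
#'   (`cand_01` ... `cand_<n_true>`).
#' @export
simulate_search_panel <- function(config = sim_config(n_decoy = 50),
                                  n_true = 1) {
  if (!inherits(config, "mp_sim_config")) mp_stop("expected an mp_sim_config")
  k <- config$n_decoy + n_true
  if (n_true < 0 || k < 1) mp_stop("need at least one candidate")
  set.seed(config$seed)
  n <- config$n
  x1 <- draw_marker(n, config$m1)
  cand <- matrix(stats::rnorm(n * k), nrow = n)
  colnames(cand) <- sprintf("cand_%02d", seq_len(k))
  true_idx <- seq_len(n_true)
  lp_resp <- config$b0 + config$b1 * x1
  lp_surv <- config$g1 * x1
  for (j in true_idx) {
    lp_resp <- lp_resp + config$b2 * cand[, j] + config$b12 * x1 * cand[, j]
    lp_surv <- lp_surv + config$g2 * cand[, j] + config$g12 * x1 * cand[, j]
  }
  d <- tibble::as_tibble(as.data.frame(cand))
  d$sample_id <- sprintf("S%04d", seq_len(n))
  d$m1 <- x1
  d$response <- stats::rbinom(n, 1, stats::plogis(lp_resp))
  t_event <- stats::rexp(n, rate = config$lambda0 * exp(lp_surv))
  t_cens <- if (config$censor_rate > 0) {
    stats::rexp(n, rate = config$censor_rate)
  } else {
    rep(Inf, n)
  }
  t_cens <- pmin(t_cens, config$admin_time)
  d$os_time <- pmin(t_event, t_cens)
  d$os_event <- as.integer(t_event <= t_cens)
  ch <- cohort(d, sample_id = "sample_id", response = "response",
               time = "os_time", event = "os_event",
               markers = c("m1", colnames(cand)),
               response_coding = "1")
  list(cohort = ch,
       truth = tibble::tibble(marker = colnames(cand),
                              is_true = seq_len(k) %in% true_idx))
}

#' Write a simulated cohort to a delimited file
#'
#' Convenience for the command-line `simulate` workflow: the written CSV is
#' directly consumable by [load_cohort()].
#'
#' @param cohort An `mp_cohort`.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot_cohort(cohort)
  d <- cohort$data
  d$.response <- NULL
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(d, path)
  } else {
    readr::write_csv(d, path)
  }
  invisible(path)
}
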