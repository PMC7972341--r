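#' Per-quadrant response summary and marker-independence test
#'
#' The response-side quadrant statistics: per-quadrant sample size,
#' responders, response rate with exact (Clopper-Pearson) confidence
#' interval, and Fisher's exact test of independence on the 2x2 high/low
#' contingency of the two markers.
#'
#' @inheritParams four_model_logit
#' @param ci_method Passed to [binomial_ci()].
#' @return A list: `quadrants` (tibble: `quadrant`, `n`, `responders`,
#'   `rate`, `ci_low`, `ci_high`), `independence` (Fisher result), and
#'   `cutpoints` (named numeric, the realized dichotomization cutpoints).
#' @export
quadrant_response_stats <- function(cohort, m1, m2,
                                    ci_method = "clopper-pearson") {
  stopifnot_cohort(cohort)
  if (!has_response(cohort)) {
    mp_stop("cohort has no response outcome",
            class = "markerpair_validation_error")
  }
  m1 <- as_marker_spec(m1); m2 <- as_marker_spec(m2)
  d <- cohort$data
  d1 <- dichotomize(d[[m1$name]], m1)
  d2 <- dichotomize(d[[m2$name]], m2)
  y <- d$.response
  keep <- !is.na(d1$levels) & !is.na(d2$levels) & !is.na(y)
  qa <- assign_quadrants(d1$levels[keep], d2$levels[keep])
  qd <- qa$assignment$quadrant
  rows <- lapply(levels(qd), function(q) {
    idx <- qd == q
    nq <- sum(idx)
    if (nq == 0L) {
      return(tibble::tibble(quadrant = q, n = 0L, responders = 0L,
                            rate = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_))
    }
    ci <- binomial_ci(sum(y[keep][idx]), nq, method = ci_method)
    tibble::tibble(quadrant = q, n = nq, responders = ci$successes,
                   rate = ci$rate, ci_low = ci$ci_low, ci_high = ci$ci_high)
  })
  counts <- table(m1 = d1$levels[keep], m2 = d2$levels[keep])
  list(quadrants = dplyr::bind_rows(rows),
       independence = fisher_exact_2x2(as.matrix(counts)),
       cutpoints = c(m1 = d1$cutpoint, m2 = d2$cutpoint))
}

# KM curves of one dichotomized marker (high vs low) plus the log-rank test
km_by_level <- function(times, events, levels) {
  keep <- !is.na(times) & !is.na(events) & !is.na(levels)
  curves <- lapply(c("low", "high"), function(lv) {
    idx <- keep & levels == lv
    if (sum(idx) == 0L) return(NULL)
    km <- km_estimate(times[idx], events[idx])
    km$curve$group <- lv
    km
  })
  names(curves) <- c("low", "high")
  curves <- compact(curves)
  lr <- if (length(curves) == 2L && sum(events[keep]) >= 1L) {
    logrank_test(times[keep], events[keep], levels[keep])
  } else {
    NULL
  }
  list(curves = curves, logrank = lr)
}

#' Build the full statistics report for one marker pair
#'
#' Computes every number behind the pair-report figure bundle: the response
#' section (per-marker boxplot data with Wilcoxon tests, the inter-marker
#' scatter with Spearman correlation, ROC data for all four logistic models,
#' quadrant sizes with Fisher independence test, exact response-rate
#' intervals, doughnut fractions and interaction line chart) and the
#' survival section (single-marker, quadrant and conditional Kaplan-Meier
#' curves with log-rank tests, per-quadrant median survival, the interaction
#' line chart) plus both four-model fits. Sections whose outcome is absent
#' from the cohort are omitted; rendering is a separate, side-effect-only
#' step ([render_pair_report()]), so every plotted number lives here.
#'
#' @inheritParams four_model_logit
#' @return An object of class `mp_pair_report`.
#' @export
build_pair_report <- function(cohort, m1, m2, covariates = character(),
                              min_n = 20, min_events = 10) {
  stopifnot_cohort(cohort)
  if (!has_response(cohort) && !has_survival(cohort)) {
    mp_stop("cohort has neither response nor survival outcome",
            class = "markerpair_validation_error")
  }
  m1 <- as_marker_spec(m1); m2 <- as_marker_spec(m2)
  d <- cohort$data
  d1 <- dichotomize(d[[m1$name]], m1)
  d2 <- dichotomize(d[[m2$name]], m2)
  x1 <- marker_regressor(d[[m1$name]], d1$spec)
  x2 <- marker_regressor(d[[m2$name]], d2$spec)

  response_section <- NULL
  if (has_response(cohort)) {
    y <- d$.response
    box <- lapply(list(m1 = x1, m2 = x2), function(x) {
      keep <- !is.na(x) & !is.na(y)
      list(data = tibble::tibble(value = x[keep],
                                 response = factor(y[keep], levels = 0:1,
                                                   labels = c("neg", "pos"))),
           wilcoxon = wilcoxon_rank_sum(x[keep][y[keep] == 1],
                                        x[keep][y[keep] == 0]))
    })
    keep_xy <- !is.na(x1) & !is.na(x2) & !is.na(y)
    scatter <- list(
      data = tibble::tibble(m1 = x1[keep_xy], m2 = x2[keep_xy],
                            response = factor(y[keep_xy], levels = 0:1,
                                              labels = c("neg", "pos"))),
      spearman = spearman_corr(x1[keep_xy], x2[keep_xy])
    )
    fm_logit <- four_model_logit(cohort, m1, m2, covariates,
                                 min_n = min_n)
    roc <- NULL
    if (fm_logit$status == "evaluated") {
      yy <- NULL
      roc_curves <- lapply(names(fm_logit$fits), function(nm) {
        f <- fm_logit$fits[[nm]]
        if (!is.null(f$flag)) return(NULL)
        labels <- f$fit$y
        r <- pROC::roc(response = labels, predictor = f$fitted,
                       levels = c(0, 1), direction = "<", quiet = TRUE)
        tibble::tibble(model = f$formula_tag,
                       fpr = 1 - r$specificities, tpr = r$sensitivities)
      })
      roc <- list(curves = dplyr::bind_rows(compact(roc_curves)),
                  auc = fm_logit$performance)
    }
    response_section <- list(
      boxplots = box, scatter = scatter, roc = roc,
      quadrants = quadrant_response_stats(cohort, m1, m2),
      four_model = fm_logit
    )
  }

  survival_section <- NULL
  if (has_survival(cohort)) {
    tt <- d[[cohort$time]]; ee <- d[[cohort$event]]
    km1 <- km_by_level(tt, ee, d1$levels)
    km2 <- km_by_level(tt, ee, d2$levels)
    keep_q <- !is.na(d1$levels) & !is.na(d2$levels) & !is.na(tt) & !is.na(ee)
    qa <- assign_quadrants(d1$levels[keep_q], d2$levels[keep_q])
    km_quad <- lapply(levels(qa$assignment$quadrant), function(q) {
      idx <- qa$assignment$quadrant == q
      if (sum(idx) == 0L) return(NULL)
      km_estimate(tt[keep_q][idx], ee[keep_q][idx])
    })
    names(km_quad) <- levels(qa$assignment$quadrant)
    cond <- lapply(c(m1_is = "m1", m2_is = "m2"), function(which_stratum) {
      strat <- if (which_stratum == "m1") d1$levels else d2$levels
      test <- if (which_stratum == "m1") d2$levels else d1$levels
      lapply(c(high = "high", low = "low"), function(sl) {
        idx <- !is.na(strat) & strat == sl
        km_by_level(tt[idx], ee[idx], test[idx])
      })
    })
    survival_section <- list(
      km_m1 = km1, km_m2 = km2,
      km_quadrants = compact(km_quad),
      quadrant_stats = quadrant_survival_stats(cohort, m1, m2),
      conditional_curves = cond,
      conditional_tests = conditional_km(cohort, m1, m2),
      four_model = four_model_cox(cohort, m1, m2, covariates,
                                  min_n = min_n, min_events = min_events)
    )
  }

  structure(
    list(m1 = d1$spec, m2 = d2$spec,
         cutpoints = c(m1 = d1$cutpoint, m2 = d2$cutpoint),
         covariates = covariates,
         response_section = response_section,
         survival_section = survival_section),
    class = "mp_pair_report"
  )
}

#' @export
print.mp_pair_report <- function(x, ...) {
  cat("<mp_pair_report> ", x$m1$name, " x ", x$m2$name, "\n", sep = "")
  cat("  sections: ",
      paste(c(if (!is.null(x$response_section)) "response",
              if (!is.null(x$survival_section)) "survival"),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# strip model objects and convert to plain lists for JSON serialization
four_model_stats <- function(fm) {
  if (is.null(fm)) return(NULL)
  if (fm$status == "skipped") {
    return(list(status = "skipped", reason = fm$reason, family = fm$family))
  }
  list(
    status = "evaluated", family = fm$family, n_used = fm$n_used,
    models = lapply(fm$fits, function(f) {
      list(formula = f$formula_tag,
           coefficients = as.list(f$coefficients),
           se = as.list(f$se), loglik = f$loglik,
           converged = f$converged, flag = f$flag)
    }),
    comparisons = as.data.frame(fm$comparisons),
    interaction_wald_p = fm$interaction_wald_p,
    performance = fm$performance
  )
}

km_stats <- function(km) {
  if (is.null(km)) return(NULL)
  list(n = km$n, n_events = km$n_events, median = km$median,
       median_ci_low = km$median_ci_low, median_ci_high = km$median_ci_high,
       curve = as.data.frame(km$curve))
}

#' Extract the serializable statistics of a pair report
#'
#' Returns the plain-list view of an `mp_pair_report` — every number shown
#' in any of the report's plots — suitable for `jsonlite::write_json()`.
#'
#' @param report An `mp_pair_report`.
#' @return A nested list of plain vectors and data frames.
#' @export
pair_report_stats <- function(report) {
  rs <- report$response_section
  ss <- report$survival_section
  km_group_stats <- function(kg) {
    list(curves = lapply(kg$curves, km_stats), logrank = kg$logrank)
  }
  compact(list(
    m1 = report$m1$name, m2 = report$m2$name,
    cutpoints = as.list(report$cutpoints),
    response = if (!is.null(rs)) compact(list(
      wilcoxon_m1 = rs$boxplots$m1$wilcoxon,
      wilcoxon_m2 = rs$boxplots$m2$wilcoxon,
      spearman = rs$scatter$spearman,
      auc = if (!is.null(rs$roc)) rs$roc$auc,
      quadrants = as.data.frame(rs$quadrants$quadrants),
      independence = rs$quadrants$independence,
      four_model = four_model_stats(rs$four_model)
    )),
    survival = if (!is.null(ss)) compact(list(
      km_m1 = km_group_stats(ss$km_m1),
      km_m2 = km_group_stats(ss$km_m2),
      km_quadrants = lapply(ss$km_quadrants, km_stats),
      quadrants = as.data.frame(ss$quadrant_stats$quadrants),
      logrank_quadrants = ss$quadrant_stats$logrank,
      independence = ss$quadrant_stats$independence,
      conditional = as.data.frame(ss$conditional_tests),
      four_model = four_model_stats(ss$four_model)
    ))
  ))
}
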