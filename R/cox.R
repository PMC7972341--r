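#' Kaplan-Meier estimate with Greenwood errors and median survival
#'
#' Product-limit survival estimate with Greenwood standard errors and
#' pointwise confidence intervals on the log-survival scale. The median is
#' the smallest observed time at which the estimate drops to 0.5 or below;
#' its confidence bounds come from intersecting the pointwise interval with
#' 0.5 (either side may be undefined and is then reported as `NA`).
#'
#' @param times Non-negative event/censoring times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @param level Confidence level (default 0.95).
#' @return An object of class `mp_km`: list with `curve` (tibble: `time`,
#'   `n_risk`, `n_event`, `survival`, `se`, `ci_low`, `ci_high`, at distinct
#'   event times), `median`, `median_ci_low`, `median_ci_high`, `n`,
#'   `n_events`.
#' @export
km_estimate <- function(times, events, level = 0.95) {
  keep <- stats::complete.cases(times, events)
  times <- times[keep]; events <- events[keep]
  if (length(times) == 0L) mp_stop("no observations for the KM estimate")
  if (any(times < 0)) mp_stop("negative survival times")
  if (!all(events %in% c(0, 1))) mp_stop("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "log", conf.int = level)
  sm <- summary(sf, censored = FALSE)
  num <- function(x) if (is.null(x)) numeric(0) else as.numeric(x)
  curve <- tibble::tibble(
    time = num(sm$time), n_risk = num(sm$n.risk), n_event = num(sm$n.event),
    survival = num(sm$surv), se = num(sm$std.err),
    ci_low = num(sm$lower), ci_high = num(sm$upper)
  )
  tab <- summary(sf)$table
  med <- unname(tab["median"])
  lcl <- unname(tab[grep("LCL", names(tab))])
  ucl <- unname(tab[grep("UCL", names(tab))])
  structure(
    list(curve = curve, median = med,
         median_ci_low = if (length(lcl)) lcl else NA_real_,
         median_ci_high = if (length(ucl)) ucl else NA_real_,
         n = length(times), n_events = sum(events), level = level),
    class = "mp_km"
  )
}

#' @export
print.mp_km <- function(x, ...) {
  cat("<mp_km> n=", x$n, " events=", x$n_events,
      " median=", format(x$median), " (",
      format(x$median_ci_low), "-", format(x$median_ci_high), ")\n", sep = "")
  invisible(x)
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square comparing the survival of k groups, with
#' hypergeometric variance at each distinct event time and k - 1 degrees of
#' freedom.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group labels, at least two non-empty groups.
#' @return A list: `chi2`, `df`, `p_value`, `n`.
#' @export
logrank_test <- function(times, events, groups) {
  keep <- stats::complete.cases(times, events, groups)
  times <- times[keep]; events <- events[keep]
  groups <- factor(as.character(groups[keep]))
  k <- nlevels(groups)
  if (k < 2L) mp_stop("log-rank test needs at least two non-empty groups")
  if (sum(events) < 1L) mp_stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- k - 1L
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       n = length(times))
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood fit with the Efron tie correction, Newton iterations
#' to a relative log-partial-likelihood tolerance of 1e-9 (at most 25
#' iterations). Monotone likelihood (a regressor that perfectly orders the
#' events, the survival analogue of separation) is flagged rather than
#' reported as a finite estimate.
#'
#' @param times,events As in [km_estimate()]; at least one event.
#' @param design Data frame of named numeric regressors (zero columns gives
#'   the null model, whose log partial likelihood is still reported).
#' @param formula_tag Label stored on the fit.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param coef_limit Absolute log-hazard size treated as divergence.
#' @return An `mp_model_fit` with the linear predictor in `lp` (centered as
#'   returned by the fit) and `loglik` the maximized log partial likelihood.
#' @export
fit_cox <- function(times, events, design = NULL, formula_tag = "M1",
                    ties = c("efron", "breslow"), coef_limit = 15) {
  ties <- match.arg(ties)
  if (!all(events %in% c(0, 1))) mp_stop("events must be 0/1")
  if (sum(events) < 1L) mp_stop("no events; cannot fit a Cox model")
  null_model <- is.null(design) || NCOL(design) == 0L
  df <- data.frame(.time = as.numeric(times), .event = as.numeric(events))
  if (!null_model) df <- cbind(df, as.data.frame(design))
  rhs <- if (null_model) "1" else paste(sprintf("`%s`", names(df)[-(1:2)]), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  flag <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 25)),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w))) {
        flag <<- "monotone_likelihood"
      }
      invokeRestart("muffleWarning")
    }
  )
  if (null_model) {
    return(new_model_fit(kind = "cox", formula_tag = formula_tag,
                         coefficients = numeric(0), se = numeric(0),
                         loglik = fit$loglik[1], n_used = nrow(df),
                         converged = TRUE,
                         lp = rep(0, nrow(df)), fit = fit))
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(is.na(cf))) {
    # unidentifiable (e.g. constant) regressors contribute nothing: report
    # them as zero effect with infinite uncertainty
    se[is.na(cf)] <- Inf
    cf[is.na(cf)] <- 0
  } else if (any(abs(cf) > coef_limit)) {
    flag <- "monotone_likelihood"
  }
  new_model_fit(kind = "cox", formula_tag = formula_tag,
                coefficients = cf, se = se, loglik = fit$loglik[2],
                n_used = nrow(df), converged = is.null(flag), flag = flag,
                covariate_names = names(df)[-(1:2)],
                lp = unname(fit$linear.predictors), fit = fit)
}

#' Concordance probability estimate for a Cox model
#'
#' The Gonen-Heller concordance probability estimate (CPE), computed from
#' the model's linear predictors only — no observed event ordering enters:
#' the mean over all unordered sample pairs \{i, j\} of
#' \eqn{1 / (1 + \exp(-|\eta_i - \eta_j|))}. Equal linear predictors give
#' 0.5; larger spread in predicted risk gives values approaching 1.
#'
#' @param fit An `mp_model_fit` of kind `"cox"`, or a numeric vector of
#'   linear predictors.
#' @return A list: `cpe` and `n_pairs` (the number of unordered pairs).
#' @export
cpe <- function(fit) {
  eta <- if (inherits(fit, "mp_model_fit")) {
    if (fit$kind != "cox") mp_stop("cpe() applies to Cox fits")
    fit$lp
  } else {
    as.numeric(fit)
  }
  n <- length(eta)
  if (n < 2L) mp_stop("need at least two samples for a concordance estimate")
  d <- abs(outer(eta, eta, "-"))
  vals <- 1 / (1 + exp(-d[upper.tri(d)]))
  list(cpe = mean(vals), n_pairs = n * (n - 1L) / 2L)
}

#' Fit the four-model Cox family for a marker pair
#'
#' The survival-side analogue of [four_model_logit()]: Surv ~ M1;
#' Surv ~ M2; Surv ~ M1 + M2; Surv ~ M1 + M2 + M1:M2, each with covariates
#' appended additively, fitted with the Efron tie correction on one
#' identical complete-case set. Nested models are compared by
#' likelihood-ratio tests on the log partial likelihoods, per-model risk
#' discrimination is the Gonen-Heller CPE, and the interaction is also
#' tested by the Wald z of the M1:M2 term.
#'
#' @inheritParams four_model_logit
#' @param min_events Minimum number of events (default 10).
#' @return An `mp_four_model` with `performance` holding CPE results.
#' @export
four_model_cox <- function(cohort, m1, m2, covariates = character(),
                           min_n = 20, min_events = 10, cor_limit = 0.999) {
  frame <- four_model_frame(cohort, m1, m2, covariates, family = "cox")
  n <- nrow(frame)
  tt <- frame[[cohort$time]]; ee <- frame[[cohort$event]]
  if (n < min_n) {
    return(four_model_skip("cox", paste0("complete cases ", n, " < ", min_n)))
  }
  if (sum(ee) < min_events) {
    return(four_model_skip("cox", paste0("events ", sum(ee), " < ", min_events)))
  }
  if (n_distinct_nonmiss(frame$.m1) < 2L || n_distinct_nonmiss(frame$.m2) < 2L) {
    return(four_model_skip("cox", "constant marker on complete cases"))
  }
  r12 <- suppressWarnings(stats::cor(frame$.m1, frame$.m2))
  if (!is.na(r12) && abs(r12) > cor_limit) {
    return(four_model_skip("cox", "collinear markers"))
  }

  covs <- frame[, covariates, drop = FALSE]
  x1 <- frame$.m1; x2 <- frame$.m2
  designs <- list(
    m1 = cbind(data.frame(.m1 = x1), covs),
    m2 = cbind(data.frame(.m2 = x2), covs),
    dual_add = cbind(data.frame(.m1 = x1, .m2 = x2), covs),
    dual_int = cbind(data.frame(.m1 = x1, .m2 = x2, .m1_x_m2 = x1 * x2), covs)
  )
  tags <- c(m1 = "M1", m2 = "M2", dual_add = "M1+M2", dual_int = "M1*M2")
  fits <- lapply(names(designs), function(nm) {
    fit_cox(tt, ee, designs[[nm]], formula_tag = tags[[nm]])
  })
  names(fits) <- names(designs)

  comparisons <- four_model_comparisons(fits)
  performance <- lapply(fits, function(f) {
    if (is.null(f$flag)) cpe(f) else NULL
  })
  structure(
    list(family = "cox", status = "evaluated", reason = NA_character_,
         fits = fits, comparisons = comparisons,
         interaction_wald_p = wald_p(fits$dual_int, ".m1_x_m2"),
         performance = performance, n_used = n),
    class = "mp_four_model"
  )
}

#' Conditional Kaplan-Meier comparisons for a marker pair
#'
#' Stratified two-group log-rank tests: M2 high vs low within each M1 level,
#' and M1 high vs low within each M2 level (four comparisons). P-values are
#' Bonferroni-adjusted with family size 4; a stratum in which a comparison
#' cannot be evaluated (empty, single level, or no events) is reported as
#' not evaluable and the family size is unchanged.
#'
#' Dichotomization cutpoints are computed on the full cohort (population
#' median by default) before stratifying.
#'
#' @inheritParams four_model_logit
#' @return A tibble with one row per comparison: `comparison`, `stratum`,
#'   `n`, `chi2`, `p_value`, `p_adjusted`, `note`.
#' @export
conditional_km <- function(cohort, m1, m2) {
  stopifnot_cohort(cohort)
  if (!has_survival(cohort)) {
    mp_stop("cohort has no survival outcome",
            class = "markerpair_validation_error")
  }
  m1 <- as_marker_spec(m1); m2 <- as_marker_spec(m2)
  d <- cohort$data
  l1 <- dichotomize(d[[m1$name]], m1)$levels
  l2 <- dichotomize(d[[m2$name]], m2)$levels
  tt <- d[[cohort$time]]; ee <- d[[cohort$event]]

  one <- function(comparison, stratum_levels, test_levels) {
    keep <- !is.na(stratum_levels) & !is.na(test_levels) &
      !is.na(tt) & !is.na(ee)
    res <- lapply(c("high", "low"), function(sl) {
      idx <- keep & stratum_levels == sl
      nm <- paste0(comparison, "_within_", sl)
      if (sum(idx) == 0L || nlevels(droplevels(test_levels[idx])) < 2L ||
          sum(ee[idx]) < 1L) {
        return(tibble::tibble(comparison = nm, stratum = sl,
                              n = sum(idx), chi2 = NA_real_,
                              p_value = NA_real_,
                              note = "not evaluable"))
      }
      lr <- logrank_test(tt[idx], ee[idx], test_levels[idx])
      tibble::tibble(comparison = nm, stratum = sl, n = lr$n,
                     chi2 = lr$chi2, p_value = lr$p_value,
                     note = NA_character_)
    })
    dplyr::bind_rows(res)
  }
  out <- dplyr::bind_rows(
    one(paste0(m2$name, "_by_", m1$name), l1, l2),
    one(paste0(m1$name, "_by_", m2$name), l2, l1)
  )
  out$p_adjusted <- bonferroni_adjust(out$p_value, m = 4)
  out
}

#' Per-quadrant survival summary and marker-independence test
#'
#' Assigns R1-R4 quadrants from the dichotomized pair, reports per-quadrant
#' sample size, events, median survival and its confidence interval (from
#' [km_estimate()] per quadrant; empty quadrants report missing medians),
#' the overall four-group log-rank test, and Fisher's exact test of
#' independence on the 2x2 high/low contingency of the two markers.
#'
#' @inheritParams four_model_logit
#' @return A list: `quadrants` (tibble: `quadrant`, `n`, `n_events`,
#'   `median`, `median_ci_low`, `median_ci_high`), `logrank` (all-group
#'   test) and `independence` (Fisher result).
#' @export
quadrant_survival_stats <- function(cohort, m1, m2) {
  stopifnot_cohort(cohort)
  if (!has_survival(cohort)) {
    mp_stop("cohort has no survival outcome",
            class = "markerpair_validation_error")
  }
  m1 <- as_marker_spec(m1); m2 <- as_marker_spec(m2)
  d <- cohort$data
  l1 <- dichotomize(d[[m1$name]], m1)$levels
  l2 <- dichotomize(d[[m2$name]], m2)$levels
  tt <- d[[cohort$time]]; ee <- d[[cohort$event]]
  keep <- !is.na(l1) & !is.na(l2) & !is.na(tt) & !is.na(ee)
  qa <- assign_quadrants(l1[keep], l2[keep])
  qd <- qa$assignment$quadrant
  rows <- lapply(levels(qd), function(q) {
    idx <- qd == q
    if (sum(idx) == 0L) {
      return(tibble::tibble(quadrant = q, n = 0L, n_events = 0L,
                            median = NA_real_, median_ci_low = NA_real_,
                            median_ci_high = NA_real_))
    }
    km <- km_estimate(tt[keep][idx], ee[keep][idx])
    tibble::tibble(quadrant = q, n = km$n, n_events = km$n_events,
                   median = km$median, median_ci_low = km$median_ci_low,
                   median_ci_high = km$median_ci_high)
  })
  counts <- table(m1 = l1[keep], m2 = l2[keep])
  lr <- if (nlevels(droplevels(qd)) >= 2L && sum(ee[keep]) >= 1L) {
    logrank_test(tt[keep], ee[keep], qd)
  } else {
    NULL
  }
  list(quadrants = dplyr::bind_rows(rows), logrank = lr,
       independence = fisher_exact_2x2(as.matrix(counts)))
}
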