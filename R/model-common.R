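# Shared machinery for the four-model families (logistic and Cox):
# ModelFit containers, nested likelihood-ratio comparison, and the
# complete-case model frame the four models share.

new_model_fit <- function(kind, formula_tag, coefficients, se, loglik,
                          n_used, converged, flag = NULL,
                          covariate_names = character(),
                          fitted = NULL, lp = NULL, fit = NULL) {
  structure(
    list(kind = kind, formula_tag = formula_tag,
         coefficients = coefficients, se = se, loglik = loglik,
         n_used = as.integer(n_used), converged = converged,
         flag = flag, covariate_names = covariate_names,
         fitted = fitted, lp = lp, fit = fit),
    class = "mp_model_fit"
  )
}

#' @export
print.mp_model_fit <- function(x, ...) {
  cat("<mp_model_fit> ", x$kind, " ", x$formula_tag,
      "  n=", x$n_used, "  logLik=", format(x$loglik, digits = 6),
      if (!is.null(x$flag)) paste0("  [", x$flag, "]"), "\n", sep = "")
  print(round(rbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Likelihood-ratio test of two nested model fits
#'
#' Compares a full and a reduced fit of the same family on the same
#' complete-case set: the statistic is twice the log-likelihood difference
#' (partial log-likelihood for Cox fits), clipped at zero, with degrees of
#' freedom equal to the difference in parameter count and an upper-tail
#' chi-square p-value.
#'
#' @param full,reduced `mp_model_fit` objects, `reduced` nested in `full`.
#' @return A list: `stat`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  if (!inherits(full, "mp_model_fit") || !inherits(reduced, "mp_model_fit")) {
    mp_stop("lrt() expects two mp_model_fit objects")
  }
  if (full$kind != reduced$kind) {
    mp_stop("cannot compare fits of different model families")
  }
  if (full$n_used != reduced$n_used) {
    mp_stop(paste0("fits use different complete-case sets (n = ",
                   full$n_used, " vs ", reduced$n_used,
                   "); refit both on the common cases"))
  }
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 1L) mp_stop("`full` must have more parameters than `reduced`")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(stat = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

# The model frame the four models of one family share: complete cases over
# outcome, both marker regressors and the covariates. Binary markers are
# coded 0/1 per their positive level; continuous markers enter raw.
four_model_frame <- function(cohort, m1, m2, covariates, family) {
  stopifnot_cohort(cohort)
  m1 <- as_marker_spec(m1); m2 <- as_marker_spec(m2)
  d <- cohort$data
  for (cv in covariates) {
    if (!cv %in% names(d)) {
      mp_stop(paste0("covariate column not found: ", cv),
              class = "markerpair_validation_error")
    }
  }
  out_cols <- if (family == "logit") {
    if (!has_response(cohort)) {
      mp_stop("cohort has no response outcome; logistic family unavailable",
              class = "markerpair_validation_error")
    }
    ".response"
  } else {
    if (!has_survival(cohort)) {
      mp_stop("cohort has no survival outcome; Cox family unavailable",
              class = "markerpair_validation_error")
    }
    c(cohort$time, cohort$event)
  }
  x1 <- marker_regressor(d[[m1$name]], m1)
  x2 <- marker_regressor(d[[m2$name]], m2)
  frame <- tibble::tibble(.m1 = x1, .m2 = x2)
  for (cl in out_cols) frame[[cl]] <- d[[cl]]
  for (cv in covariates) {
    cvspec <- resolve_kind(d[[cv]], marker_spec(cv))
    frame[[cv]] <- marker_regressor(d[[cv]], cvspec)
  }
  frame <- frame[stats::complete.cases(frame), , drop = FALSE]
  frame
}

four_model_skip <- function(family, reason) {
  structure(
    list(family = family, status = "skipped", reason = reason,
         fits = NULL, comparisons = NULL, interaction_wald_p = NA_real_,
         performance = NULL, n_used = NA_integer_),
    class = "mp_four_model"
  )
}

# the five nested comparisons of the family; any flagged fit drops its
# comparisons (the flag reason is recorded instead of a p-value)
four_model_comparisons <- function(fits) {
  specs <- list(
    dual_add_vs_m1 = c("dual_add", "m1"),
    dual_int_vs_m1 = c("dual_int", "m1"),
    dual_add_vs_m2 = c("dual_add", "m2"),
    dual_int_vs_m2 = c("dual_int", "m2"),
    dual_int_vs_dual_add = c("dual_int", "dual_add")
  )
  rows <- lapply(names(specs), function(nm) {
    fu <- fits[[specs[[nm]][1]]]; re <- fits[[specs[[nm]][2]]]
    if (!is.null(fu$flag) || !is.null(re$flag)) {
      return(tibble::tibble(comparison = nm, stat = NA_real_, df = NA_integer_,
                            p_value = NA_real_,
                            note = paste(c(fu$flag, re$flag), collapse = ";")))
    }
    r <- lrt(fu, re)
    tibble::tibble(comparison = nm, stat = r$stat, df = as.integer(r$df),
                   p_value = r$p_value, note = NA_character_)
  })
  dplyr::bind_rows(rows)
}

wald_p <- function(fit, term) {
  b <- fit$coefficients[term]; s <- fit$se[term]
  if (is.na(b) || is.na(s) || !is.finite(s) || s <= 0) return(NA_real_)
  2 * stats::pnorm(-abs(b / s))
}

#' @export
print.mp_four_model <- function(x, ...) {
  cat("<mp_four_model> family=", x$family, " status=", x$status, sep = "")
  if (x$status == "skipped") {
    cat("  (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("  n=", x$n_used, "\n", sep = "")
  print(as.data.frame(x$comparisons))
  cat("interaction Wald p =", format(x$interaction_wald_p, digits = 4), "\n")
  invisible(x)
}
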