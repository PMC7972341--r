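#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic fit with intercept via iteratively reweighted
#' least squares. Quasi-complete separation is detected (non-convergence or
#' a coefficient diverging beyond `coef_limit`) and flagged rather than
#' silently reported; flagged fits are excluded from likelihood-ratio
#' comparisons.
#'
#' @param response 0/1 vector.
#' @param design Data frame (or matrix) of named numeric regressor columns;
#'   zero columns gives the intercept-only fit.
#' @param formula_tag Label stored on the fit (e.g. `"M1"`, `"M1*M2"`).
#' @param coef_limit Absolute coefficient size treated as divergence
#'   (default 15; on the log-odds scale this is far beyond any plausible
#'   biomarker effect).
#' @return An `mp_model_fit` with coefficients, standard errors, maximized
#'   log-likelihood, fitted probabilities, and a `flag` of `"separation"`
#'   when the fit is degenerate.
#' @export
fit_logistic <- function(response, design = NULL, formula_tag = "M1",
                         coef_limit = 15) {
  y <- as.numeric(response)
  if (!all(y %in% c(0, 1))) mp_stop("response must be 0/1")
  if (length(unique(y)) < 2L) mp_stop("response is constant; cannot fit")
  df <- if (is.null(design) || NCOL(design) == 0L) {
    data.frame(.y = y)
  } else {
    cbind(data.frame(.y = y), as.data.frame(design))
  }
  if (nrow(df) < ncol(df) + 1L) mp_stop("too few observations for parameters")
  rhs <- if (ncol(df) == 1L) "1" else paste(sprintf("`%s`", names(df)[-1]), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- suppressWarnings(
    stats::glm(fml, data = df, family = stats::binomial(),
               control = list(epsilon = 1e-9, maxit = 25))
  )
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  flag <- NULL
  if (!fit$converged || any(abs(cf) > coef_limit)) flag <- "separation"
  if (any(is.na(cf))) flag <- "rank_deficient"
  new_model_fit(kind = "logit", formula_tag = formula_tag,
                coefficients = cf, se = se,
                loglik = as.numeric(stats::logLik(fit)),
                n_used = nrow(df), converged = fit$converged, flag = flag,
                covariate_names = names(df)[-1],
                fitted = unname(stats::fitted(fit)), fit = fit)
}

#' ROC AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney statistic of the scores against the labels
#' (ties between a positive and a negative score count 1/2); its variance is
#' estimated by DeLong's structural-components method and a normal-theory
#' confidence interval is truncated to \[0, 1\]. The score direction is
#' fixed (higher score = predicted positive): scores here are fitted model
#' probabilities, or raw marker values when explicitly requested, and no
#' automatic direction flipping is performed, so an unfavorable raw marker
#' can yield AUC < 0.5.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 class labels; both classes must be present.
#' @param level Confidence level (default 0.95).
#' @return A list: `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
roc_auc_delong <- function(scores, labels, level = 0.95) {
  keep <- stats::complete.cases(scores, labels)
  scores <- scores[keep]; labels <- as.numeric(labels[keep])
  if (!all(labels %in% c(0, 1))) mp_stop("labels must be 0/1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    mp_stop("both classes must be present to compute an AUC")
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong",
                                             conf.level = level))),
    error = function(e) c(auc, auc, auc)
  )
  lo <- max(0, min(ci[1], auc)); hi <- min(1, max(ci[3], auc))
  if (is.na(lo)) lo <- auc
  if (is.na(hi)) hi <- auc
  list(auc = auc, ci_low = lo, ci_high = hi,
       n_pos = n_pos, n_neg = n_neg)
}

#' Fit the four-model logistic family for a marker pair
#'
#' Fits, on one identical complete-case set, the four nested logistic
#' models: response ~ M1; response ~ M2; response ~ M1 + M2; and
#' response ~ M1 + M2 + M1:M2. Covariates are appended additively to every
#' model. The five pairwise nested comparisons (each dual model against each
#' single model, and interaction vs additive) are evaluated by
#' likelihood-ratio test; each model's classification performance is the
#' DeLong AUC of its fitted probabilities, and the interaction effect is
#' additionally tested by the Wald z of the M1:M2 term.
#'
#' @param cohort An `mp_cohort` with a response outcome.
#' @param m1,m2 Marker specs (see [marker_spec()]) or bare column names.
#' @param covariates Character vector of covariate columns.
#' @param min_n Minimum complete cases (default 20).
#' @param min_per_class Minimum responders and non-responders (default 5).
#' @param cor_limit Absolute M1-M2 correlation above which the pair is
#'   treated as collinear and skipped (default 0.999).
#' @return An `mp_four_model` with `fits` (named `m1`, `m2`, `dual_add`,
#'   `dual_int`), `comparisons` (five-row tibble of LRT results),
#'   `interaction_wald_p`, and `performance` (per-model AUC results).
#'   Degenerate input yields `status = "skipped"` with a reason.
#' @export
four_model_logit <- function(cohort, m1, m2, covariates = character(),
                             min_n = 20, min_per_class = 5,
                             cor_limit = 0.999) {
  frame <- four_model_frame(cohort, m1, m2, covariates, family = "logit")
  n <- nrow(frame)
  if (n < min_n) {
    return(four_model_skip("logit", paste0("complete cases ", n, " < ", min_n)))
  }
  if (min(table(factor(frame$.response, levels = 0:1))) < min_per_class) {
    return(four_model_skip("logit", "fewer than min_per_class in one response class"))
  }
  if (n_distinct_nonmiss(frame$.m1) < 2L || n_distinct_nonmiss(frame$.m2) < 2L) {
    return(four_model_skip("logit", "constant marker on complete cases"))
  }
  r12 <- suppressWarnings(stats::cor(frame$.m1, frame$.m2))
  if (!is.na(r12) && abs(r12) > cor_limit) {
    return(four_model_skip("logit", "collinear markers"))
  }

  y <- frame$.response
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
    fit_logistic(y, designs[[nm]], formula_tag = tags[[nm]])
  })
  names(fits) <- names(designs)

  comparisons <- four_model_comparisons(fits)
  performance <- lapply(fits, function(f) {
    if (is.null(f$flag)) roc_auc_delong(f$fitted, y) else NULL
  })
  structure(
    list(family = "logit", status = "evaluated", reason = NA_character_,
         fits = fits, comparisons = comparisons,
         interaction_wald_p = wald_p(fits$dual_int, ".m1_x_m2"),
         performance = performance, n_used = n),
    class = "mp_four_model"
  )
}
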