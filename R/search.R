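#' Signed -log10 p-value for search prioritization
#'
#' The search score: \eqn{-\log_{10} p} signed by the direction of the
#' candidate's single-marker effect. "Favorable" means the candidate alone
#' predicts a better outcome — higher response odds in the logistic family,
#' or longer survival (negative log-hazard coefficient) in the Cox family —
#' and gives a positive sign.
#'
#' @param p P-value in (0, 1].
#' @param direction `"favorable"` or `"unfavorable"`.
#' @param cap Maximum absolute value, used when `p` underflows to 0
#'   (default 300).
#' @return Signed -log10 p.
#' @export
signed_log10_p <- function(p, direction = c("favorable", "unfavorable"),
                           cap = 300) {
  direction <- match.arg(direction)
  if (is.na(p)) return(NA_real_)
  if (p < 0 || p > 1) mp_stop("p must be in [0, 1]")
  mag <- if (p == 0) cap else min(cap, -log10(p))
  if (direction == "favorable") mag else -mag
}

#' Search configuration for partner discovery
#'
#' @param family `"logit"` (binary response) or `"cox"` (survival).
#' @param covariates Covariate columns appended to every model.
#' @param min_n,min_per_class,min_events Complete-case guards passed to the
#'   four-model fitters.
#' @param cor_limit Collinearity guard on the M1-M2 correlation.
#' @param alpha Reporting significance lines (default 0.01 and 0.05).
#' @return A list of class `mp_search_config`.
#' @export
search_config <- function(family = c("logit", "cox"),
                          covariates = character(),
                          min_n = 20, min_per_class = 5, min_events = 10,
                          cor_limit = 0.999, alpha = c(0.01, 0.05)) {
  structure(
    list(family = match.arg(family), covariates = covariates,
         min_n = min_n, min_per_class = min_per_class,
         min_events = min_events, cor_limit = cor_limit, alpha = alpha),
    class = "mp_search_config"
  )
}

# evaluate one (m1, m2) pair into one search-result row
search_one_pair <- function(cohort, m1, m2, config) {
  m1 <- as_marker_spec(m1); m2 <- as_marker_spec(m2)
  skipped_row <- function(reason) {
    tibble::tibble(
      m1_name = m1$name, m2_name = m2$name, status = paste0("skipped(", reason, ")"),
      n_used = NA_integer_, p_dual_vs_m1 = NA_real_, p_dual_vs_m2 = NA_real_,
      chosen_dual_vs_m1 = NA_character_, chosen_dual_vs_m2 = NA_character_,
      interaction_p = NA_real_, m2_single_p = NA_real_,
      m2_single_direction = NA_character_, signed_log10_p = NA_real_,
      perf_m1 = NA_real_, perf_m2 = NA_real_, perf_dual_add = NA_real_,
      perf_dual_int = NA_real_
    )
  }
  fm <- tryCatch(
    if (config$family == "logit") {
      four_model_logit(cohort, m1, m2, covariates = config$covariates,
                       min_n = config$min_n,
                       min_per_class = config$min_per_class,
                       cor_limit = config$cor_limit)
    } else {
      four_model_cox(cohort, m1, m2, covariates = config$covariates,
                     min_n = config$min_n, min_events = config$min_events,
                     cor_limit = config$cor_limit)
    },
    error = function(e) conditionMessage(e)
  )
  if (is.character(fm)) return(skipped_row(fm))
  if (fm$status == "skipped") return(skipped_row(fm$reason))

  cmp <- fm$comparisons
  pick <- function(add_nm, int_nm) {
    p_add <- cmp$p_value[cmp$comparison == add_nm]
    p_int <- cmp$p_value[cmp$comparison == int_nm]
    if (is.na(p_add) && is.na(p_int)) {
      return(list(p = NA_real_, which = NA_character_))
    }
    # the dual model (additive or interaction) with the smaller LRT p is taken
    if (is.na(p_int) || (!is.na(p_add) && p_add <= p_int)) {
      list(p = p_add, which = "additive")
    } else {
      list(p = p_int, which = "interaction")
    }
  }
  vs1 <- pick("dual_add_vs_m1", "dual_int_vs_m1")
  vs2 <- pick("dual_add_vs_m2", "dual_int_vs_m2")

  m2fit <- fm$fits$m2
  b2 <- unname(m2fit$coefficients[".m2"])
  m2_p <- wald_p(m2fit, ".m2")
  direction <- if (is.na(b2)) {
    NA_character_
  } else if (config$family == "logit") {
    if (b2 >= 0) "favorable" else "unfavorable"
  } else {
    # longer survival = lower hazard = negative log-hazard coefficient
    if (b2 <= 0) "favorable" else "unfavorable"
  }
  perf <- function(nm) {
    p <- fm$performance[[nm]]
    if (is.null(p)) NA_real_ else if (config$family == "logit") p$auc else p$cpe
  }
  tibble::tibble(
    m1_name = m1$name, m2_name = m2$name, status = "evaluated",
    n_used = fm$n_used,
    p_dual_vs_m1 = vs1$p, p_dual_vs_m2 = vs2$p,
    chosen_dual_vs_m1 = vs1$which, chosen_dual_vs_m2 = vs2$which,
    interaction_p = fm$interaction_wald_p,
    m2_single_p = m2_p, m2_single_direction = direction,
    signed_log10_p = if (is.na(vs1$p) || is.na(direction)) NA_real_ else
      signed_log10_p(vs1$p, direction),
    perf_m1 = perf("m1"), perf_m2 = perf("m2"),
    perf_dual_add = perf("dual_add"), perf_dual_int = perf("dual_int")
  )
}

#' Search partner markers (M2) for a fixed marker M1
#'
#' For each candidate M2, the four-model family of the chosen regression
#' type is fitted and the candidate is scored by the smaller of the two
#' likelihood-ratio p-values of the dual models (additive and interaction)
#' against the M1 single-marker model — and, analogously, against the M2
#' single-marker model. Benjamini-Hochberg adjustment is applied column-wise
#' across the evaluated candidates, and rows are sorted by `p_dual_vs_m1`
#' ascending. Degenerate candidates (constant, collinear with M1,
#' separation/monotone likelihood, too few cases) become skipped rows with
#' a reason, never errors.
#'
#' @param cohort An `mp_cohort`.
#' @param m1 Marker spec or column name of the fixed marker.
#' @param candidates Character vector (or list of [marker_spec()]) of
#'   candidate M2 columns; M1 itself is dropped if present.
#' @param config A [search_config()].
#' @return A tibble with one row per candidate (`SearchResultRow` layout):
#'   LRT p-values and chosen dual model per comparison, interaction Wald p,
#'   single-M2 effect direction and p, the signed -log10 p score, BH-adjusted
#'   columns `adj_p_dual_vs_m1` / `adj_p_dual_vs_m2`, and per-model
#'   performance (AUC or CPE).
#' @export
search_m2 <- function(cohort, m1, candidates, config = search_config()) {
  stopifnot_cohort(cohort)
  m1 <- as_marker_spec(m1)
  specs <- lapply(candidates, as_marker_spec)
  specs <- specs[vapply(specs, function(s) s$name != m1$name, logical(1))]
  if (length(specs) == 0L) mp_stop("no candidates beyond m1 itself")
  rows <- dplyr::bind_rows(lapply(specs, function(s) {
    search_one_pair(cohort, m1, s, config)
  }))
  finalize_search_rows(rows)
}

#' Score all unordered marker pairs
#'
#' Evaluates every unordered pair \{i, j\} of the candidate markers with the
#' lexicographically first name taking the M1 role, using the same
#' statistics as [search_m2()].
#'
#' @inheritParams search_m2
#' @param candidates At least two candidate markers.
#' @return A tibble with one row per unordered pair; see [search_m2()].
#' @export
comb_m <- function(cohort, candidates, config = search_config()) {
  stopifnot_cohort(cohort)
  specs <- lapply(candidates, as_marker_spec)
  if (length(specs) < 2L) mp_stop("need at least two candidates")
  nms <- vapply(specs, function(s) s$name, character(1))
  specs <- specs[order(nms)]
  k <- length(specs)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      rows[[length(rows) + 1L]] <-
        search_one_pair(cohort, specs[[i]], specs[[j]], config)
    }
  }
  finalize_search_rows(dplyr::bind_rows(rows))
}

# BH adjustment over evaluated rows only; deterministic sort by
# (p_dual_vs_m1, m1_name, m2_name)
finalize_search_rows <- function(rows) {
  ev <- rows$status == "evaluated"
  rows$adj_p_dual_vs_m1 <- NA_real_
  rows$adj_p_dual_vs_m2 <- NA_real_
  rows$adj_p_dual_vs_m1[ev] <- bh_adjust(rows$p_dual_vs_m1[ev])
  rows$adj_p_dual_vs_m2[ev] <- bh_adjust(rows$p_dual_vs_m2[ev])
  rows[order(rows$p_dual_vs_m1, rows$m1_name, rows$m2_name,
             na.last = TRUE), , drop = FALSE]
}
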