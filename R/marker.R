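#' Describe how one marker is interpreted and dichotomized
#'
#' A marker spec fixes how a cohort column enters the analysis: continuous
#' markers enter regression models raw and unscaled and are dichotomized
#' (for quadrant stratification and plots only) at the population median or
#' at an explicit cutoff; binary markers are coded 0/1 with `positive_level`
#' mapped to 1/"high".
#'
#' @param name Marker column name.
#' @param kind `"auto"` (resolved against the data: two observed levels =>
#'   binary, otherwise continuous), `"continuous"`, or `"binary"`.
#' @param cutoff For continuous markers: `"median"` or an explicit numeric
#'   cutpoint. Ignored for binary markers.
#' @param positive_level For binary markers: the level coded positive/high.
#' @param label_high,label_low Display labels for the two levels.
#' @param strict_gt Tie rule at the cutpoint for continuous markers: if
#'   `TRUE` (default) a sample is "high" iff its value is strictly greater
#'   than the cutpoint, so the median sample itself is "low"; if `FALSE`,
#'   "high" means greater-or-equal.
#' @return An object of class `mp_marker_spec`.
#' @export
marker_spec <- function(name, kind = c("auto", "continuous", "binary"),
                        cutoff = "median", positive_level = NULL,
                        label_high = NULL, label_low = NULL,
                        strict_gt = TRUE) {
  kind <- match.arg(kind)
  if (!(identical(cutoff, "median") || (is.numeric(cutoff) && length(cutoff) == 1L))) {
    mp_stop("`cutoff` must be \"median\" or a single numeric value")
  }
  structure(
    list(name = name, kind = kind, cutoff = cutoff,
         positive_level = positive_level,
         label_high = label_high %||% paste0(name, ".high"),
         label_low = label_low %||% paste0(name, ".low"),
         strict_gt = isTRUE(strict_gt)),
    class = "mp_marker_spec"
  )
}

as_marker_spec <- function(x) {
  if (inherits(x, "mp_marker_spec")) x else marker_spec(as.character(x))
}

# fix kind = "auto" against observed values
resolve_kind <- function(values, spec) {
  if (spec$kind != "auto") return(spec)
  spec$kind <- if (is_binaryish(values) || !is.numeric(values)) "binary" else "continuous"
  spec
}

#' Dichotomize marker values into high/low levels
#'
#' For continuous markers the cutpoint is the population median of the
#' non-missing values (or the explicit cutoff in the spec) and a sample is
#' "high" iff its value exceeds the cutpoint (strictly by default, see
#' [marker_spec()]). For binary markers the `positive_level` is "high".
#' Missing values propagate as missing.
#'
#' @param values Vector of marker values.
#' @param spec An [marker_spec()] (a bare column name is promoted to an
#'   auto-typed spec).
#' @return A list with `levels` (factor with levels `low`, `high`),
#'   `cutpoint` (the numeric cutpoint actually used; `NA` for binary
#'   markers), and the resolved `spec`.
#' @export
dichotomize <- function(values, spec) {
  spec <- resolve_kind(values, as_marker_spec(spec))
  if (spec$kind == "continuous") {
    if (!is.numeric(values)) {
      mp_stop(paste0("continuous marker '", spec$name, "' is not numeric"))
    }
    if (n_distinct_nonmiss(values) < 2L) {
      mp_stop(paste0("constant marker '", spec$name,
                     "': no stratification possible"))
    }
    cutpoint <- if (identical(spec$cutoff, "median")) {
      stats::median(values, na.rm = TRUE)
    } else {
      spec$cutoff
    }
    high <- if (spec$strict_gt) values > cutpoint else values >= cutpoint
    if (identical(spec$cutoff, "median") &&
        n_distinct_nonmiss(high) < 2L) {
      mp_stop(paste0("marker '", spec$name,
                     "': median cutoff leaves a single level; ",
                     "values are too heavily tied"))
    }
  } else {
    ux <- unique(values[!is.na(values)])
    if (length(ux) > 2L) {
      mp_stop(paste0("binary marker '", spec$name, "' has ", length(ux),
                     " observed levels; ordinal markers are unsupported"))
    }
    pos <- spec$positive_level
    if (is.null(pos)) {
      # default positive level: 1/TRUE if present, else the later sorted level
      pos <- if (any(as.character(ux) %in% c("1", "TRUE"))) {
        ux[as.character(ux) %in% c("1", "TRUE")][1]
      } else {
        sort(as.character(ux))[length(ux)]
      }
      spec$positive_level <- pos
    }
    if (!as.character(pos) %in% as.character(ux)) {
      mp_stop(paste0("positive_level '", pos, "' of marker '", spec$name,
                     "' is not an observed level"))
    }
    high <- as.character(values) == as.character(pos)
    cutpoint <- NA_real_
  }
  levels <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  list(levels = levels, cutpoint = cutpoint, spec = spec)
}

# numeric regressor for model fitting: raw values for continuous markers,
# 0/1 (positive_level = 1) for binary markers
marker_regressor <- function(values, spec) {
  spec <- resolve_kind(values, as_marker_spec(spec))
  if (spec$kind == "continuous") {
    if (!is.numeric(values)) {
      mp_stop(paste0("continuous marker '", spec$name, "' is not numeric"))
    }
    as.numeric(values)
  } else {
    d <- dichotomize(values, spec)
    as.numeric(d$levels == "high")
  }
}

#' Assign samples to the four R1-R4 quadrants
#'
#' Jointly dichotomized markers partition the cohort into four quadrants:
#' R1 = M1 high / M2 high, R2 = M1 low / M2 high, R3 = M1 low / M2 low,
#' R4 = M1 high / M2 low. Samples missing either level are excluded from all
#' four quadrants and counted separately.
#'
#' @param m1_levels,m2_levels Factors (or characters) with levels
#'   `low`/`high`, same length.
#' @return An object of class `mp_quadrants`: list with `assignment` (tibble
#'   of per-sample m1/m2 levels and quadrant), `counts` (named n per R1-R4),
#'   and `n_excluded`.
#' @export
assign_quadrants <- function(m1_levels, m2_levels) {
  if (length(m1_levels) != length(m2_levels)) {
    mp_stop("m1 and m2 level vectors must have the same length")
  }
  l1 <- as.character(m1_levels)
  l2 <- as.character(m2_levels)
  bad <- stats::na.omit(setdiff(unique(c(l1, l2)), c("low", "high")))
  if (length(bad) > 0L) {
    mp_stop(paste0("levels must be 'low'/'high'; saw: ",
                   paste(bad, collapse = ", ")))
  }
  quadrant <- dplyr::case_when(
    l1 == "high" & l2 == "high" ~ "R1",
    l1 == "low" & l2 == "high" ~ "R2",
    l1 == "low" & l2 == "low" ~ "R3",
    l1 == "high" & l2 == "low" ~ "R4"
  )
  assignment <- tibble::tibble(
    m1_level = factor(l1, levels = c("low", "high")),
    m2_level = factor(l2, levels = c("low", "high")),
    quadrant = factor(quadrant, levels = c("R1", "R2", "R3", "R4"))
  )
  counts <- table(assignment$quadrant)
  structure(
    list(assignment = assignment,
         counts = stats::setNames(as.integer(counts), names(counts)),
         n_excluded = sum(is.na(quadrant))),
    class = "mp_quadrants"
  )
}

#' @export
print.mp_quadrants <- function(x, ...) {
  cat("<mp_quadrants> ")
  cat(paste0(names(x$counts), "=", x$counts, collapse = " "),
      " excluded=", x$n_excluded, "\n", sep = "")
  invisible(x)
}
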