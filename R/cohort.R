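#' Construct a patient cohort from a data frame
#'
#' A cohort is the central data container: one row per patient, with a unique
#' sample identifier, an optional binary response outcome, an optional
#' time-to-event outcome (time plus 0/1 event indicator), and any number of
#' marker and covariate columns. At least one outcome must be present for any
#' downstream analysis to run.
#'
#' The response column may hold any two coded levels (e.g. `"R"`/`"NR"`,
#' `0`/`1`, `TRUE`/`FALSE`); `response_coding` names the level treated as
#' responder, which is stored internally as 1. A response with more (or
#' fewer) than two observed levels is rejected: ordinal outcomes with more
#' than two levels are unsupported and must be dichotomized beforehand.
#'
#' @param data A data frame, one row per patient.
#' @param sample_id Name of the unique sample-identifier column.
#' @param response Name of the binary response column, or `NULL`.
#' @param time,event Names of the survival time and 0/1 event-indicator
#'   columns, or `NULL`. Supply both or neither.
#' @param markers Character vector of marker column names (continuous or
#'   binary).
#' @param covariates Character vector of covariate column names.
#' @param response_coding The level of `response` coded as responder.
#'   Defaults to `1`/`TRUE`/`"1"` when such a level is observed; otherwise it
#'   must be given explicitly.
#' @return An object of class `mp_cohort`: a list with the validated `data`
#'   tibble (response recoded to 0/1 in column `.response`), the column
#'   roles, and `load_report`, a tibble of per-column missingness.
#' @export
cohort <- function(data, sample_id = "sample_id", response = NULL,
                   time = NULL, event = NULL,
                   markers = character(), covariates = character(),
                   response_coding = NULL) {
  data <- tibble::as_tibble(data)
  mapped <- c(sample_id = sample_id, response = response,
              time = time, event = event, markers, covariates)
  missing_cols <- setdiff(unname(mapped), names(data))
  if (length(missing_cols) > 0L) {
    mp_stop(paste0("mapped column(s) not found in table: ",
                   paste(missing_cols, collapse = ", ")),
            class = "markerpair_validation_error")
  }
  if (xor(is.null(time), is.null(event))) {
    mp_stop("survival outcome needs both `time` and `event` columns",
            class = "markerpair_validation_error")
  }
  if (is.null(response) && is.null(time)) {
    mp_stop("at least one outcome (response or time+event) is required",
            class = "markerpair_validation_error")
  }

  ids <- data[[sample_id]]
  if (anyDuplicated(ids)) {
    mp_stop(paste0("sample ids are not unique (e.g. '",
                   ids[duplicated(ids)][1], "')"),
            class = "markerpair_validation_error")
  }

  flagged <- character()

  if (!is.null(response)) {
    resp_raw <- data[[response]]
    lev <- sort(unique(as.character(resp_raw[!is.na(resp_raw)])))
    if (length(lev) != 2L) {
      mp_stop(paste0("response column '", response, "' has ", length(lev),
                     " observed level(s); ordinal/multi-level response ",
                     "unsupported - exactly two levels are required"),
              class = "markerpair_validation_error")
    }
    if (is.null(response_coding)) {
      default_pos <- intersect(c("1", "TRUE", "yes", "responder", "R"), lev)
      if (length(default_pos) != 1L) {
        mp_stop(paste0("cannot infer the responder level of '", response,
                       "' from levels {", paste(lev, collapse = ", "),
                       "}; supply `response_coding`"),
                class = "markerpair_validation_error")
      }
      response_coding <- default_pos
    }
    response_coding <- as.character(response_coding)
    if (!response_coding %in% lev) {
      mp_stop(paste0("responder level '", response_coding,
                     "' not observed in column '", response, "'"),
              class = "markerpair_validation_error")
    }
    data$.response <- as.integer(as.character(resp_raw) == response_coding)
  }

  if (!is.null(time)) {
    tt <- data[[time]]
    ee <- data[[event]]
    if (!is.numeric(tt)) {
      mp_stop(paste0("survival time column '", time, "' is not numeric"),
              class = "markerpair_validation_error")
    }
    bad_t <- which(!is.na(tt) & tt < 0)
    if (length(bad_t) > 0L) {
      mp_stop(paste0("negative survival time in row(s): ",
                     paste(utils::head(bad_t, 5), collapse = ", ")),
              class = "markerpair_validation_error")
    }
    ok_e <- is.na(ee) | ee %in% c(0, 1)
    if (!all(ok_e)) {
      mp_stop(paste0("event indicator '", event,
                     "' must be 0/1; offending row(s): ",
                     paste(utils::head(which(!ok_e), 5), collapse = ", ")),
              class = "markerpair_validation_error")
    }
    # an event flag without a time (or vice versa) is flagged, never dropped
    half <- xor(is.na(tt), is.na(ee))
    if (any(half)) {
      flagged <- c(flagged, paste0("row ", which(half),
                                   ": incomplete survival outcome"))
    }
  }

  report_cols <- unique(c(unname(mapped),
                          if (!is.null(response)) ".response"))
  load_report <- tibble::tibble(
    column = report_cols,
    n_missing = vapply(report_cols, function(cl) sum(is.na(data[[cl]])),
                       integer(1)),
    n = nrow(data)
  )

  structure(
    list(data = data, sample_id = sample_id, response = response,
         time = time, event = event,
         markers = unname(markers), covariates = unname(covariates),
         response_coding = if (!is.null(response)) response_coding,
         flagged = flagged, load_report = load_report),
    class = "mp_cohort"
  )
}

#' Load a cohort from a delimited text file
#'
#' Reads a CSV or TSV patient table (header row required; missing values as
#' empty strings or `NA`) and validates it into a cohort via [cohort()].
#' The delimiter is taken from the file extension (`.tsv`/`.txt` are
#' tab-separated, anything else comma-separated) unless `delim` is given.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter; `NULL` to infer from the extension.
#' @inheritParams cohort
#' @return An `mp_cohort`; see [cohort()].
#' @export
load_cohort <- function(path, sample_id = "sample_id", response = NULL,
                        time = NULL, event = NULL,
                        markers = character(), covariates = character(),
                        response_coding = NULL, delim = NULL) {
  if (!file.exists(path)) {
    mp_stop(paste0("input file not found: ", path),
            class = "markerpair_validation_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  data <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                            show_col_types = FALSE, progress = FALSE)
  cohort(data, sample_id = sample_id, response = response, time = time,
         event = event, markers = markers, covariates = covariates,
         response_coding = response_coding)
}

#' @export
print.mp_cohort <- function(x, ...) {
  cat("<mp_cohort> ", nrow(x$data), " samples\n", sep = "")
  cat("  response: ", x$response %||% "<none>",
      if (!is.null(x$response)) paste0(" (responder = '", x$response_coding, "')"),
      "\n", sep = "")
  cat("  survival: ",
      if (is.null(x$time)) "<none>" else paste0(x$time, " + ", x$event),
      "\n", sep = "")
  cat("  markers (", length(x$markers), "): ",
      paste(utils::head(x$markers, 8), collapse = ", "),
      if (length(x$markers) > 8) ", ...", "\n", sep = "")
  if (length(x$covariates)) {
    cat("  covariates: ", paste(x$covariates, collapse = ", "), "\n", sep = "")
  }
  if (length(x$flagged)) {
    cat("  flagged rows: ", length(x$flagged), "\n", sep = "")
  }
  invisible(x)
}

# [[ ]] avoids partial matching (e.g. $response against response_coding)
has_response <- function(cohort) !is.null(cohort[["response"]])
has_survival <- function(cohort) !is.null(cohort[["time"]])

stopifnot_cohort <- function(cohort) {
  if (!inherits(cohort, "mp_cohort")) {
    mp_stop("expected an `mp_cohort` object; see cohort() / load_cohort()")
  }
  invisible(cohort)
}
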