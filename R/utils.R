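# internal helpers shared across modules

# stop with a classed condition so callers/tests can distinguish validation
# failures from runtime errors
mp_stop <- function(msg, class = "markerpair_error", ...) {
  rlang::abort(msg, class = class, ...)
}

is_binaryish <- function(x) {
  ux <- unique(x[!is.na(x)])
  length(ux) == 2L
}

# number of distinct non-missing values
n_distinct_nonmiss <- function(x) length(unique(x[!is.na(x)]))

compact <- function(x) x[!vapply(x, is.null, logical(1))]
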