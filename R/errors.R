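# Classed conditions used across the package.  Every user-facing error carries a
# betacage_* class so callers (and tests) can match on the failure kind rather
# than on message text.

abort_invalid_spec <- function(msg, ...) {
  abort(msg, class = c("betacage_invalid_spec", "betacage_error"), ...)
}

abort_insufficient_data <- function(msg, ...) {
  abort(msg, class = c("betacage_insufficient_data", "betacage_error"), ...)
}

abort_calibration_infeasible <- function(msg, achievable, ...) {
  abort(msg,
    class = c("betacage_calibration_infeasible", "betacage_error"),
    achievable = achievable, ...
  )
}

abort_ordering <- function(msg, ...) {
  abort(msg, class = c("betacage_ordering", "betacage_error"), ...)
}

abort_parse <- function(msg, ...) {
  abort(msg, class = c("betacage_parse", "betacage_error"), ...)
}

abort_undefined_rate <- function(msg, ...) {
  abort(msg, class = c("betacage_undefined_rate", "betacage_error"), ...)
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = NULL) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort_invalid_spec(sprintf("`%s` must be a single number", name))
  }
  if (!is.null(strict_min) && x <= strict_min) {
    abort_invalid_spec(sprintf("`%s` must be > %g", name, strict_min))
  }
  if (x < min) {
    abort_invalid_spec(sprintf("`%s` must be >= %g", name, min))
  }
  invisible(x)
}
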