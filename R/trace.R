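#' Construct an LFP trace
#'
#' A uniformly sampled local field potential voltage series.  Traces are
#' tibbles with a time column `t` (seconds) and a value column `v`
#' (microvolts by default), carrying the sampling rate, start time and unit
#' as attributes so downstream operations need not re-derive them.
#'
#' @param v Numeric vector of voltage samples.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param t0 Start time of the first sample, seconds.
#' @param unit Unit label for `v` (default `"uV"`).
#'
#' @return A tibble of class `lfp_trace` with columns `t` and `v`.
#' @export
#' @examples
#' x <- lfp_trace(sin(2 * pi * 20 * seq(0, 1, by = 1e-3)), fs = 1000)
#' trace_fs(x)
lfp_trace <- function(v, fs, t0 = 0, unit = "uV") {
  check_scalar_number(fs, "fs", strict_min = 0)
  check_scalar_number(t0, "t0")
  if (length(v) < 1) {
    abort_insufficient_data("an LFP trace needs at least one sample")
  }
  new_betacage_trace(as.double(v), fs, t0,
    unit = unit, class = "lfp_trace"
  )
}

#' Construct a band power trace
#'
#' The rectified, window-averaged band power series that drives conditioning.
#' Values are nonnegative; when `quantized` is `TRUE` they are integer power
#' units (the on-chip representation thresholds are compared against).
#'
#' @inheritParams lfp_trace
#' @param quantized Logical flag: are values integer power units?
#'
#' @return A tibble of class `power_trace` with columns `t` and `v`.
#' @export
power_trace <- function(v, fs, t0 = 0, unit = "uV", quantized = FALSE) {
  check_scalar_number(fs, "fs", strict_min = 0)
  if (length(v) < 1) {
    abort_insufficient_data("a power trace needs at least one sample")
  }
  if (any(v < 0, na.rm = TRUE)) {
    abort_invalid_spec("power values must be nonnegative")
  }
  new_betacage_trace(as.double(v), fs, t0,
    unit = unit, quantized = isTRUE(quantized), class = "power_trace"
  )
}

new_betacage_trace <- function(v, fs, t0, ..., class) {
  out <- tibble(t = t0 + (seq_along(v) - 1) / fs, v = v)
  attr(out, "fs") <- fs
  attr(out, "t0") <- t0
  extras <- list(...)
  for (nm in names(extras)) attr(out, nm) <- extras[[nm]]
  class(out) <- c(class, "betacage_trace", class(out))
  out
}

#' Trace accessors
#'
#' `trace_fs()` returns the sampling rate (falling back to the median time
#' step when the attribute has been stripped, e.g. after a dplyr verb);
#' `trace_t0()` the start time; `trace_unit()` the unit label;
#' `is_quantized()` whether a power trace holds integer power units.
#'
#' @param x A trace tibble with columns `t` and `v`.
#' @return A scalar.
#' @export
trace_fs <- function(x) {
  fs <- attr(x, "fs")
  if (!is.null(fs)) {
    return(fs)
  }
  if (!is.data.frame(x) || !"t" %in% names(x) || nrow(x) < 2) {
    abort_invalid_spec("cannot infer a sampling rate from this object")
  }
  1 / median(diff(x$t))
}

#' @rdname trace_fs
#' @export
trace_t0 <- function(x) attr(x, "t0") %||% x$t[1]

#' @rdname trace_fs
#' @export
trace_unit <- function(x) attr(x, "unit") %||% "uV"

#' @rdname trace_fs
#' @export
is_quantized <- function(x) isTRUE(attr(x, "quantized"))
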