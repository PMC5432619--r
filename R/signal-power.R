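#' Band-limit an LFP trace
#'
#' Applies the conditioning system's digital bandpass: a Butterworth design of
#' the given order, run forward and backward (`bidirectional = TRUE`, the
#' default) for zero phase shift, exactly as the on-chip 3rd-order 10-30 Hz
#' beta filter behaves.  One-directional (causal) filtering is available for
#' latency studies.
#'
#' @param trace An [lfp_trace()].
#' @param order Filter order (default 3).
#' @param low_hz,high_hz Band edges in Hz (defaults 10 and 30).
#' @param bidirectional Filter forward-backward for zero phase? Default `TRUE`.
#'
#' @return An `lfp_trace` of the same length and sampling rate.
#' @export
#' @examples
#' x <- lfp_trace(sin(2 * pi * 20 * seq(0, 2, by = 1e-3)), fs = 1000)
#' y <- bandpass_filter(x)
bandpass_filter <- function(trace, order = 3, low_hz = 10, high_hz = 30,
                            bidirectional = TRUE) {
  fs <- trace_fs(trace)
  check_scalar_number(order, "order", min = 1)
  check_scalar_number(low_hz, "low_hz", strict_min = 0)
  check_scalar_number(high_hz, "high_hz", strict_min = 0)
  if (low_hz >= high_hz) {
    abort_invalid_spec("`low_hz` must be below `high_hz`")
  }
  if (high_hz >= fs / 2) {
    abort_invalid_spec(sprintf(
      "`high_hz` (%g Hz) must be below the Nyquist rate (%g Hz)", high_hz, fs / 2
    ))
  }
  n <- nrow(trace)
  # forward-backward filtering needs a few filter lengths of signal to settle
  min_n <- 3 * (2 * order + 1)
  if (n < min_n) {
    abort_insufficient_data(sprintf(
      "trace too short to filter: %d samples, need at least %d", n, min_n
    ))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  y <- if (isTRUE(bidirectional)) {
    signal::filtfilt(bf, trace$v)
  } else {
    as.numeric(signal::filter(bf, trace$v))
  }
  new_betacage_trace(y, fs, trace_t0(trace),
    unit = trace_unit(trace), class = "lfp_trace"
  )
}

#' Sliding-window rectified power
#'
#' The conditioned quantity: a running average of the rectified (absolute
#' value) signal over a trailing window, 500 ms by default.  The window is
#' trailing (causal) because the original detector ran online.  During the
#' first partial window the mean is taken over the samples available so far,
#' so the output has the same length as the input.
#'
#' @param trace A band-limited [lfp_trace()].
#' @param window_ms Averaging window in milliseconds (default 500).
#'
#' @return A [power_trace()] of the same length and sampling rate.
#' @export
rectified_power <- function(trace, window_ms = 500) {
  check_scalar_number(window_ms, "window_ms", strict_min = 0)
  n <- nrow(trace)
  if (n < 1) {
    abort_insufficient_data("cannot compute power of an empty trace")
  }
  fs <- trace_fs(trace)
  w <- max(1L, as.integer(round(window_ms / 1000 * fs)))
  if (n * 1000 / fs < window_ms) {
    abort_insufficient_data(sprintf(
      "trace duration (%.3g ms) is shorter than the %g ms window",
      n * 1000 / fs, window_ms
    ))
  }
  cs <- cumsum(abs(trace$v))
  lagged <- c(rep(0, min(w, n)), cs)[seq_len(n)]
  denom <- pmin(seq_len(n), w)
  power_trace((cs - lagged) / denom,
    fs = fs, t0 = trace_t0(trace), unit = trace_unit(trace)
  )
}

#' Quantize a power trace to integer units
#'
#' Mirrors the on-chip integer power representation: values become
#' `floor(value * scale)`.  Thresholds calibrated against quantized power are
#' whole numbers, matching the integer-based power computation the deployed
#' detector used.
#'
#' @param power A [power_trace()].
#' @param scale Positive units-per-microvolt factor (default 1).
#'
#' @return A quantized `power_trace`.
#' @export
quantize_power <- function(power, scale = 1) {
  check_scalar_number(scale, "scale", strict_min = 0)
  power_trace(floor(power$v * scale),
    fs = trace_fs(power), t0 = trace_t0(power),
    unit = sprintf("int(%g/%s)", scale, trace_unit(power)), quantized = TRUE
  )
}
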