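#' Event-triggered average of a trace or GMV series
#'
#' Aligns windows of a uniformly sampled signal to a set of event times and
#' averages them on a common relative-time grid — the peri-event averaging
#' used to reveal consistent structure around rewards (e.g. the pre-event
#' movement pause and post-event retrieval peak, or the post-reward beta
#' drop).  Events whose `[-pre_s, +post_s]` window does not lie fully inside
#' the record are excluded and counted.
#'
#' @param x A [power_trace()], [lfp_trace()] or [gmv_series()] (any tibble
#'   with a `t` column plus a `v` or `total` value column).
#' @param event_times Numeric vector of event times (seconds).
#' @param pre_s,post_s Window extent before/after each event (seconds).
#' @param value_col Name of the value column; chosen automatically when
#'   omitted (`v` for traces, `total` for GMV series).
#'
#' @return An object of class `eta`: list with `t_rel` (relative time grid),
#'   `mean`, `se`, `n_events`, `n_excluded`, and the aligned `windows` matrix
#'   (one row per usable event).
#' @export
#' @examples
#' p <- power_trace(seq(0, 1, length.out = 101), fs = 100)
#' ev <- event_triggered_average(p, 0.5, pre_s = 0.1, post_s = 0.1)
#' ev$n_events
event_triggered_average <- function(x, event_times, pre_s, post_s,
                                    value_col = NULL) {
  check_scalar_number(pre_s, "pre_s", min = 0)
  check_scalar_number(post_s, "post_s", min = 0)
  if (is.null(value_col)) {
    value_col <- if ("v" %in% names(x)) "v" else "total"
  }
  if (!all(c("t", value_col) %in% names(x))) {
    abort_invalid_spec("`x` must have a `t` column and a value column")
  }
  v <- x[[value_col]]
  t <- x$t
  fs <- trace_fs(x)
  wpre <- as.integer(round(pre_s * fs))
  wpost <- as.integer(round(post_s * fs))
  n <- length(v)
  centers <- as.integer(round((event_times - t[1]) * fs)) + 1L
  usable <- centers - wpre >= 1L & centers + wpost <= n
  if (!any(usable)) {
    abort_insufficient_data(
      "no event has a full window inside the record"
    )
  }
  idx_rel <- (-wpre):wpost
  windows <- t(vapply(
    centers[usable],
    function(c0) v[c0 + idx_rel],
    numeric(length(idx_rel))
  ))
  m <- colMeans(windows)
  se <- if (nrow(windows) > 1) {
    apply(windows, 2, stats::sd) / sqrt(nrow(windows))
  } else {
    rep(NA_real_, ncol(windows))
  }
  structure(
    list(
      t_rel = idx_rel / fs, mean = m, se = se,
      n_events = sum(usable), n_excluded = sum(!usable),
      windows = windows, value_col = value_col
    ),
    class = "eta"
  )
}

#' @export
print.eta <- function(x, ...) {
  cat(sprintf(
    "<event-triggered average> %d events (%d excluded), window [%+.2f, %+.2f] s\n",
    x$n_events, x$n_excluded, x$t_rel[1], x$t_rel[length(x$t_rel)]
  ))
  invisible(x)
}

#' @method tidy eta
#' @export
tidy.eta <- function(x, ...) {
  tibble(t = x$t_rel, mean = x$mean, se = x$se)
}

#' @method glance eta
#' @export
glance.eta <- function(x, ...) {
  tibble(
    n_events = x$n_events, n_excluded = x$n_excluded,
    pre_s = -x$t_rel[1], post_s = x$t_rel[length(x$t_rel)]
  )
}
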