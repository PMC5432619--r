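#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session record> %.0f s, %d events (%d rewarded), %d epochs, seed %s\n",
    x$config$duration_s, nrow(x$events), sum(x$events$rewarded, na.rm = TRUE),
    nrow(x$schedule), format(x$seed %||% NA)
  ))
  invisible(x)
}

#' Tidy and summarize a session record
#'
#' `tidy()` returns the epoch-labeled event table; `glance()` a one-row
#' session summary (duration, event counts, R/NR rates).
#'
#' @param x A `session_record` (see [synth_session()]).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy session_record
#' @export
tidy.session_record <- function(x, ...) {
  as_tibble(x$events)
}

#' @rdname tidy.session_record
#' @method glance session_record
#' @export
glance.session_record <- function(x, ...) {
  # a kind absent from the schedule reports NA rather than erroring
  rate_of <- function(k) {
    mins <- sum(x$schedule$end_s[x$schedule$kind == k] -
                  x$schedule$start_s[x$schedule$kind == k]) / 60
    if (mins == 0) {
      return(NA_real_)
    }
    sum(x$events$epoch_kind == k, na.rm = TRUE) / mins
  }
  tibble(
    duration_s = x$config$duration_s,
    n_events = nrow(x$events),
    n_rewarded = sum(x$events$rewarded, na.rm = TRUE),
    r_rate = rate_of("R"),
    nr_rate = rate_of("NR")
  )
}
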