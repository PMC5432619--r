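#' Reward rates per epoch kind
#'
#' Events per minute separately for Reinforced and Non-Reinforced epochs:
#' the count of events labeled with each kind divided by the total minutes
#' that kind occupies in the schedule.  Comparing the two rates shows whether
#' the subject discriminates when reward is available.
#'
#' @param events An epoch-labeled `reward_events` tibble (see
#'   [gate_events()]).
#' @param schedule The [schedule_epochs()] schedule the events were labeled
#'   with.
#'
#' @return A tibble with columns `kind`, `n`, `minutes`, `rate`.
#' @export
epoch_rates <- function(events, schedule) {
  out <- purrr::map_dfr(c("R", "NR"), function(k) {
    mins <- sum(schedule$end_s[schedule$kind == k] -
                  schedule$start_s[schedule$kind == k]) / 60
    if (mins == 0) {
      abort_undefined_rate(sprintf(
        "no %s time in the schedule: the %s rate is undefined", k, k
      ))
    }
    tibble(kind = k, n = sum(events$epoch_kind == k, na.rm = TRUE),
           minutes = mins)
  })
  out$rate <- out$n / out$minutes
  out
}

#' Normalized performance across sessions
#'
#' The cross-session performance metric: for each session,
#' `d = R events/min - NR events/min`, normalized to the maximum absolute
#' difference across the provided sessions, so values lie in `[-1, 1]` (all
#' zeros when every session has equal rates).  Scale-invariant by
#' construction.
#'
#' @param summaries A tibble with one row per session and columns `r_rate`
#'   and `nr_rate` (events/min).
#'
#' @return The input with columns `d` and `performance` added.
#' @export
#' @examples
#' performance_metric(tibble::tibble(r_rate = c(2, 3, 5), nr_rate = 1))
performance_metric <- function(summaries) {
  if (nrow(summaries) < 1) {
    abort_insufficient_data("at least one session summary is required")
  }
  d <- summaries$r_rate - summaries$nr_rate
  mx <- max(abs(d))
  summaries$d <- d
  summaries$performance <- if (mx > 0) d / mx else d * 0
  summaries
}

#' Event-triggered power averages for R vs NR events
#'
#' Averages the band-passed, rectified power around events occurring during
#' Reinforced epochs and, separately, Non-Reinforced epochs on a common
#' relative-time grid.  The deployed system's signature result: the
#' post-reward beta drop is present after R events (pellet retrieval) and
#' absent after NR events (nothing to retrieve).
#'
#' @param power A [power_trace()].
#' @param r_events,nr_events Event times (numeric) or `reward_events` rows
#'   for each epoch kind; both must be nonempty.
#' @param pre_s,post_s Window extent (defaults 5 and 10 s).
#'
#' @return A list of class `triggered_compare` with `eta` elements `r` and
#'   `nr`.
#' @export
triggered_compare <- function(power, r_events, nr_events,
                              pre_s = 5, post_s = 10) {
  r_t <- if (is.data.frame(r_events)) r_events$t else r_events
  nr_t <- if (is.data.frame(nr_events)) nr_events$t else nr_events
  if (length(r_t) == 0) {
    abort_insufficient_data("the R event set is empty")
  }
  if (length(nr_t) == 0) {
    abort_insufficient_data("the NR event set is empty")
  }
  structure(
    list(
      r = event_triggered_average(power, r_t, pre_s, post_s),
      nr = event_triggered_average(power, nr_t, pre_s, post_s)
    ),
    class = "triggered_compare"
  )
}

#' @export
print.triggered_compare <- function(x, ...) {
  cat(sprintf(
    "<triggered compare> R: %d events, NR: %d events\n",
    x$r$n_events, x$nr$n_events
  ))
  invisible(x)
}

#' @method tidy triggered_compare
#' @export
tidy.triggered_compare <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$r), kind = "R"),
    dplyr::mutate(tidy(x$nr), kind = "NR")
  )
}

#' Permutation test for the R-only post-event power drop
#'
#' Tests whether mean post-event power is lower after R events than after NR
#' events by permuting the R/NR labels over the pooled events.  The statistic
#' is `mean(NR post-event power) - mean(R post-event power)` (positive when R
#' shows the retrieval drop); the p-value is one-sided with the +1
#' correction.
#'
#' @inheritParams triggered_compare
#' @param post_window Two-vector window (s after the event) over which each
#'   event's mean power is taken (default `c(0.5, 5)`, skipping the
#'   transmission artifact).
#' @param n_perm Number of label permutations (default 200).
#' @param seed RNG seed for the permutations.
#'
#' @return A one-row tibble with `statistic`, `p.value`, `n_r`, `n_nr`,
#'   `n_perm`.
#' @export
triggered_drop_test <- function(power, r_events, nr_events,
                                post_window = c(0.5, 5), n_perm = 200,
                                seed = 1) {
  r_t <- if (is.data.frame(r_events)) r_events$t else r_events
  nr_t <- if (is.data.frame(nr_events)) nr_events$t else nr_events
  if (length(r_t) == 0 || length(nr_t) == 0) {
    abort_insufficient_data("both event sets must be nonempty")
  }
  fs <- trace_fs(power)
  post_mean <- function(e) {
    i0 <- as.integer(round((e - power$t[1]) * fs)) + 1L
    idx <- (i0 + as.integer(round(post_window[1] * fs))):
      (i0 + as.integer(round(post_window[2] * fs)))
    idx <- idx[idx >= 1 & idx <= nrow(power)]
    if (length(idx) == 0) NA_real_ else mean(power$v[idx])
  }
  r_m <- vapply(r_t, post_mean, numeric(1))
  nr_m <- vapply(nr_t, post_mean, numeric(1))
  vals <- c(r_m[!is.na(r_m)], nr_m[!is.na(nr_m)])
  n_r <- sum(!is.na(r_m))
  stat <- mean(vals[-seq_len(n_r)]) - mean(vals[seq_len(n_r)])
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample(length(vals), n_r)
      mean(vals[-lab]) - mean(vals[lab])
    }, numeric(1))
  })
  tibble(
    statistic = stat,
    p.value = (1 + sum(perm >= stat)) / (n_perm + 1),
    n_r = n_r, n_nr = length(vals) - n_r, n_perm = n_perm
  )
}

#' Correlation between movement (GMV) and beta power
#'
#' Pearson correlation between the GMV series and the band power
#' interpolated at the GMV timestamps — the session-level check of the
#' inverse movement/beta relationship.
#'
#' @param gmv A [gmv_series()] (its `total` column is used).
#' @param power A [power_trace()].
#'
#' @return A one-row tibble with `estimate`, `p.value`, `n`.
#' @export
gmv_beta_correlation <- function(gmv, power) {
  p_at <- approx(power$t, power$v, xout = gmv$t, rule = 2)$y
  ct <- cor.test(gmv$total, p_at, method = "pearson")
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
         n = nrow(gmv))
}

#' Estimate the post-reward recovery time from a triggered average
#'
#' Fits the linear recovery segment of an event-triggered power average and
#' returns the time at which the fit re-crosses the pre-event baseline.  The
#' baseline is the mean over `baseline_window`; the recovery segment is taken
#' between 10% and 85% of the climb from the post-event minimum back to
#' baseline, after smoothing with a short moving average.
#'
#' @param eta An [event_triggered_average()] of power around rewarded events.
#' @param baseline_window Window (s, relative to the event) for the baseline
#'   mean (default `c(-6, -2)`, clear of the pre-event volitional burst).
#' @param search_window Window (s) within which the minimum and recovery are
#'   sought (default `c(0.3, 15)`).
#' @param smooth_s Moving-average width for the profile (default 0.5 s).
#'
#' @return Estimated recovery time in seconds (`NA` if no drop is present).
#' @export
estimate_recovery_time <- function(eta, baseline_window = c(-6, -2),
                                   search_window = c(0.3, 15),
                                   smooth_s = 0.5) {
  t <- eta$t_rel
  fs <- 1 / median(diff(t))
  k <- max(1L, as.integer(round(smooth_s * fs)))
  sm <- as.numeric(stats::filter(eta$mean, rep(1 / k, k), sides = 2))
  base <- mean(sm[t >= baseline_window[1] & t <= baseline_window[2]],
               na.rm = TRUE)
  in_search <- which(t >= search_window[1] & t <= search_window[2] & !is.na(sm))
  if (length(in_search) < 3) {
    return(NA_real_)
  }
  i_min <- in_search[which.min(sm[in_search])]
  if (sm[i_min] >= base) {
    return(NA_real_)
  }
  climb <- (sm - sm[i_min]) / (base - sm[i_min])
  seg <- which(seq_along(t) >= i_min & t <= search_window[2] &
                 climb >= 0.1 & climb <= 0.85 & !is.na(sm))
  # stop the segment at the first re-crossing of baseline
  over <- which(seq_along(t) > i_min & climb >= 1)
  if (length(over)) seg <- seg[seg < over[1]]
  if (length(seg) < 3) {
    return(NA_real_)
  }
  fit <- lm(sm[seg] ~ t[seg])
  slope <- stats::coef(fit)[2]
  if (!is.finite(slope) || slope <= 0) {
    return(NA_real_)
  }
  unname((base - stats::coef(fit)[1]) / slope)
}

#' Session status report
#'
#' The remote-monitoring summary the deployed system emailed: running
#' status, total event count, timestamp of the most recent event, and
#' uptime.  Rendered to JSON or plain text by [write_report()].
#'
#' @param session A `session_record` (or any list with an `events` tibble
#'   and a `config$duration_s`).
#' @param as_of_t Report time, seconds on the session clock.
#'
#' @return A list of class `status_report`.
#' @export
status_report <- function(session, as_of_t) {
  check_scalar_number(as_of_t, "as_of_t")
  if (as_of_t < 0) {
    abort_invalid_spec("`as_of_t` precedes the session start")
  }
  ev <- session$events
  seen <- ev[ev$t <= as_of_t, , drop = FALSE]
  structure(
    list(
      status = if (as_of_t <= session$config$duration_s) "running" else "idle",
      as_of_t = as_of_t,
      uptime_s = min(as_of_t, session$config$duration_s),
      total_events = nrow(seen),
      last_event_t = if (nrow(seen)) max(seen$t) else NULL
    ),
    class = "status_report"
  )
}

#' @export
print.status_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

format_report <- function(x) {
  c(
    sprintf("status: %s", x$status),
    sprintf("uptime: %.1f s (as of t = %.1f s)", x$uptime_s, x$as_of_t),
    sprintf("total events: %d", x$total_events),
    sprintf("last event: %s",
            if (is.null(x$last_event_t)) "none" else
              sprintf("t = %.3f s", x$last_event_t))
  )
}
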