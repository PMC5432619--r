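#' Detect reward events from a power trace
#'
#' Emits an event whenever power reaches the threshold, gated by a refractory
#' lockout: no event can occur within `lockout_s` of the previous one (10 s by
#' default, matching the deployed system; the hardware allowed 5-10 s).
#'
#' Two retrigger modes are supported.  In `"level"` mode (default) a sustained
#' supra-threshold power re-triggers as soon as the lockout expires — the
#' lockout is the sole gate, so constant supra-threshold power yields events
#' exactly `lockout_s` apart.  In `"edge"` mode the power must additionally
#' cross from below the threshold.
#'
#' @param power A [power_trace()].
#' @param threshold Power level; events fire where `v >= threshold`.
#' @param lockout_s Refractory period in seconds (default 10).
#' @param retrigger `"level"` (default) or `"edge"`.
#'
#' @return A tibble of class `reward_events` with columns `event_id`, `t`,
#'   `epoch_kind` (`NA` until labeled by [gate_events()]) and `rewarded`.
#' @export
#' @examples
#' p <- power_trace(c(rep(0, 10), rep(5, 10), rep(0, 10)), fs = 1)
#' detect_events(p, threshold = 3, lockout_s = 5)
detect_events <- function(power, threshold, lockout_s = 10,
                          retrigger = c("level", "edge")) {
  retrigger <- match.arg(retrigger)
  check_scalar_number(threshold, "threshold")
  check_scalar_number(lockout_s, "lockout_s", strict_min = 0)
  if (is.null(power) || nrow(power) == 0) {
    abort_insufficient_data("cannot detect events in an empty power trace")
  }
  v <- power$v
  cand <- if (retrigger == "level") {
    which(v >= threshold)
  } else {
    # first sample counts as a crossing if already supra-threshold
    which(v >= threshold & dplyr::lag(v, default = -Inf) < threshold)
  }
  tt <- power$t[cand]
  eps <- 1e-9
  times <- numeric(0)
  i <- 1L
  n <- length(tt)
  while (i <= n) {
    times <- c(times, tt[i])
    # jump to the first candidate at or past lockout expiry
    nxt <- tt[i] + lockout_s - eps
    i <- findInterval(nxt, tt, left.open = TRUE) + 1L
  }
  new_reward_events(times)
}

new_reward_events <- function(times, epoch_kind = NA_character_,
                              rewarded = NA) {
  out <- tibble(
    event_id = seq_along(times),
    t = as.double(times),
    epoch_kind = rep_len(epoch_kind, length(times)),
    rewarded = rep_len(rewarded, length(times))
  )
  class(out) <- c("reward_events", class(out))
  out
}

#' Calibrate the reward threshold from a baseline recording
#'
#' Reproduces the protocol's threshold-setting rule: given an unrewarded
#' baseline power trace, find the threshold such that, had the baseline been a
#' rewarded session, the subject would have received the chosen number of
#' rewards.  Concretely, returns the largest integer threshold `T` for which
#' [detect_events()] on the baseline (with the same lockout) yields at least
#' `target_count` events.  `target_count = 0` returns `max(power) + 1` so no
#' event can fire.
#'
#' @param baseline A quantized (integer-valued) [power_trace()], see
#'   [quantize_power()].
#' @param target_count Desired baseline reward count (nonnegative integer).
#' @param lockout_s Refractory period used during detection (default 10).
#' @param retrigger Passed to [detect_events()].
#'
#' @return A single integer threshold.
#' @export
calibrate_threshold <- function(baseline, target_count, lockout_s = 10,
                                retrigger = c("level", "edge")) {
  retrigger <- match.arg(retrigger)
  check_scalar_number(target_count, "target_count", min = 0)
  if (is.null(baseline) || nrow(baseline) == 0) {
    abort_insufficient_data("cannot calibrate against an empty baseline")
  }
  v <- baseline$v
  if (!isTRUE(all(v == floor(v)))) {
    abort_invalid_spec(
      "baseline power must be integer-valued; quantize it first (see quantize_power())"
    )
  }
  top <- max(v)
  if (target_count == 0) {
    return(top + 1)
  }
  count_at <- function(thr) {
    nrow(detect_events(baseline, thr, lockout_s, retrigger))
  }
  achievable <- count_at(1)
  if (achievable < target_count) {
    abort_calibration_infeasible(
      sprintf(
        "target of %d events is unreachable: at threshold 1 the baseline yields only %d",
        target_count, achievable
      ),
      achievable = achievable
    )
  }
  # event count is non-increasing in threshold: binary search for the largest
  # threshold still reaching the target
  lo <- 1
  hi <- top
  while (lo < hi) {
    mid <- ceiling((lo + hi) / 2)
    if (count_at(mid) >= target_count) lo <- mid else hi <- mid - 1
  }
  lo
}

#' Build an alternating Reinforced / Non-Reinforced epoch schedule
#'
#' Tiles `[0, session_s)` with alternating Reinforced (R, reward available)
#' and Non-Reinforced (NR, events logged but unrewarded) epochs.  The deployed
#' protocol used 2-5 minute epochs (sessions 1-2 ran 2 min R : 2 min NR;
#' sessions 3-8 ran 5 min R : 10 min NR).  The final epoch is truncated at the
#' session end.  Epoch intervals are half-open `[start, end)`.
#'
#' @param session_s Session length in seconds (0 gives an empty schedule).
#' @param r_duration_s,nr_duration_s Epoch durations in seconds (defaults 120).
#' @param start_kind First epoch kind, `"R"` (default) or `"NR"`.
#' @param r_cue_hz Continuous cue tone frequency marking R epochs (default
#'   700 Hz, the feeder tone), stored as an attribute.
#'
#' @return A tibble of class `epoch_schedule` with columns `kind`, `start_s`,
#'   `end_s`.
#' @export
#' @examples
#' schedule_epochs(480, 120, 120)
schedule_epochs <- function(session_s, r_duration_s = 120, nr_duration_s = 120,
                            start_kind = c("R", "NR"), r_cue_hz = 700) {
  start_kind <- match.arg(start_kind)
  check_scalar_number(session_s, "session_s", min = 0)
  check_scalar_number(r_duration_s, "r_duration_s", strict_min = 0)
  check_scalar_number(nr_duration_s, "nr_duration_s", strict_min = 0)
  kinds <- character(0)
  starts <- numeric(0)
  ends <- numeric(0)
  cur <- 0
  kind <- start_kind
  while (cur < session_s) {
    dur <- if (kind == "R") r_duration_s else nr_duration_s
    kinds <- c(kinds, kind)
    starts <- c(starts, cur)
    ends <- c(ends, min(cur + dur, session_s))
    cur <- cur + dur
    kind <- if (kind == "R") "NR" else "R"
  }
  out <- tibble(kind = kinds, start_s = starts, end_s = ends)
  attr(out, "r_cue_hz") <- r_cue_hz
  class(out) <- c("epoch_schedule", class(out))
  out
}

#' Label events by their containing epoch
#'
#' Assigns each event to the epoch whose half-open interval `[start, end)`
#' contains it; events outside the schedule span are labeled `"baseline"`.
#' `rewarded` is `TRUE` only inside R epochs — during NR epochs events are
#' counted for analysis but no reward is delivered, and the lockout (enforced
#' upstream by [detect_events()]) runs continuously across epoch boundaries.
#'
#' @param events A `reward_events` tibble (sorted by time).
#' @param schedule An [schedule_epochs()] result.
#'
#' @return The events tibble with `epoch_kind` and `rewarded` filled in.
#' @export
gate_events <- function(events, schedule) {
  if (nrow(events) == 0) {
    return(events)
  }
  if (is.unsorted(events$t)) {
    abort_ordering("event times must be sorted increasing")
  }
  kind <- rep("baseline", nrow(events))
  if (nrow(schedule) > 0) {
    idx <- findInterval(events$t, schedule$start_s)
    inside <- idx >= 1 & events$t < schedule$end_s[pmax(idx, 1)]
    kind[inside] <- schedule$kind[idx[inside]]
  }
  events$epoch_kind <- kind
  events$rewarded <- kind == "R"
  events
}

#' Audio feedback schedule for a reward event
#'
#' Each delivered reward triggers three short beeps (1200 Hz, 250 ms on,
#' 250 ms off) cueing the subject that food is available.  The audio unit is
#' configurable within hardware limits: tone frequencies 10-4000 Hz and a
#' minimum on-time of 50 ms; requests outside those ranges are rejected.
#'
#' @param event A single-row `reward_events` tibble or a scalar event time.
#' @param freq_hz Beep frequency (default 1200).
#' @param on_ms,off_ms Beep on/off durations in ms (defaults 250/250).
#' @param n_beeps Number of beeps (default 3).
#'
#' @return A tibble of class `audio_schedule` with columns `onset_s`,
#'   `freq_hz`, `on_ms`, `off_ms`.
#' @export
#' @examples
#' audio_for_event(10)
audio_for_event <- function(event, freq_hz = 1200, on_ms = 250, off_ms = 250,
                            n_beeps = 3) {
  t <- if (is.data.frame(event)) event$t[1] else event
  check_scalar_number(t, "event time")
  check_scalar_number(n_beeps, "n_beeps", min = 1)
  if (freq_hz < 10 || freq_hz > 4000) {
    abort_invalid_spec("tone frequency must lie within the 10-4000 Hz hardware range")
  }
  if (on_ms < 50) {
    abort_invalid_spec("beep on-time must be at least the 50 ms hardware minimum")
  }
  check_scalar_number(off_ms, "off_ms", min = 0)
  out <- tibble(
    onset_s = t + (seq_len(n_beeps) - 1) * (on_ms + off_ms) / 1000,
    freq_hz = freq_hz, on_ms = on_ms, off_ms = off_ms
  )
  class(out) <- c("audio_schedule", class(out))
  out
}
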