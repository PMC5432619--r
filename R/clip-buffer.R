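#' Rolling event-triggered clip buffer
#'
#' State machine mirroring the video-snippet recorder: frames stream in at
#' `source_fps`, every `decimation`-th frame is retained (the deployed system
#' processed and saved every 4th frame of a 32 fps feed, i.e. stored 8 fps),
#' and the buffer keeps a rolling `buffer_s` seconds (default 8 s).  When an
#' event triggers, the buffer keeps running `post_s` more seconds and the
#' frames in `[trigger - pre_s, trigger + post_s]` are saved as a clip tagged
#' with the event id.
#'
#' @param buffer_s Rolling capacity in seconds (default 8).
#' @param pre_s Seconds kept before a trigger (default 4; must be
#'   `<= buffer_s`).
#' @param post_s Seconds recorded after a trigger (default 4).
#' @param source_fps Camera frame rate (default 32).
#' @param decimation Keep every Nth pushed frame (default 4).
#'
#' @return A list of class `clip_buffer` holding the configuration, the
#'   retained frames, pending triggers and finalized clips.
#' @export
#' @examples
#' st <- clip_buffer()
#' clip_stored_fps(st)
clip_buffer <- function(buffer_s = 8, pre_s = 4, post_s = 4,
                        source_fps = 32, decimation = 4) {
  for (nm in c("buffer_s", "pre_s", "post_s", "source_fps", "decimation")) {
    check_scalar_number(get(nm), nm, strict_min = 0)
  }
  if (pre_s > buffer_s) {
    abort_invalid_spec("`pre_s` cannot exceed the rolling capacity `buffer_s`")
  }
  structure(
    list(
      config = list(
        buffer_s = buffer_s, pre_s = pre_s, post_s = post_s,
        source_fps = source_fps, decimation = as.integer(decimation)
      ),
      n_pushed = 0L,
      last_t = -Inf,
      frames = tibble(t = numeric(0), seq = integer(0), payload = list()),
      pending = list(),
      clips = list()
    ),
    class = "clip_buffer"
  )
}

#' @rdname clip_buffer
#' @param state A `clip_buffer` state.
#' @export
clip_stored_fps <- function(state) {
  state$config$source_fps / state$config$decimation
}

#' Push a frame into the clip buffer
#'
#' The frame is retained only if it passes decimation (the 1st, (N+1)-th,
#' ... pushed frames); retained frames older than `buffer_s` before the
#' newest are evicted.  Any pending clip whose post-trigger window has fully
#' elapsed is finalized first.
#'
#' @param state A [clip_buffer()] state.
#' @param t Frame timestamp in seconds; must exceed the previous frame's.
#' @param payload Arbitrary frame payload (e.g. a depth matrix or an index);
#'   stored as-is.
#'
#' @return The updated state.
#' @export
push_frame <- function(state, t, payload = NULL) {
  check_scalar_number(t, "t")
  if (t <= state$last_t) {
    abort_ordering(sprintf(
      "frame timestamp %g is not after the previous frame (%g)", t, state$last_t
    ))
  }
  keep <- state$n_pushed %% state$config$decimation == 0L
  state$n_pushed <- state$n_pushed + 1L
  state$last_t <- t
  if (keep) {
    state$frames <- dplyr::bind_rows(
      state$frames,
      tibble(t = t, seq = state$n_pushed, payload = list(payload))
    )
  }
  state <- finalize_ready(state, now = t)
  # evict strictly-older-than-capacity frames; the boundary frame stays so a
  # trigger at now - post_s still finds its full pre window
  state$frames <- state$frames[state$frames$t >= t - state$config$buffer_s, ]
  state
}

#' Register an event trigger
#'
#' Marks a clip pending at `trigger_t`; it finalizes once frames beyond
#' `trigger_t + post_s` have been pushed (or when [collect_clips()] is called
#' with `flush = TRUE`).  Event ids must be unique — clip tagging is
#' injective.
#'
#' @param state A [clip_buffer()] state.
#' @param event_id Scalar identifier for the event.
#' @param trigger_t Trigger time in seconds.
#'
#' @return The updated state.
#' @export
trigger_clip <- function(state, event_id, trigger_t) {
  check_scalar_number(trigger_t, "trigger_t")
  ids <- c(
    vapply(state$pending, function(p) as.character(p$event_id), character(1)),
    vapply(state$clips, function(p) as.character(p$event_id), character(1))
  )
  if (as.character(event_id) %in% ids) {
    abort_invalid_spec(sprintf("event id %s already has a clip", event_id))
  }
  state$pending <- c(state$pending,
    list(list(event_id = event_id, trigger_t = trigger_t))
  )
  state
}

finalize_ready <- function(state, now, flush = FALSE) {
  if (length(state$pending) == 0) {
    return(state)
  }
  still <- list()
  for (p in state$pending) {
    if (flush || now >= p$trigger_t + state$config$post_s) {
      state$clips <- c(state$clips, list(make_clip(state, p)))
    } else {
      still <- c(still, list(p))
    }
  }
  state$pending <- still
  state
}

make_clip <- function(state, p) {
  cfg <- state$config
  lo <- p$trigger_t - cfg$pre_s
  hi <- p$trigger_t + cfg$post_s
  fr <- state$frames[state$frames$t >= lo & state$frames$t <= hi, ]
  structure(
    list(
      event_id = p$event_id, trigger_t = p$trigger_t,
      frames = fr,
      window = c(lo, hi),
      fps = clip_stored_fps(state),
      short_pre = nrow(fr) == 0 ||
        min(fr$t) > lo + cfg$decimation / cfg$source_fps
    ),
    class = "clip"
  )
}

#' Collect finalized clips
#'
#' Returns the clips finalized so far and removes them from the state.  With
#' `flush = TRUE`, pending clips are finalized immediately with whatever
#' post-trigger frames have arrived (used at end of session).
#'
#' @param state A [clip_buffer()] state.
#' @param flush Finalize pending clips too? Default `FALSE`.
#'
#' @return A list with `clips` (list of `clip` objects) and `state`.
#' @export
collect_clips <- function(state, flush = FALSE) {
  state <- finalize_ready(state, now = state$last_t, flush = flush)
  clips <- state$clips
  state$clips <- list()
  list(clips = clips, state = state)
}

#' @export
print.clip <- function(x, ...) {
  cat(sprintf(
    "<clip event %s> trigger %.3f s, %d frames @ %g fps, window [%.3f, %.3f]%s\n",
    x$event_id, x$trigger_t, nrow(x$frames), x$fps, x$window[1], x$window[2],
    if (x$short_pre) " (short pre)" else ""
  ))
  invisible(x)
}

#' Extract event clips from a whole frame stream
#'
#' Convenience wrapper running the [clip_buffer()] state machine over a full
#' session: every frame is pushed in order, triggers are interleaved at their
#' event times, and all clips are collected (flushing at the end).
#'
#' @param frame_times Strictly increasing frame timestamps (s).
#' @param events A `reward_events` tibble (or numeric event times).
#' @param config A [clip_buffer()] state carrying the configuration.
#' @param payloads Optional list of per-frame payloads.
#'
#' @return A list of `clip` objects, one per event.
#' @export
extract_clips <- function(frame_times, events, config = clip_buffer(),
                          payloads = NULL) {
  ev <- if (is.data.frame(events)) {
    tibble(event_id = events$event_id, t = events$t)
  } else {
    tibble(event_id = seq_along(events), t = as.double(events))
  }
  state <- config
  j <- 1L
  for (i in seq_along(frame_times)) {
    while (j <= nrow(ev) && ev$t[j] <= frame_times[i]) {
      state <- trigger_clip(state, ev$event_id[j], ev$t[j])
      j <- j + 1L
    }
    state <- push_frame(state, frame_times[i],
      payload = if (is.null(payloads)) i else payloads[[i]]
    )
  }
  while (j <= nrow(ev)) { # events after the last frame
    state <- trigger_clip(state, ev$event_id[j], ev$t[j])
    j <- j + 1L
  }
  collect_clips(state, flush = TRUE)$clips
}
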