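#' Synthetic session configuration
#'
#' Parameters of the fully synthetic closed-loop session generator.  The
#' generator emulates the statistics the deployed system faced: broadband
#' (1/f) LFP background with 10-30 Hz beta whose amplitude is suppressed
#' while the subject moves, strong beta bursts preceding each planned reward
#' event, a post-retrieval beta drop recovering over 3-10 s, 100-150 ms RF
#' transmission artifacts, and depth scenes with a roaming subject blob plus
#' a reflective-bar flicker region giving the characteristic nonzero GMV
#' floor.
#'
#' @param duration_s Session length, seconds (default 600).
#' @param lfp_fs LFP sampling rate, Hz (default 1000).
#' @param frame_fps Depth-camera frame rate, Hz (default 32).
#' @param frame_h,frame_w Depth raster size in pixels (default 96 x 128, a
#'   downscaled camera viewport).
#' @param beta_center_hz Beta oscillation frequency (default 20).
#' @param baseline_beta_amp Resting beta amplitude, µV (default 30).
#' @param burst_rate_per_min Rate of spontaneous beta bursts (default 4).
#' @param burst_gain Amplitude gain of spontaneous bursts over baseline
#'   (default 1.5).
#' @param event_burst_gain Amplitude gain of the volitional burst preceding
#'   each planned event (default 4).
#' @param movement_coupling_gain Movement-to-beta suppression gain `g >= 0`;
#'   the beta envelope is scaled by `max(0, 1 - g * movement)` (default 1).
#' @param retrieval_drop_frac Fractional beta drop after a rewarded event, in
#'   `[0, 1]` (default 0.6).
#' @param retrieval_recovery_s Linear recovery time of the post-reward drop,
#'   seconds, in the observed 3-10 s range (default 5).
#' @param artifact_amp RF transmission artifact amplitude, µV (default 400).
#' @param artifact_dur_ms Two-vector range of artifact durations, ms
#'   (default `c(100, 150)`).
#' @param flicker_pixel_frac Fraction of frame pixels in the reflective
#'   flicker region (default 0.004).
#' @param blob_size_px Subject blob horizontal radius, pixels (default 18).
#' @param blob_speed_px_s Mean in-plane blob speed, px/s (default 20).
#' @param blob_depth_speed_mm_s Mean blob approach/recede speed, mm/s
#'   (default 50).
#' @param noise_sd LFP background (pink noise) SD, µV (default 20).
#' @param event_rate_per_min Planned threshold-crossing rate (default 2).
#' @param r_epoch_s,nr_epoch_s Reinforced / Non-Reinforced epoch durations,
#'   seconds (default 120 each, the 2 min : 2 min protocol).
#' @param background_mm,blob_mm,bar_mm Scene depths: back wall, subject, and
#'   reflective bars, mm (defaults 4000, 2000, 1200).
#' @param near_mm,far_mm Default analysis depth cutoffs (defaults 500, 3500;
#'   they exclude the back wall, as in deployment).
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 600, lfp_fs = 1000, frame_fps = 32,
                         frame_h = 96, frame_w = 128,
                         beta_center_hz = 20, baseline_beta_amp = 30,
                         burst_rate_per_min = 4, burst_gain = 1.5,
                         event_burst_gain = 4, movement_coupling_gain = 1,
                         retrieval_drop_frac = 0.6, retrieval_recovery_s = 5,
                         artifact_amp = 400, artifact_dur_ms = c(100, 150),
                         flicker_pixel_frac = 0.004, blob_size_px = 18,
                         blob_speed_px_s = 20, blob_depth_speed_mm_s = 50,
                         noise_sd = 20, event_rate_per_min = 2,
                         r_epoch_s = 120, nr_epoch_s = 120,
                         background_mm = 4000, blob_mm = 2000, bar_mm = 1200,
                         near_mm = 500, far_mm = 3500) {
  cfg <- as.list(environment())
  for (nm in c("duration_s", "lfp_fs", "frame_fps", "frame_h", "frame_w",
               "beta_center_hz", "baseline_beta_amp", "r_epoch_s",
               "nr_epoch_s")) {
    check_scalar_number(cfg[[nm]], nm, strict_min = 0)
  }
  if (movement_coupling_gain < 0) {
    abort_invalid_spec("`movement_coupling_gain` must be >= 0")
  }
  if (retrieval_drop_frac < 0 || retrieval_drop_frac > 1) {
    abort_invalid_spec("`retrieval_drop_frac` must lie in [0, 1]")
  }
  if (flicker_pixel_frac < 0 || flicker_pixel_frac > 1) {
    abort_invalid_spec("`flicker_pixel_frac` must lie in [0, 1]")
  }
  if (retrieval_recovery_s <= 0) {
    abort_invalid_spec("`retrieval_recovery_s` must be positive")
  }
  if (length(artifact_dur_ms) != 2 || artifact_dur_ms[1] > artifact_dur_ms[2]) {
    abort_invalid_spec("`artifact_dur_ms` must be an increasing range")
  }
  structure(cfg, class = "synth_config")
}

# 1/f ("pink") amplitude-shaped Gaussian noise via FFT filtering.  The FFT
# length is padded to a highly composite size (then truncated) so awkward
# sample counts never hit a slow large-prime transform.
pink_noise <- function(n, sd) {
  if (sd == 0 || n < 2) {
    return(numeric(n))
  }
  m <- stats::nextn(n, 2)
  w <- fft(rnorm(m))
  k <- seq_len(m) - 1
  f <- pmin(k, m - k) # symmetric frequency index
  shape <- c(0, 1 / sqrt(f[-1]))
  x <- Re(fft(w * shape, inverse = TRUE))[seq_len(n)] / m
  x * sd / stats::sd(x)
}

#' Synthesize the subject's movement trajectory
#'
#' A smoothly varying (Ornstein-Uhlenbeck velocity) random walk of the
#' subject blob inside the cage viewport, with an accompanying depth
#' (approach/recede) walk.  Around each planned event the walk reproduces the
#' stereotyped behavior seen on video: a near-pause in the ~1.5 s before the
#' event, and, for rewarded events, a fast reach toward the hopper just
#' after.  The scalar movement intensity is the blob's in-plane speed, so it
#' integrates to the total path length.
#'
#' @param config A [synth_config()].
#' @param seed RNG seed (integer).
#' @param events Optional `reward_events` tibble (or numeric times) of
#'   planned events to modulate around; `rewarded` marks reach bursts.
#'
#' @return A list of class `synth_movement` with `t`, `x`, `y` (pixels),
#'   `z_mm`, and `intensity` (px/s).
#' @export
synth_movement <- function(config, seed, events = NULL) {
  withr::with_seed(seed, {
    dt <- 1 / config$frame_fps
    n <- as.integer(round(config$duration_s * config$frame_fps)) + 1L
    t <- (seq_len(n) - 1) * dt
    tau <- 2 # velocity correlation time, s
    a <- exp(-dt / tau)
    sig_xy <- config$blob_speed_px_s / sqrt(pi / 2)
    sig_z <- config$blob_depth_speed_mm_s / sqrt(pi / 2)
    innov <- sqrt(1 - a^2)
    ou <- function(sig) {
      if (sig == 0) {
        return(numeric(n))
      }
      v <- numeric(n)
      e <- rnorm(n, sd = sig * innov)
      v[1] <- rnorm(1, sd = sig)
      for (k in 2:n) v[k] <- a * v[k - 1] + e[k]
      v
    }
    vx <- ou(sig_xy)
    vy <- ou(sig_xy)
    vz <- ou(sig_z)
    # speed multiplier: pause before every event, reach burst after rewards
    m <- rep(1, n)
    if (!is.null(events)) {
      ev_t <- if (is.data.frame(events)) events$t else as.double(events)
      rew <- if (is.data.frame(events)) events$rewarded else rep(TRUE, length(ev_t))
      for (i in seq_along(ev_t)) {
        m[t >= ev_t[i] - 1.5 & t < ev_t[i]] <- 0.15
        if (isTRUE(rew[i])) {
          m[t >= ev_t[i] & t < ev_t[i] + 1.5] <- 3
        }
      }
    }
    # keep the roaming box non-degenerate even for tiny test frames
    margin_x <- min(config$blob_size_px + 2, config$frame_w / 2 - 1)
    margin_y <- min(config$blob_size_px + 2, config$frame_h / 2 - 1)
    reflect <- function(p, lo, hi) {
      # fold positions back into [lo, hi]
      span <- hi - lo
      q <- (p - lo) %% (2 * span)
      lo + ifelse(q > span, 2 * span - q, q)
    }
    x <- reflect(config$frame_w / 2 + cumsum(vx * m * dt),
                 margin_x, config$frame_w - margin_x)
    y <- reflect(config$frame_h / 2 + cumsum(vy * m * dt),
                 margin_y, config$frame_h - margin_y)
    z <- reflect(config$blob_mm + cumsum(vz * m * dt),
                 config$blob_mm - 400, config$blob_mm + 400)
    step <- sqrt(diff(x)^2 + diff(y)^2)
    structure(
      list(t = t, x = x, y = y, z_mm = z,
           intensity = c(0, step / dt)),
      class = "synth_movement"
    )
  })
}

#' Synthesize a coupled LFP trace
#'
#' Generates pink-noise background plus a beta oscillation whose envelope is
#' `baseline_beta_amp * max(0, 1 - g * movement) * (1 + bursts)`, where
#' `movement` is the intensity normalized by the configured mean blob speed.
#' Spontaneous bursts occur at `burst_rate_per_min`; a stronger volitional
#' burst precedes each planned event so it produces a threshold crossing.
#' After each *rewarded* event the envelope drops by `retrieval_drop_frac`
#' (pellet retrieval) and recovers linearly over `retrieval_recovery_s`;
#' rewarded events also carry a biphasic RF transmission artifact of
#' 100-150 ms.  Non-rewarded events are not transmitted, so they get neither.
#'
#' @param config A [synth_config()].
#' @param movement A [synth_movement()] result, or `NULL` for no coupling.
#' @param events Planned events (`reward_events` tibble or numeric times;
#'   numeric times count as rewarded), or `NULL`.
#' @param seed RNG seed.
#'
#' @return A list with `trace` (an [lfp_trace()]) and `truth` (ground truth:
#'   `envelope`, `movement`, `event_times`, `rewarded`, `burst_times`).
#' @export
synth_lfp <- function(config, movement = NULL, events = NULL, seed = 1) {
  withr::with_seed(seed, {
    fs <- config$lfp_fs
    n <- as.integer(round(config$duration_s * fs)) + 1L
    t <- (seq_len(n) - 1) / fs
    # movement normalized so typical roaming speed suppresses beta partially
    # (g = 1 halves the envelope at the mean speed); only vigorous movement
    # like the retrieval reach silences it, which is what keeps the
    # post-reward drop visible in triggered averages on top of the coupling
    mnorm <- if (is.null(movement) || config$blob_speed_px_s == 0) {
      numeric(n)
    } else {
      approx(movement$t, movement$intensity, xout = t, rule = 2)$y /
        (2 * config$blob_speed_px_s)
    }
    ev_t <- if (is.data.frame(events)) events$t else as.double(events %||% numeric(0))
    rew <- if (is.data.frame(events)) {
      events$rewarded
    } else {
      rep(TRUE, length(ev_t))
    }
    # spontaneous burst process
    n_burst <- rpois(1, config$burst_rate_per_min / 60 * config$duration_s)
    burst_t <- sort(runif(n_burst, 0, config$duration_s))
    bump <- function(center, sd_s, amp) {
      lo <- findInterval(center - 4 * sd_s, t) + 1L
      hi <- findInterval(center + 4 * sd_s, t)
      if (hi < lo) {
        return(NULL)
      }
      list(idx = lo:hi, val = amp * exp(-(t[lo:hi] - center)^2 / (2 * sd_s^2)))
    }
    bursts <- numeric(n)
    for (b in burst_t) {
      bb <- bump(b, 0.2, config$burst_gain)
      if (!is.null(bb)) bursts[bb$idx] <- bursts[bb$idx] + bb$val
    }
    for (e in ev_t) { # volitional burst driving the crossing
      bb <- bump(e - 0.35, 0.15, config$event_burst_gain)
      if (!is.null(bb)) bursts[bb$idx] <- bursts[bb$idx] + bb$val
    }
    # post-retrieval suppression, rewarded events only
    supp <- rep(1, n)
    for (i in seq_along(ev_t)) {
      if (!isTRUE(rew[i])) next
      rel <- t - ev_t[i]
      in_rec <- rel >= 0 & rel < config$retrieval_recovery_s
      supp[in_rec] <- pmin(
        supp[in_rec],
        1 - config$retrieval_drop_frac *
          (1 - rel[in_rec] / config$retrieval_recovery_s)
      )
    }
    envelope <- config$baseline_beta_amp *
      pmax(0, 1 - config$movement_coupling_gain * mnorm) *
      (1 + bursts) * supp
    phase <- runif(1, 0, 2 * pi)
    v <- pink_noise(n, config$noise_sd) +
      envelope * sin(2 * pi * config$beta_center_hz * t + phase)
    # RF transmission artifacts on transmitted (rewarded) events
    for (i in seq_along(ev_t)) {
      if (!isTRUE(rew[i])) next
      dur <- runif(1, config$artifact_dur_ms[1], config$artifact_dur_ms[2]) / 1000
      i0 <- findInterval(ev_t[i], t) + 1L
      half <- as.integer(round(dur / 2 * fs))
      pos <- i0:(i0 + half - 1L)
      neg <- (i0 + half):(i0 + 2L * half - 1L)
      v[pos[pos <= n]] <- v[pos[pos <= n]] + config$artifact_amp
      v[neg[neg <= n]] <- v[neg[neg <= n]] - config$artifact_amp
    }
    list(
      trace = lfp_trace(v, fs = fs),
      truth = list(
        envelope = envelope, movement = mnorm,
        event_times = ev_t, rewarded = rew, burst_times = burst_t
      )
    )
  })
}

# Deterministic per-session depth-frame generator.  All randomness (flicker
# firing, bar depth jitter) is drawn up-front so `gen(i)` is pure in `i` and
# long sessions can stream frames without holding them.
make_frame_generator <- function(config, movement, seed) {
  withr::with_seed(seed, {
    h <- config$frame_h
    w <- config$frame_w
    n <- length(movement$t)
    n_flick <- max(0L, as.integer(round(config$flicker_pixel_frac * h * w)))
    # reflective bar region: a vertical strip near the right frame edge
    bar_rows <- seq.int(max(1L, h %/% 3), min(h, 2L * (h %/% 3)))
    bar_cols <- seq.int(max(1L, w - 5L), w - 1L)
    cells <- expand.grid(r = bar_rows, c = bar_cols)
    pick <- sample.int(nrow(cells), min(n_flick, nrow(cells)))
    bar_idx <- (cells$c[pick] - 1L) * h + cells$r[pick] # column-major linear
    fired <- matrix(runif(length(bar_idx) * n) < 0.7, length(bar_idx), n)
    jitter <- matrix(runif(length(bar_idx) * n, -10, 10), length(bar_idx), n)
    ry <- 1.3 * config$blob_size_px
    rx <- config$blob_size_px
    function(i) {
      mat <- matrix(config$background_mm, h, w)
      rc <- min(h, max(1L, round(movement$y[i])))
      cc <- min(w, max(1L, round(movement$x[i])))
      rows <- max(1L, rc - ceiling(ry)):min(h, rc + ceiling(ry))
      cols <- max(1L, cc - ceiling(rx)):min(w, cc + ceiling(rx))
      mask <- outer(
        ((rows - movement$y[i]) / ry)^2,
        ((cols - movement$x[i]) / rx)^2, "+"
      ) <= 1
      sub <- mat[rows, cols, drop = FALSE]
      sub[mask] <- movement$z_mm[i]
      mat[rows, cols] <- sub
      # the reflective bars sit between camera and subject, so they render
      # on top: the blob can never occlude them
      if (length(bar_idx)) {
        on <- fired[, i]
        mat[bar_idx[on]] <- config$bar_mm + jitter[on, i]
      }
      mat
    }
  })
}

#' Synthesize a depth-frame sequence
#'
#' Renders the scene the movement trajectory describes: a back wall at
#' `background_mm`, a reflective bar strip whose pixels flicker between
#' invalid and a jittered near reading (`bar_mm`) — the source of the nonzero
#' GMV floor — and an ellipsoidal subject blob at the trajectory position and
#' depth.
#'
#' @inheritParams synth_movement
#' @param movement A [synth_movement()] trajectory.
#' @param frame_idx Optional integer subset of frames to render (default all).
#'
#' @return A [depth_seq()].
#' @export
synth_depth_frames <- function(config, movement, seed,
                               frame_idx = seq_along(movement$t)) {
  gen <- make_frame_generator(config, movement, seed)
  depth_seq(lapply(frame_idx, gen), movement$t[frame_idx],
    fps = config$frame_fps
  )
}

#' Synthesize a complete closed-loop session
#'
#' End-to-end composition with known ground truth: plans rewardable events on
#' an alternating R/NR epoch schedule, generates the movement trajectory
#' (with the pre-event pause and post-reward retrieval reach), the coupled
#' LFP, and the depth scene; then runs the power pipeline (bandpass 10-30 Hz,
#' 500 ms rectified window, integer quantization) and the streaming GMV
#' computation exactly as an analysis of recorded data would.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; the whole session is deterministic given
#'   `(config, seed)`.
#' @param keep_frames Also materialize and return the depth frames?  Default
#'   `FALSE` (frames are streamed through the GMV computation and dropped).
#' @param roi Analysis ROI; defaults to the full frame with the configured
#'   depth cutoffs (excluding the back wall) and a 2 x 2 quadrant grid.
#'
#' @return A list of class `session_record` with elements `lfp`, `power`
#'   (quantized), `events` (planned, epoch-labeled), `schedule`, `gmv`,
#'   `clips` (empty manifest), `roi`, `config`, `truth`, and optionally
#'   `frames`.
#' @export
synth_session <- function(config = synth_config(), seed = 1,
                          keep_frames = FALSE, roi = NULL) {
  schedule <- schedule_epochs(config$duration_s, config$r_epoch_s,
                              config$nr_epoch_s)
  # planned rewardable crossings, jittered around the configured rate
  ev_t <- if (config$event_rate_per_min <= 0) {
    numeric(0)
  } else {
    spacing <- 60 / config$event_rate_per_min
    withr::with_seed(seed, {
      base <- seq(min(spacing / 2, config$duration_s), config$duration_s - 5,
                  by = spacing)
      jit <- runif(length(base), 0, 0.2 * spacing)
      sort(base + jit)
    })
  }
  events <- gate_events(new_reward_events(ev_t), schedule)
  movement <- synth_movement(config, seed + 1L, events)
  lfp_out <- synth_lfp(config, movement, events, seed + 2L)
  if (is.null(roi)) {
    # whole-ROI extremes: per-quadrant series are available by passing a
    # gridded ROI, but a roaming subject crossing tile boundaries makes the
    # quadrant *total* spike (the blob enters/leaves tiles), so the
    # session-level movement stream uses the plain ROI
    roi <- roi_config(
      bottom = config$frame_h, right = config$frame_w,
      near_mm = config$near_mm, far_mm = config$far_mm
    )
  }
  gen <- make_frame_generator(config, movement, seed + 3L)
  gmv <- gmv_series_impl(gen, movement$t, roi, depth_scale = 1,
                         max_gap_s = Inf)
  power <- quantize_power(rectified_power(bandpass_filter(lfp_out$trace)))
  out <- list(
    lfp = lfp_out$trace, power = power, events = events,
    schedule = schedule, gmv = gmv, clips = list(), roi = roi,
    config = config, seed = seed, truth = lfp_out$truth,
    movement = movement
  )
  if (isTRUE(keep_frames)) {
    out$frames <- synth_depth_frames(config, movement, seed + 3L)
  }
  structure(out, class = "session_record")
}
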