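small_cfg <- function(...) {
  args <- utils::modifyList(
    list(duration_s = 60, frame_h = 48, frame_w = 64), list(...)
  )
  do.call(synth_config, args)
}

test_that("movement trajectories are seeded, bounded and integrate to path length", {
  cfg <- small_cfg()
  m1 <- synth_movement(cfg, seed = 5)
  m2 <- synth_movement(cfg, seed = 5)
  expect_identical(m1, m2)
  m3 <- synth_movement(cfg, seed = 6)
  expect_false(identical(m1$x, m3$x))

  # inside the viewport
  expect_true(all(m1$x >= 0 & m1$x <= cfg$frame_w))
  expect_true(all(m1$y >= 0 & m1$y <= cfg$frame_h))

  # intensity integrates to total in-plane path length
  dt <- 1 / cfg$frame_fps
  path_len <- sum(sqrt(diff(m1$x)^2 + diff(m1$y)^2))
  expect_equal(sum(m1$intensity * dt), path_len, tolerance = 1e-9)

  # zero speed -> frozen blob
  m0 <- synth_movement(small_cfg(blob_speed_px_s = 0,
                                 blob_depth_speed_mm_s = 0), seed = 1)
  expect_equal(sd(m0$x), 0)
  expect_equal(max(m0$intensity), 0)
})

test_that("movement pauses before events and bursts after rewarded events", {
  cfg <- small_cfg(duration_s = 120)
  ev_t <- c(30, 60, 90)
  ev <- betacage:::new_reward_events(ev_t)
  ev$rewarded <- TRUE
  m <- synth_movement(cfg, seed = 2, events = ev)
  win_mean <- function(lo, hi) {
    mean(unlist(lapply(ev_t, function(e) {
      m$intensity[m$t >= e + lo & m$t < e + hi]
    })))
  }
  pre <- win_mean(-1.4, -0.1)
  post <- win_mean(0.1, 1.4)
  free <- mean(m$intensity[m$t < 28])
  expect_lt(pre, 0.5 * free) # near-pause before events
  expect_gt(post, 4 * pre)   # retrieval reach after rewards
})

test_that("synthetic LFP realizes the configured coupling structure", {
  # g = 0, no events: envelope independent of movement.  The two signals are
  # smooth (seconds-scale correlation), so a long record is needed for the
  # sample correlation to concentrate near zero.
  cfg_long <- synth_config(duration_s = 2000)
  m_long <- synth_movement(cfg_long, seed = 3)
  out0 <- synth_lfp(synth_config(duration_s = 2000,
                                 movement_coupling_gain = 0),
                    m_long, NULL, seed = 4)
  r0 <- cor(out0$truth$envelope, out0$truth$movement)
  expect_lt(abs(r0), 0.05)

  # g > 0: envelope negatively correlated with movement
  cfg <- synth_config(duration_s = 100)
  m <- synth_movement(cfg, seed = 3)
  out1 <- synth_lfp(cfg, m, NULL, seed = 4)
  expect_lt(cor(out1$truth$envelope, out1$truth$movement), 0)

  # full suppression: power near the noise floor right after a reward
  cfg_drop <- synth_config(duration_s = 40, retrieval_drop_frac = 1,
                           blob_speed_px_s = 0, artifact_amp = 0)
  outd <- synth_lfp(cfg_drop, NULL, 20, seed = 9)
  t_lfp <- (seq_along(outd$truth$envelope) - 1) / cfg_drop$lfp_fs
  just_after <- outd$truth$envelope[findInterval(20.01, t_lfp)]
  before <- outd$truth$envelope[findInterval(18, t_lfp)]
  expect_lt(just_after, 0.01 * cfg_drop$baseline_beta_amp)
  expect_gt(before, 0.5 * cfg_drop$baseline_beta_amp)

  # determinism
  outa <- synth_lfp(cfg, m, 50, seed = 11)
  outb <- synth_lfp(cfg, m, 50, seed = 11)
  expect_identical(outa$trace$v, outb$trace$v)
})

test_that("synthetic depth frames produce the expected GMV structure", {
  # no flicker, frozen blob -> GMV identically zero
  cfg0 <- small_cfg(duration_s = 5, flicker_pixel_frac = 0,
                    blob_speed_px_s = 0, blob_depth_speed_mm_s = 0)
  m0 <- synth_movement(cfg0, seed = 1)
  fr0 <- synth_depth_frames(cfg0, m0, seed = 2)
  roi <- roi_config(bottom = cfg0$frame_h, right = cfg0$frame_w,
                    near_mm = cfg0$near_mm, far_mm = cfg0$far_mm)
  expect_equal(max(gmv_series(fr0, roi)$total), 0)

  # flicker with a frozen blob -> strictly positive GMV floor
  cfg1 <- small_cfg(duration_s = 5, blob_speed_px_s = 0,
                    blob_depth_speed_mm_s = 0)
  m1 <- synth_movement(cfg1, seed = 1)
  fr1 <- synth_depth_frames(cfg1, m1, seed = 2)
  floor_gmv <- gmv_series(fr1, roi)$total
  expect_gt(mean(floor_gmv > 0), 0.5)

  # a moving blob exceeds the flicker floor
  cfg2 <- small_cfg(duration_s = 5)
  m2 <- synth_movement(cfg2, seed = 1)
  fr2 <- synth_depth_frames(cfg2, m2, seed = 2)
  moving_gmv <- gmv_series(fr2, roi)$total
  expect_gt(mean(moving_gmv), mean(floor_gmv))

  # frames are 16-bit-range depth rasters with the declared shape
  expect_equal(dim(fr2$frames[[1]]), c(48, 64))
  expect_true(all(vapply(fr2$frames, max, numeric(1)) <= 65535))
})

test_that("whole sessions are deterministic and internally consistent", {
  cfg <- small_cfg(duration_s = 90)
  s1 <- synth_session(cfg, seed = 7)
  s2 <- synth_session(cfg, seed = 7)
  expect_identical(s1$lfp$v, s2$lfp$v)
  expect_identical(s1$gmv$total, s2$gmv$total)
  expect_identical(s1$events$t, s2$events$t)

  s3 <- synth_session(cfg, seed = 8)
  expect_false(identical(s1$lfp$v, s3$lfp$v))
  expect_identical(s1$config, s3$config) # config echo unchanged by seed

  # components share the session clock
  expect_equal(max(s1$power$t), cfg$duration_s, tolerance = 0.1)
  expect_equal(max(s1$gmv$t), cfg$duration_s, tolerance = 0.1)
  expect_true(all(s1$events$t <= cfg$duration_s))
  # planned events are epoch-labeled against the schedule
  expect_true(all(s1$events$epoch_kind %in% c("R", "NR")))
  expect_equal(s1$events$rewarded, s1$events$epoch_kind == "R")

  print_out <- capture.output(print(s1))
  expect_match(print_out, "session record")
  expect_s3_class(tidy(s1), "tbl_df")
  g <- glance(s1)
  expect_equal(g$n_events, nrow(s1$events))
})

test_that("the full pipeline recovers the injected event count", {
  # calibrate on an event-free baseline, detect on a session with planned
  # events; the count should come back within +/-20% at default SNR
  base_cfg <- synth_config(duration_s = 600, event_rate_per_min = 0.0001)
  sess_cfg <- synth_config(duration_s = 600)
  base <- synth_lfp(base_cfg, synth_movement(base_cfg, 100), NULL, seed = 101)
  to_power <- function(tr) quantize_power(rectified_power(bandpass_filter(tr)))
  p_base <- to_power(base$trace)

  sess <- synth_session(sess_cfg, seed = 202)
  thr <- calibrate_threshold(p_base, target_count = 2)
  got <- nrow(detect_events(sess$power, thr))
  planned <- nrow(sess$events)
  expect_gt(planned, 10)
  expect_lte(abs(got - planned) / planned, 0.20)
})
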