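impulse_power <- function(times, heights, duration_s, fs = 10) {
  v <- numeric(duration_s * fs + 1)
  v[round(times * fs) + 1] <- heights
  power_trace(v, fs = fs)
}

test_that("detection honors threshold and lockout", {
  # everywhere sub-threshold -> no events
  p <- power_trace(runif(100, 0, 0.5), fs = 10)
  expect_equal(nrow(detect_events(p, 1)), 0)

  # impulses at 1, 3, 12 s with a 10 s lockout -> events at 1 and 12 only
  p <- impulse_power(c(1, 3, 12), 5, 20)
  ev <- detect_events(p, 5, lockout_s = 10)
  expect_equal(ev$t, c(1, 12))

  # sustained supra-threshold power retriggers exactly at lockout expiry
  p <- power_trace(rep(10, 601), fs = 10)
  ev <- detect_events(p, 5, lockout_s = 10)
  expect_equal(ev$t, seq(0, 60, by = 10))
  expect_equal(min(diff(ev$t)), 10)

  # edge mode requires a dip below threshold first
  ev_edge <- detect_events(p, 5, lockout_s = 10, retrigger = "edge")
  expect_equal(ev_edge$t, 0)

  expect_error(detect_events(power_trace(1, fs = 1)[0, ], 1),
               class = "betacage_insufficient_data")
})

test_that("detector agrees with the brute-force refractory scan", {
  withr::local_seed(11)
  for (i in 1:50) {
    fs <- 5
    n <- 400
    v <- floor(rexp(n, 1 / 3))
    t <- (seq_len(n) - 1) / fs
    thr <- sample(1:6, 1)
    lock <- sample(c(2, 5, 10), 1)
    mode <- sample(c("level", "edge"), 1)
    got <- detect_events(power_trace(v, fs), thr, lock, mode)$t
    expect_equal(got, naive_detect(t, v, thr, lock, mode))
  }
})

test_that("event count is non-increasing in threshold", {
  withr::local_seed(3)
  v <- floor(rexp(500, 1 / 4))
  p <- power_trace(v, fs = 2)
  counts <- vapply(1:10, function(thr) nrow(detect_events(p, thr, 5)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("calibration returns the maximal threshold reaching the target", {
  # isolated peaks 9, 7, 5 a minute apart, lockout 10 s, target 2 -> threshold 7
  p <- impulse_power(c(10, 70, 130), c(9, 7, 5), 150, fs = 10)
  expect_equal(calibrate_threshold(p, 2), 7)
  expect_equal(calibrate_threshold(p, 2), naive_calibrate(p$t, p$v, 2, 10))

  # target 0 -> max + 1, yielding zero events
  thr0 <- calibrate_threshold(p, 0)
  expect_equal(thr0, 10)
  expect_equal(nrow(detect_events(p, thr0)), 0)

  # infeasible target carries the achievable maximum
  err <- expect_error(calibrate_threshold(p, 10),
                      class = "betacage_calibration_infeasible")
  expect_equal(err$achievable, 3)

  # quantization is required
  expect_error(calibrate_threshold(power_trace(c(0.5, 1.2), 1), 1),
               class = "betacage_invalid_spec")
})

test_that("calibration matches brute force and is maximal on random baselines", {
  withr::local_seed(21)
  for (i in 1:50) {
    v <- floor(rexp(300, 1 / 4))
    if (max(v) == 0) v[1] <- 3
    p <- power_trace(v, fs = 2)
    achievable <- nrow(detect_events(p, 1, 10))
    target <- sample(seq_len(max(achievable, 1)), 1)
    thr <- calibrate_threshold(p, target, 10)
    expect_equal(thr, naive_calibrate(p$t, p$v, target, 10))
    expect_gte(nrow(detect_events(p, thr, 10)), target)
    expect_lt(nrow(detect_events(p, thr + 1, 10)), target)
  }
})

test_that("epoch schedules tile the session with the configured ratio", {
  s <- schedule_epochs(480, 120, 120)
  expect_equal(s$kind, c("R", "NR", "R", "NR"))
  expect_equal(s$start_s, c(0, 120, 240, 360))
  expect_equal(s$end_s, c(120, 240, 360, 480))

  s2 <- schedule_epochs(900, 300, 600)
  expect_equal(s2$kind, c("R", "NR"))
  expect_equal(s2$start_s, c(0, 300))
  expect_equal(s2$end_s, c(300, 900))

  expect_equal(nrow(schedule_epochs(0)), 0)
  expect_error(schedule_epochs(100, 0, 60), class = "betacage_invalid_spec")

  # truncated final epoch; epochs partition the session
  s3 <- schedule_epochs(500, 120, 120)
  expect_equal(s3$end_s[nrow(s3)], 500)
  expect_equal(sum(s3$end_s - s3$start_s), 500)
  expect_equal(s3$start_s[-1], s3$end_s[-nrow(s3)])
})

test_that("gating labels events by containing epoch with half-open bounds", {
  sched <- schedule_epochs(480, 120, 120)
  ev <- gate_events(betacage:::new_reward_events(c(60, 180)), sched)
  expect_equal(ev$epoch_kind, c("R", "NR"))
  expect_equal(ev$rewarded, c(TRUE, FALSE))

  # boundary event belongs to the starting epoch
  evb <- gate_events(betacage:::new_reward_events(120), sched)
  expect_equal(evb$epoch_kind, "NR")

  # outside the span -> baseline
  evo <- gate_events(betacage:::new_reward_events(c(100, 700)), sched)
  expect_equal(evo$epoch_kind, c("R", "baseline"))
  expect_false(any(evo$rewarded[2]))

  expect_equal(nrow(gate_events(betacage:::new_reward_events(numeric(0)), sched)), 0)
  expect_error(gate_events(betacage:::new_reward_events(c(5, 2)), sched),
               class = "betacage_ordering")

  # every event maps to exactly one epoch (interval lookup oracle)
  withr::local_seed(5)
  tt <- sort(runif(50, 0, 480))
  lab <- gate_events(betacage:::new_reward_events(tt), sched)$epoch_kind
  oracle <- vapply(tt, function(x) {
    hit <- which(x >= sched$start_s & x < sched$end_s)
    expect_length(hit, 1)
    sched$kind[hit]
  }, character(1))
  expect_equal(lab, oracle)
})

test_that("reward audio is three 1200 Hz beeps on a 500 ms cadence", {
  a <- audio_for_event(10)
  expect_equal(nrow(a), 3)
  expect_equal(a$onset_s, c(10, 10.5, 11))
  expect_equal(unique(a$freq_hz), 1200)
  expect_equal(unique(a$on_ms), 250)
  expect_equal(unique(a$off_ms), 250)

  # hardware limits: minimum 50 ms on-time, 10-4000 Hz
  expect_error(audio_for_event(1, on_ms = 20), class = "betacage_invalid_spec")
  expect_error(audio_for_event(1, freq_hz = 5000), class = "betacage_invalid_spec")
  expect_error(audio_for_event(1, freq_hz = 5), class = "betacage_invalid_spec")
  expect_silent(audio_for_event(1, freq_hz = 700, on_ms = 50))
})

test_that("all detector outputs respect the lockout (property sweep)", {
  withr::local_seed(9)
  for (i in 1:20) {
    v <- floor(rexp(600, 1 / 5))
    p <- power_trace(v, fs = sample(c(1, 4, 10), 1))
    lock <- runif(1, 2, 12)
    ev <- detect_events(p, sample(1:8, 1), lockout_s = lock)
    if (nrow(ev) > 1) expect_true(all(diff(ev$t) >= lock - 1e-9))
  }
})
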