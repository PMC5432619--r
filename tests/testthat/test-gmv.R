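test_that("ROI masking zeroes pixels outside margins and depth cutoffs", {
  f <- matrix(1000, 10, 12)
  roi_all <- roi_config(bottom = 10, right = 12)
  expect_equal(apply_roi(f, roi_all), f)
  expect_equal(apply_roi(f, NULL), f)

  f2 <- f
  f2[3, 4] <- 5000
  out <- apply_roi(f2, roi_config(bottom = 10, right = 12, far_mm = 4000))
  expect_equal(out[3, 4], 0)
  expect_equal(out[-3, ], f2[-3, ])

  # brute-force count of surviving pixels on a random frame
  withr::local_seed(2)
  fr <- matrix(sample(0:4000, 200, replace = TRUE), 10, 20)
  roi <- roi_config(top = 2, bottom = 8, left = 3, right = 17,
                    near_mm = 500, far_mm = 3000)
  got <- apply_roi(fr, roi)
  n_naive <- 0
  for (r in 1:10) {
    for (cc in 1:20) {
      inside <- r >= 2 && r <= 8 && cc >= 3 && cc <= 17
      d <- fr[r, cc]
      if (inside && d >= 500 && d <= 3000) n_naive <- n_naive + 1
    }
  }
  expect_equal(sum(got > 0), n_naive)

  expect_error(apply_roi(f, roi_config(bottom = 99, right = 12)),
               class = "betacage_invalid_spec")
  expect_error(roi_config(top = 5, bottom = 2, right = 4),
               class = "betacage_invalid_spec")
  expect_error(roi_config(bottom = 4, right = 4, near_mm = 10, far_mm = 5),
               class = "betacage_invalid_spec")
})

test_that("frame extremes locate the six extremal voxels", {
  f <- blob_frame(10, 10, 3, 7, 1200)
  e <- frame_extremes(f)
  expect_equal(unlist(e), c(top_px = 3, bottom_px = 3, left_px = 7,
                            right_px = 7, front_mm = 1200, back_mm = 1200))

  f2 <- blob_frame(8, 8, 2:5, 1:4, 700)
  e2 <- frame_extremes(f2)
  expect_equal(unlist(e2), c(top_px = 2, bottom_px = 5, left_px = 1,
                             right_px = 4, front_mm = 700, back_mm = 700))

  expect_null(frame_extremes(matrix(0, 4, 4)))
})

test_that("pairwise GMV follows the extremal-difference formula", {
  e <- frame_extremes(blob_frame(20, 20, 5:8, 5:8, 1000))
  expect_equal(gmv_pair(e, e), 0)

  # translate 3 px rightward: left and right both +3 -> GMV 6
  e_r <- frame_extremes(blob_frame(20, 20, 5:8, 8:11, 1000))
  expect_equal(gmv_pair(e, e_r), 6)

  # rigid approach by 50 mm: front and back both -50 -> GMV 100
  e_n <- frame_extremes(blob_frame(20, 20, 5:8, 5:8, 950))
  expect_equal(gmv_pair(e, e_n), 100)
  expect_equal(gmv_pair(e, e_n, depth_scale = 0.1), 10)

  # empty side contributes zero
  expect_equal(gmv_pair(NULL, e), 0)
})

test_that("GMV matches the exhaustive extremal-scan oracle on random frames", {
  withr::local_seed(31)
  for (i in 1:25) {
    h <- sample(6:14, 1)
    w <- sample(6:14, 1)
    mk <- function() {
      f <- matrix(0, h, w)
      n_px <- sample(1:8, 1)
      f[sample(h * w, n_px)] <- sample(500:3000, n_px, replace = TRUE)
      f
    }
    f0 <- mk()
    f1 <- mk()
    got <- gmv_pair(frame_extremes(f0), frame_extremes(f1))
    expect_equal(got, naive_gmv(f0, f1))
  }
})

test_that("whole-ROI GMV ignores permutations of interior pixel values", {
  withr::local_seed(13)
  f0 <- blob_frame(12, 12, 4:8, 4:8, 1500)
  f0[5:7, 5:7] <- sample(1000:2000, 9) # varied interior depths
  # shuffling the interior values among their positions moves no extreme
  f1 <- f0
  f1[5:7, 5:7] <- matrix(sample(as.vector(f0[5:7, 5:7])), 3, 3)
  expect_equal(gmv_pair(frame_extremes(f0), frame_extremes(f1)), 0)
  # but changing an interior value beyond the depth range does (via back_mm)
  f2 <- f0
  f2[6, 6] <- 2500
  expect_gt(gmv_pair(frame_extremes(f0), frame_extremes(f2)), 0)
})

test_that("quadrant decomposition localizes movement and sums to the total", {
  h <- 20
  w <- 20
  roi <- roi_config(bottom = h, right = w, grid_rows = 2, grid_cols = 2)
  # motion confined to the top-left tile
  f0 <- blob_frame(h, w, 2:4, 2:4, 1000)
  f1 <- blob_frame(h, w, 3:5, 2:4, 1000)
  q <- gmv_quadrants(f0, f1, roi)
  expect_equal(q$per_quadrant[1, 1], 2)
  expect_equal(q$per_quadrant[c(2, 3, 4)], c(0, 0, 0))
  expect_equal(q$total, sum(q$per_quadrant))

  # 1x1 grid equals the whole-ROI computation
  roi1 <- roi_config(bottom = h, right = w)
  q1 <- gmv_quadrants(f0, f1, roi1)
  expect_equal(q1$total, gmv_pair(frame_extremes(f0), frame_extremes(f1)))

  # per-tile oracle on random frames
  withr::local_seed(41)
  for (i in 1:10) {
    g0 <- matrix(sample(c(0, 0, 800, 2500), h * w, replace = TRUE), h, w)
    g1 <- matrix(sample(c(0, 0, 800, 2500), h * w, replace = TRUE), h, w)
    q <- gmv_quadrants(g0, g1, roi)
    for (r in 1:2) {
      for (cc in 1:2) {
        rows <- ((r - 1) * 10 + 1):(r * 10)
        cols <- ((cc - 1) * 10 + 1):(cc * 10)
        expect_equal(q$per_quadrant[r, cc],
                     naive_gmv(g0[rows, cols], g1[rows, cols]))
      }
    }
    expect_equal(q$total, sum(q$per_quadrant))
  }
})

test_that("GMV series handles static scenes, alternation and dropouts", {
  f_a <- blob_frame(10, 10, 3:5, 3:5, 1000)
  f_b <- blob_frame(10, 10, 3:5, 5:7, 1000)

  # identical frames -> all zeros
  s0 <- gmv_series(depth_seq(rep(list(f_a), 5), 0:4))
  expect_equal(s0$total, rep(0, 4))

  # alternating poses -> constant positive series
  s1 <- gmv_series(depth_seq(list(f_a, f_b, f_a, f_b), 0:3))
  expect_equal(s1$total, rep(4, 3))
  expect_true(all(s1$total > 0))

  # an all-invalid frame reuses previous extremes (no spurious spike)
  s2 <- gmv_series(depth_seq(list(f_a, matrix(0, 10, 10), f_a), 0:2))
  expect_equal(s2$total, c(0, 0))

  # length and timestamps: n-1 values at the later frame's time
  expect_equal(s1$t, 1:3)
  expect_error(gmv_series(depth_seq(list(f_a), 0)),
               class = "betacage_insufficient_data")

  # total column equals the tile sum for a gridded ROI
  roi <- roi_config(bottom = 10, right = 10, grid_rows = 2, grid_cols = 2)
  s3 <- gmv_series(depth_seq(list(f_a, f_b, f_a), 0:2), roi)
  tiles <- as.matrix(s3[, grep("^gmv_", names(s3))])
  expect_equal(s3$total, unname(rowSums(tiles)))
})

test_that("min-max normalization maps the session range onto [0, 1]", {
  s <- gmv_series(depth_seq(list(
    blob_frame(8, 8, 2:3, 2:3, 1000),
    blob_frame(8, 8, 3:4, 2:3, 1000), # GMV 2
    blob_frame(8, 8, 3:4, 2:3, 1000), # GMV 0
    blob_frame(8, 8, 6:7, 5:6, 1000)  # larger move
  ), 0:3))
  n <- normalize_gmv(s)
  expect_equal(min(n$total), 0)
  expect_equal(max(n$total), 1)
  expect_true(isTRUE(attr(n, "normalized")))

  # explicit arithmetic: [2, 7, 12] -> [0, 0.5, 1]
  fake <- s[1:3, ]
  fake$total <- c(2, 7, 12)
  expect_equal(normalize_gmv(fake)$total, c(0, 0.5, 1))

  # constant series maps to zeros
  const <- s[1:3, ]
  const$total <- rep(4, 3)
  expect_equal(normalize_gmv(const)$total, rep(0, 3))
})

test_that("event-triggered averaging aligns, excludes truncated windows", {
  # deterministic ramp at 10 Hz
  p <- power_trace(seq(0, 100, by = 0.1), fs = 10)

  # single event: average equals the event's own window
  one <- event_triggered_average(p, 30, pre_s = 1, post_s = 1)
  expect_equal(one$n_events, 1)
  i0 <- 301
  expect_equal(one$mean, p$v[(i0 - 10):(i0 + 10)])

  # two events on a ramp: average equals the midpoint window
  two <- event_triggered_average(p, c(20, 40), pre_s = 1, post_s = 1)
  mid <- event_triggered_average(p, 30, pre_s = 1, post_s = 1)
  expect_equal(two$mean, mid$mean)

  # truncated events are excluded and counted
  mix <- event_triggered_average(p, c(0.05, 30, 99.99), pre_s = 1, post_s = 1)
  expect_equal(mix$n_events, 1)
  expect_equal(mix$n_excluded, 2)
  expect_error(event_triggered_average(p, 0.01, pre_s = 1, post_s = 1),
               class = "betacage_insufficient_data")

  # works on GMV series via the total column
  s <- gmv_series(depth_seq(rep(list(blob_frame(6, 6, 2, 2, 900),
                                     blob_frame(6, 6, 3, 2, 900)), 10),
                            seq(0, 19) * 0.5))
  eta <- event_triggered_average(s, 5, pre_s = 1, post_s = 1)
  expect_equal(length(eta$mean), 5)
  expect_s3_class(tidy(eta), "tbl_df")
  expect_equal(glance(eta)$n_events, 1)
})
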