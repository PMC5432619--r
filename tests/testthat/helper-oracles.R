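# Independent brute-force oracles the implementation is checked against.
# These deliberately use naive loops and closed forms, never the package's
# own code paths.

# trailing-window mean of |x|, partial windows at the start
naive_sliding_power <- function(v, w) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - w + 1L)
    out[i] <- mean(abs(v[lo:i]))
  }
  out
}

# linear scan honoring the refractory lockout
naive_detect <- function(t, v, threshold, lockout_s,
                         retrigger = c("level", "edge")) {
  retrigger <- match.arg(retrigger)
  out <- numeric(0)
  last <- -Inf
  prev <- -Inf
  for (i in seq_along(v)) {
    supra <- v[i] >= threshold
    crossing <- if (retrigger == "level") supra else supra && prev < threshold
    if (crossing && t[i] >= last + lockout_s - 1e-9) {
      out <- c(out, t[i])
      last <- t[i]
    }
    prev <- v[i]
  }
  out
}

# exhaustive search for the largest integer threshold reaching the target
naive_calibrate <- function(t, v, target, lockout_s) {
  if (target == 0) {
    return(max(v) + 1)
  }
  best <- NA_real_
  for (thr in seq_len(max(v))) {
    if (length(naive_detect(t, v, thr, lockout_s)) >= target) best <- thr
  }
  best
}

# exhaustive extremal scan over every pixel of both frames
naive_gmv <- function(f0, f1, depth_scale = 1) {
  scan <- function(f) {
    top <- Inf; bottom <- -Inf; left <- Inf; right <- -Inf
    front <- Inf; back <- -Inf
    for (r in seq_len(nrow(f))) {
      for (cc in seq_len(ncol(f))) {
        d <- f[r, cc]
        if (d > 0) {
          top <- min(top, r); bottom <- max(bottom, r)
          left <- min(left, cc); right <- max(right, cc)
          front <- min(front, d); back <- max(back, d)
        }
      }
    }
    c(top, bottom, left, right, front, back)
  }
  e0 <- scan(f0)
  e1 <- scan(f1)
  if (any(!is.finite(e0)) || any(!is.finite(e1))) {
    return(0)
  }
  sum(abs(e1[1:4] - e0[1:4])) + depth_scale * sum(abs(e1[5:6] - e0[5:6]))
}

# analytic magnitude response of an analog Butterworth bandpass prototype
butter_bp_mag <- function(f_hz, low_hz, high_hz, order) {
  w <- 2 * pi * f_hz
  w0sq <- (2 * pi * low_hz) * (2 * pi * high_hz)
  bw <- 2 * pi * (high_hz - low_hz)
  1 / sqrt(1 + ((w^2 - w0sq) / (w * bw))^(2 * order))
}

# steady-state oscillation amplitude, robust to edges
measured_amplitude <- function(v, fs, trim_s = 0.5) {
  core <- v[(trim_s * fs):(length(v) - trim_s * fs)]
  (quantile(core, 0.999, names = FALSE) - quantile(core, 0.001, names = FALSE)) / 2
}

# small deterministic blob-on-background frame builder for GMV tests
blob_frame <- function(h, w, rows, cols, depth, background = 0) {
  f <- matrix(background, h, w)
  f[rows, cols] <- depth
  f
}
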