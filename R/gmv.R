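#' Depth-frame sequence container
#'
#' Holds a sequence of depth rasters (matrices of millimetre distances,
#' 0 = invalid / no return) with per-frame timestamps.
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param t Numeric vector of frame timestamps (seconds), strictly increasing.
#' @param fps Nominal frame rate (Hz); inferred from `t` when omitted.
#'
#' @return A list of class `depth_seq` with elements `frames`, `t`, `fps`,
#'   `shape`.
#' @export
depth_seq <- function(frames, t, fps = NULL) {
  if (length(frames) != length(t)) {
    abort_invalid_spec("`frames` and `t` must have equal length")
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    abort_ordering("frame timestamps must be strictly increasing")
  }
  shape <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), shape), logical(1))
  if (!all(ok)) {
    abort_invalid_spec("all frames must share one shape")
  }
  if (is.null(fps)) {
    fps <- if (length(t) > 1) 1 / median(diff(t)) else NA_real_
  }
  structure(list(frames = frames, t = as.double(t), fps = fps, shape = shape),
    class = "depth_seq"
  )
}

#' Analysis region-of-interest for depth frames
#'
#' The analysis area is delimited by top/bottom/left/right pixel margins
#' (1-based, inclusive) — used to outline the cage and exclude neighbouring
#' cages — and by near/far depth cutoffs in mm: depth values outside
#' `[near_mm, far_mm]` fall to zero, suppressing back-wall reflections and
#' passers-by.  The ROI can further be split into a `grid_rows x grid_cols`
#' quadrant grid for localized movement values.
#'
#' @param top,bottom,left,right Pixel margins (rows `top:bottom`, columns
#'   `left:right` are analyzed).
#' @param near_mm,far_mm Depth cutoffs in mm (defaults 0 and `Inf`).
#' @param grid_rows,grid_cols Quadrant grid (default 1 x 1).
#'
#' @return A list of class `roi_config`.
#' @export
roi_config <- function(top = 1, bottom, left = 1, right,
                       near_mm = 0, far_mm = Inf,
                       grid_rows = 1, grid_cols = 1) {
  if (top < 1 || left < 1 || top > bottom || left > right) {
    abort_invalid_spec("margins must satisfy 1 <= top <= bottom, 1 <= left <= right")
  }
  if (near_mm < 0 || near_mm >= far_mm) {
    abort_invalid_spec("cutoffs must satisfy 0 <= near_mm < far_mm")
  }
  check_scalar_number(grid_rows, "grid_rows", min = 1)
  check_scalar_number(grid_cols, "grid_cols", min = 1)
  structure(
    list(
      top = as.integer(top), bottom = as.integer(bottom),
      left = as.integer(left), right = as.integer(right),
      near_mm = near_mm, far_mm = far_mm,
      grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols)
    ),
    class = "roi_config"
  )
}

roi_for_frame <- function(frame, roi = NULL) {
  if (is.null(roi)) {
    roi <- roi_config(bottom = nrow(frame), right = ncol(frame))
  }
  if (roi$bottom > nrow(frame) || roi$right > ncol(frame)) {
    abort_invalid_spec("ROI margins exceed the frame dimensions")
  }
  roi
}

#' Mask a depth frame to the region of interest
#'
#' Pixels outside the margins, or whose depth lies outside
#' `[near_mm, far_mm]`, are set to 0 (invalid).  Others pass unchanged.
#'
#' @param frame Numeric depth matrix (mm; 0 = invalid).
#' @param roi An [roi_config()]; `NULL` means the whole frame with no cutoff.
#'
#' @return The masked depth matrix.
#' @export
apply_roi <- function(frame, roi = NULL) {
  roi <- roi_for_frame(frame, roi)
  out <- matrix(0, nrow(frame), ncol(frame))
  rows <- roi$top:roi$bottom
  cols <- roi$left:roi$right
  sub <- frame[rows, cols, drop = FALSE]
  sub[sub < roi$near_mm | sub > roi$far_mm] <- 0
  out[rows, cols] <- sub
  out
}

#' Extremal valid voxels of a depth frame
#'
#' Finds the subject's topmost, bottommost, leftmost and rightmost valid
#' (nonzero) pixel indices and its closest (`front_mm`) and furthest
#' (`back_mm`) valid depths — the six values the gross movement value is
#' built from.
#'
#' @param frame Numeric depth matrix (mm; 0 = invalid), typically already
#'   ROI-masked.
#'
#' @return A one-row tibble with columns `top_px`, `bottom_px`, `left_px`,
#'   `right_px`, `front_mm`, `back_mm`, or `NULL` when the frame holds no
#'   valid pixel (the empty-frame signal; streaming callers substitute the
#'   previous frame's extremes).
#' @export
frame_extremes <- function(frame) {
  e <- .extremes(frame)
  if (is.null(e)) {
    return(NULL)
  }
  tibble(
    top_px = e[1], bottom_px = e[2], left_px = e[3], right_px = e[4],
    front_mm = e[5], back_mm = e[6]
  )
}

# fast path: extremes as a bare length-6 vector (top, bottom, left, right,
# front, back), NULL when the frame holds no valid pixel
.extremes <- function(frame) {
  valid <- frame > 0
  if (!any(valid)) {
    return(NULL)
  }
  rs <- which(.rowSums(valid, nrow(frame), ncol(frame)) > 0)
  cs <- which(.colSums(valid, nrow(frame), ncol(frame)) > 0)
  d <- frame[valid]
  c(rs[1], rs[length(rs)], cs[1], cs[length(cs)], min(d), max(d))
}

.gmv_pair <- function(e0, e1, depth_scale) {
  if (is.null(e0) || is.null(e1)) {
    return(0)
  }
  sum(abs(e1[1:4] - e0[1:4])) + depth_scale * sum(abs(e1[5:6] - e0[5:6]))
}

as_extremes_vec <- function(e) {
  if (is.null(e)) {
    return(NULL)
  }
  if (is.data.frame(e)) {
    c(e$top_px, e$bottom_px, e$left_px, e$right_px, e$front_mm, e$back_mm)
  } else {
    e
  }
}

#' Gross movement value between two frames' extremes
#'
#' The GMV for a frame pair is the sum of absolute changes of the six
#' extremal values:
#' `|top1-top0| + |bottom1-bottom0| + |right1-right0| + |left1-left0| +
#'  |front1-front0| + |back1-back0|`.
#' Pixel terms are in pixels and depth terms in mm, summed as-is (the units
#' are mixed by construction); `depth_scale` re-weights the depth terms when
#' a different balance is wanted.
#'
#' @param e0,e1 Extremes of successive frames ([frame_extremes()] rows); a
#'   `NULL` (empty-frame) side contributes 0.
#' @param depth_scale Weight on the front/back (mm) terms (default 1).
#'
#' @return A nonnegative scalar.
#' @export
gmv_pair <- function(e0, e1, depth_scale = 1) {
  .gmv_pair(as_extremes_vec(e0), as_extremes_vec(e1), depth_scale)
}

# Split the ROI span into near-equal contiguous tiles; remainder pixels go to
# the last tile.  Returns a list of index vectors.
tile_spans <- function(from, to, n) {
  len <- to - from + 1L
  if (n > len) {
    abort_invalid_spec("more grid tiles than pixels in the ROI")
  }
  base <- len %/% n
  starts <- from + (seq_len(n) - 1L) * base
  ends <- c(starts[-1L] - 1L, to)
  purrr::map2(starts, ends, seq.int)
}

#' Per-quadrant gross movement values for a frame pair
#'
#' Splits the ROI into a `grid_rows x grid_cols` grid of near-equal tiles and
#' computes [gmv_pair()] on each tile's own extremes, so movement is
#' localized to the region it occurred in.  The total is the sum over tiles
#' (`GMV_total`).  A tile with no valid pixel in either frame contributes 0.
#'
#' @param f0,f1 Successive depth frames (matrices of equal shape).
#' @param roi An [roi_config()] (its `grid_rows`/`grid_cols` set the grid).
#' @param depth_scale Passed to [gmv_pair()].
#'
#' @return A list with `per_quadrant` (a `grid_rows x grid_cols` matrix) and
#'   `total` (their sum).
#' @export
gmv_quadrants <- function(f0, f1, roi = NULL, depth_scale = 1) {
  if (!identical(dim(f0), dim(f1))) {
    abort_invalid_spec("frames must share one shape")
  }
  roi <- roi_for_frame(f0, roi)
  m0 <- apply_roi(f0, roi)
  m1 <- apply_roi(f1, roi)
  row_tiles <- tile_spans(roi$top, roi$bottom, roi$grid_rows)
  col_tiles <- tile_spans(roi$left, roi$right, roi$grid_cols)
  g <- matrix(0, roi$grid_rows, roi$grid_cols)
  for (r in seq_len(roi$grid_rows)) {
    for (cc in seq_len(roi$grid_cols)) {
      e0 <- .extremes(m0[row_tiles[[r]], col_tiles[[cc]], drop = FALSE])
      e1 <- .extremes(m1[row_tiles[[r]], col_tiles[[cc]], drop = FALSE])
      g[r, cc] <- .gmv_pair(e0, e1, depth_scale)
    }
  }
  list(per_quadrant = g, total = sum(g))
}

#' Gross movement value series over a frame sequence
#'
#' Applies the per-quadrant GMV computation to every consecutive frame pair.
#' For each tile the last valid extremes are carried forward across
#' all-invalid (dropout) frames, so dropouts contribute no spurious movement.
#' Frame pairing uses consecutive frames regardless of timestamp gaps; pairs
#' whose gap exceeds `max_gap_s` are flagged in the `gap` column.
#'
#' @param frames A [depth_seq()] (or plain list of matrices with a `t`
#'   attribute supplied via `depth_seq()`).
#' @param roi An [roi_config()].
#' @param depth_scale Passed to [gmv_pair()].
#' @param max_gap_s Flag pairs further apart than this (default `Inf`).
#'
#' @return A tibble of class `gmv_series`: column `t` (time of the later
#'   frame of each pair), `total`, one `gmv_<r>_<c>` column per tile, and
#'   `gap`.  `total` equals the row sum of the tile columns.
#' @export
gmv_series <- function(frames, roi = NULL, depth_scale = 1, max_gap_s = Inf) {
  if (!inherits(frames, "depth_seq")) {
    abort_invalid_spec("`frames` must be a depth_seq")
  }
  n <- length(frames$frames)
  if (n < 2) {
    abort_insufficient_data("need at least two frames for a GMV series")
  }
  roi <- roi_for_frame(frames$frames[[1]], roi)
  gen <- function(i) frames$frames[[i]]
  gmv_series_impl(gen, frames$t, roi, depth_scale, max_gap_s)
}

# Streaming core shared with the synthetic generator: `gen(i)` yields frame i
# on demand so long sessions never hold all frames in memory.
gmv_series_impl <- function(gen, t, roi, depth_scale, max_gap_s) {
  n <- length(t)
  row_tiles <- tile_spans(roi$top, roi$bottom, roi$grid_rows)
  col_tiles <- tile_spans(roi$left, roi$right, roi$grid_cols)
  nt <- roi$grid_rows * roi$grid_cols
  extremes_of <- function(frame) {
    m <- apply_roi(frame, roi)
    out <- vector("list", nt)
    k <- 1L
    for (r in seq_len(roi$grid_rows)) {
      for (cc in seq_len(roi$grid_cols)) {
        # assign via list() so a NULL (empty tile) keeps its slot
        out[k] <- list(.extremes(m[row_tiles[[r]], col_tiles[[cc]],
                                   drop = FALSE]))
        k <- k + 1L
      }
    }
    out
  }
  prev <- extremes_of(gen(1L))
  vals <- matrix(0, n - 1L, nt)
  for (i in 2L:n) {
    cur <- extremes_of(gen(i))
    for (k in seq_len(nt)) {
      if (is.null(cur[[k]])) cur[k] <- prev[k] # carry across dropouts
      vals[i - 1L, k] <- .gmv_pair(prev[[k]], cur[[k]], depth_scale)
    }
    prev <- cur
  }
  out <- tibble(t = t[-1L], total = rowSums(vals))
  k <- 1L
  for (r in seq_len(roi$grid_rows)) {
    for (cc in seq_len(roi$grid_cols)) {
      out[[sprintf("gmv_%d_%d", r, cc)]] <- vals[, k]
      k <- k + 1L
    }
  }
  out$gap <- diff(t) > max_gap_s
  attr(out, "normalized") <- FALSE
  class(out) <- c("gmv_series", class(out))
  out
}

#' Min-max normalize a GMV series
#'
#' GMV has a scene-dependent nonzero baseline (infrared flicker around
#' reflective cage bars), so within-session analyses normalize it to the
#' session's own minimum and maximum: each value column is mapped through
#' `(x - min) / (max - min)` into `[0, 1]`.  A constant column maps to all
#' zeros.  The tile-sum identity holds only for unnormalized series.
#'
#' @param series A [gmv_series()] result.
#' @return The series with value columns rescaled and the `normalized`
#'   attribute set.
#' @export
normalize_gmv <- function(series) {
  if (nrow(series) == 0) {
    abort_insufficient_data("cannot normalize an empty series")
  }
  cols <- setdiff(names(series), c("t", "gap"))
  for (cl in cols) {
    x <- series[[cl]]
    rng <- range(x)
    series[[cl]] <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  }
  attr(series, "normalized") <- TRUE
  series
}
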