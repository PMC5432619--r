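# Shared on-disk formats.  Every writer stamps a format name and version;
# readers reject unknown formats and future major versions.

FORMAT_VERSION <- 1L

check_version <- function(ver, what, where) {
  ver <- suppressWarnings(as.integer(ver))
  if (is.na(ver) || ver > FORMAT_VERSION) {
    abort_parse(sprintf(
      "%s: unsupported %s format version '%s' (this build reads <= %d)",
      where, what, ver, FORMAT_VERSION
    ))
  }
}

#' Read and write traces as delimited text
#'
#' Plain-text trace container: `#`-prefixed header lines (format name and
#' version, sampling rate, unit, kind, quantized flag) followed by a
#' `time,value` CSV body.
#'
#' @param x An [lfp_trace()] or [power_trace()].
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   the reconstructed trace.
#' @export
write_trace_csv <- function(x, path) {
  kind <- if (inherits(x, "power_trace")) "power" else "lfp"
  hdr <- c(
    sprintf("# betacage-trace v%d", FORMAT_VERSION),
    sprintf("# fs: %.10g", trace_fs(x)),
    sprintf("# t0: %.10g", trace_t0(x)),
    sprintf("# unit: %s", trace_unit(x)),
    sprintf("# kind: %s", kind),
    sprintf("# quantized: %d", as.integer(is_quantized(x))),
    "time,value"
  )
  body <- sprintf("%.10g,%.17g", x$t, x$v)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readr::read_lines(path, n_max = 7)
  m <- regmatches(lines[1], regexec("^# betacage-trace v(\\d+)$", lines[1]))[[1]]
  if (length(m) == 0) {
    abort_parse(sprintf("%s: line 1 is not a betacage-trace header", path))
  }
  check_version(m[2], "trace", path)
  field <- function(i, key) {
    mm <- regmatches(lines[i], regexec(paste0("^# ", key, ": (.*)$"), lines[i]))[[1]]
    if (length(mm) == 0) {
      abort_parse(sprintf("%s: line %d: expected '# %s:' header", path, i, key))
    }
    mm[2]
  }
  fs <- as.numeric(field(2, "fs"))
  t0 <- as.numeric(field(3, "t0"))
  unit <- field(4, "unit")
  kind <- field(5, "kind")
  quant <- field(6, "quantized") == "1"
  body <- readr::read_csv(path, skip = 6, show_col_types = FALSE,
                          progress = FALSE)
  if (kind == "power") {
    power_trace(body$value, fs = fs, t0 = t0, unit = unit, quantized = quant)
  } else {
    lfp_trace(body$value, fs = fs, t0 = t0, unit = unit)
  }
}

#' Read and write traces in the binary container
#'
#' Compact binary trace container: magic `BCTR`, int32 version, float64
#' sampling rate and start time, a length-prefixed unit string, kind and
#' quantized flag bytes, int32 sample count, then little-endian float32
#' samples.
#'
#' @inheritParams write_trace_csv
#' @export
write_trace_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BCTR"), con)
  writeBin(FORMAT_VERSION, con, size = 4, endian = "little")
  writeBin(c(trace_fs(x), trace_t0(x)), con, size = 8, endian = "little")
  unit <- charToRaw(trace_unit(x))
  writeBin(length(unit), con, size = 4, endian = "little")
  writeBin(unit, con)
  kind <- if (inherits(x, "power_trace")) 1L else 0L
  writeBin(c(kind, as.integer(is_quantized(x))), con, size = 1)
  writeBin(nrow(x), con, size = 4, endian = "little")
  writeBin(x$v, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_trace_bin
#' @export
read_trace_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic), "BCTR")) {
    abort_parse(sprintf("%s: bad magic at byte offset 0 (not a betacage trace)",
                        path))
  }
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  check_version(ver, "trace", path)
  fs_t0 <- readBin(con, "double", 2, size = 8, endian = "little")
  ulen <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(ulen) || ulen < 0 || ulen > 1024) {
    abort_parse(sprintf("%s: corrupt unit-string length at byte offset 24", path))
  }
  unit <- rawToChar(readBin(con, "raw", ulen))
  flags <- readBin(con, "integer", 2, size = 1)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  v <- readBin(con, "double", n, size = 4, endian = "little")
  if (length(v) != n) {
    abort_parse(sprintf(
      "%s: truncated payload at byte offset %d (%d of %d samples)",
      path, 30 + ulen + 4 * length(v), length(v), n
    ))
  }
  if (flags[1] == 1L) {
    power_trace(v, fs = fs_t0[1], t0 = fs_t0[2], unit = unit,
                quantized = flags[2] == 1L)
  } else {
    lfp_trace(v, fs = fs_t0[1], t0 = fs_t0[2], unit = unit)
  }
}

#' Read and write event logs
#'
#' JSON-lines event logs: a header object carrying the format name and
#' version, then one object per event (`event_id`, `t`, `epoch_kind`,
#' `rewarded`).  A CSV flavour is available via `format = "csv"`.  Readers
#' reject unsorted event times.
#'
#' @param events A `reward_events` tibble.
#' @param path File path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @export
write_events <- function(events, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_lines(sprintf("# betacage-events v%d", FORMAT_VERSION), path)
    readr::write_csv(as_tibble(events), path, append = TRUE, col_names = TRUE)
  } else {
    hdr <- jsonlite::toJSON(
      list(format = "betacage-events", version = FORMAT_VERSION),
      auto_unbox = TRUE
    )
    rows <- vapply(seq_len(nrow(events)), function(i) {
      as.character(jsonlite::toJSON(
        list(
          event_id = events$event_id[i], t = events$t[i],
          epoch_kind = events$epoch_kind[i], rewarded = events$rewarded[i]
        ),
        auto_unbox = TRUE, na = "null", digits = NA
      ))
    }, character(1))
    readr::write_lines(c(as.character(hdr), rows), path)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    first <- readr::read_lines(path, n_max = 1)
    m <- regmatches(first, regexec("^# betacage-events v(\\d+)$", first))[[1]]
    if (length(m) == 0) {
      abort_parse(sprintf("%s: line 1 is not a betacage-events header", path))
    }
    check_version(m[2], "events", path)
    d <- readr::read_csv(path, skip = 1, show_col_types = FALSE,
                         progress = FALSE)
  } else {
    lines <- readr::read_lines(path)
    hdr <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e) NULL)
    if (is.null(hdr) || !identical(hdr$format, "betacage-events")) {
      abort_parse(sprintf("%s: line 1 is not a betacage-events header", path))
    }
    check_version(hdr$version, "events", path)
    d <- purrr::map_dfr(lines[-1], function(l) {
      as_tibble(jsonlite::fromJSON(l))
    })
  }
  if (nrow(d) > 1 && is.unsorted(d$t)) {
    abort_ordering(sprintf("%s: event times are not sorted", path))
  }
  out <- new_reward_events(d$t %||% numeric(0))
  if (nrow(d)) {
    out$event_id <- d$event_id
    out$epoch_kind <- as.character(d$epoch_kind)
    out$rewarded <- as.logical(d$rewarded)
  }
  out
}

# ---- depth frames: plain (P2) PGM per frame + JSON manifest -----------------

write_pgm <- function(frame, path, maxval = 65535) {
  m <- round(frame)
  if (any(m < 0) || any(m > maxval)) {
    abort_invalid_spec("depth values outside the PGM range")
  }
  hdr <- c("P2", sprintf("%d %d", ncol(m), nrow(m)), sprintf("%d", maxval))
  body <- apply(m, 1, paste, collapse = " ")
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 4 || toks[1] != "P2") {
    abort_parse(sprintf("%s: not a plain (P2) PGM file", path))
  }
  w <- as.integer(toks[2])
  h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) {
    abort_parse(sprintf("%s: expected %d pixels, found %d", path, w * h,
                        length(vals)))
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Read and write depth-frame sequences
#'
#' A directory of plain (P2) 16-bit-range PGM frames (`frame_00001.pgm`,
#' pixel value = depth in mm, 0 = invalid) plus a `manifest.json` carrying
#' format version, frame rate, shape, and per-frame timestamps.  The reader
#' validates the manifest against the files present.
#'
#' @param frames A [depth_seq()].
#' @param dir Directory (created if missing).
#' @export
write_depth_seq <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(frames$frames)
  for (i in seq_len(n)) {
    write_pgm(frames$frames[[i]], file.path(dir, sprintf("frame_%05d.pgm", i)))
  }
  manifest <- list(
    format = "betacage-depth", version = FORMAT_VERSION,
    fps = frames$fps, shape = as.integer(frames$shape),
    n_frames = n, timestamps = frames$t
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_depth_seq
#' @export
read_depth_seq <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    abort_parse(sprintf("%s: no manifest.json", dir))
  }
  m <- jsonlite::fromJSON(mpath)
  if (!identical(m$format, "betacage-depth")) {
    abort_parse(sprintf("%s: manifest is not a betacage-depth manifest", mpath))
  }
  check_version(m$version, "depth", mpath)
  files <- file.path(dir, sprintf("frame_%05d.pgm", seq_len(m$n_frames)))
  missing <- !file.exists(files)
  if (any(missing)) {
    abort_parse(sprintf(
      "%s: manifest declares %d frames but %s is missing",
      dir, m$n_frames, basename(files[which(missing)[1]])
    ))
  }
  if (length(m$timestamps) != m$n_frames) {
    abort_parse(sprintf(
      "%s: manifest has %d timestamps for %d frames",
      mpath, length(m$timestamps), m$n_frames
    ))
  }
  depth_seq(lapply(files, read_pgm), m$timestamps, fps = m$fps)
}

#' Read and write GMV series as CSV
#'
#' Columns `t`, `total`, one column per quadrant, and the `gap` flag, with a
#' versioned comment header.
#'
#' @param series A [gmv_series()].
#' @param path File path.
#' @export
write_gmv_csv <- function(series, path) {
  readr::write_lines(sprintf(
    "# betacage-gmv v%d normalized: %d",
    FORMAT_VERSION, as.integer(isTRUE(attr(series, "normalized")))
  ), path)
  readr::write_csv(as_tibble(series), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_gmv_csv
#' @export
read_gmv_csv <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  m <- regmatches(first,
                  regexec("^# betacage-gmv v(\\d+) normalized: (\\d)$", first))[[1]]
  if (length(m) == 0) {
    abort_parse(sprintf("%s: line 1 is not a betacage-gmv header", path))
  }
  check_version(m[2], "gmv", path)
  d <- readr::read_csv(path, skip = 1, show_col_types = FALSE, progress = FALSE)
  attr(d, "normalized") <- m[3] == "1"
  class(d) <- c("gmv_series", class(d))
  d
}

#' Write a status report
#'
#' @param report A [status_report()].
#' @param path Output path.
#' @param format `"json"` or `"text"`.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      c(list(format = "betacage-report", version = FORMAT_VERSION),
        unclass(report)),
      path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  } else {
    readr::write_lines(format_report(report), path)
  }
  invisible(path)
}
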