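#' Default run configuration
#'
#' The nested configuration shared by the command-line surface: sections for
#' the synthetic generator, the power pipeline, conditioning, the RF codec,
#' GMV, clips and analysis, plus a global seed and output directory.  Every
#' field's default is the deployed protocol value (or, for synthetic-scene
#' parameters, the generator default documented in [synth_config()]).
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "betacage-out",
    synth = c(unclass(synth_config()), list(write_frames = FALSE)),
    signal = list(
      order = 3, low_hz = 10, high_hz = 30, window_ms = 500,
      quantize_scale = 1
    ),
    conditioning = list(
      target_count = 2, lockout_s = 10, retrigger = "level",
      baseline_s = 3600, r_duration_s = 120, nr_duration_s = 120,
      r_cue_hz = 700
    ),
    rf = list(
      n_sets = 3, pulses_per_set = 10, pulse_width_ms = 1,
      pulse_rate_hz = 1000, set_period_ms = 20, fs = 20000,
      set_drop_prob = 0, noise_sd = 0, tolerance_s = 0.06
    ),
    gmv = list(
      grid_rows = 2, grid_cols = 2, depth_scale = 1
    ),
    clips = list(
      buffer_s = 8, pre_s = 4, post_s = 4, source_fps = 32, decimation = 4
    ),
    analysis = list(pre_s = 5, post_s = 10)
  )
}

check_against <- function(cfg, template, path = "config") {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown)) {
    abort_invalid_spec(sprintf(
      "%s: unknown key(s): %s", path, paste(unknown, collapse = ", ")
    ))
  }
  for (nm in names(cfg)) {
    here <- paste0(path, "$", nm)
    if (is.list(template[[nm]])) {
      if (!is.list(cfg[[nm]])) {
        abort_invalid_spec(sprintf("%s must be a section (object)", here))
      }
      check_against(cfg[[nm]], template[[nm]], here)
    } else if (is.numeric(template[[nm]]) && !is.null(cfg[[nm]]) &&
               !is.numeric(cfg[[nm]])) {
      abort_invalid_spec(sprintf("%s must be numeric", here))
    }
  }
  invisible(cfg)
}

#' Validate and complete a run configuration
#'
#' Checks the supplied (possibly partial) configuration against
#' [default_config()] — unknown keys are rejected, numeric fields
#' type-checked — and fills unset fields with their defaults.
#'
#' @param config A nested named list (e.g. from [read_config()]).
#' @return The completed configuration.
#' @export
validate_config <- function(config) {
  template <- default_config()
  check_against(config, template)
  out <- utils::modifyList(template, config)
  if (out$synth$duration_s <= 0) {
    abort_invalid_spec("config$synth$duration_s must be positive")
  }
  out
}

#' Read or write a run configuration as JSON
#'
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  cfg <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) abort_parse(sprintf("%s: %s", path, conditionMessage(e)))
  )
  validate_config(cfg)
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
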