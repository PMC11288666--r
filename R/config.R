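#' Default run configuration
#'
#' The resolved defaults of every tunable analysis and simulation
#' parameter, as a nested list that serialises cleanly to YAML. Analysis
#' outputs embed a hash of the resolved configuration for provenance.
#'
#' @return Named nested list.
#' @export
erg_default_config <- function() {
  list(
    trace = list(sampling_rate_hz = 1000, duration_ms = 1000,
                 stimulus_onset_ms = 100),
    flash = list(attenuations = c(-4, -3, -2, -1, 0),
                 stimulus_duration_ms = 100,
                 inter_stimulus_interval_ms = 7000,
                 source_intensity_uW_cm2 = 1874.4),
    bwave = list(baseline_window_ms = 50, search_window_ms = 300,
                 filter_bounds_ms = c(50, 230)),
    flicker = list(start_freq_hz = 7, step_hz = 1, max_freq_hz = 40,
                   pulse_duration_ms = 15, record_duration_ms = 2000),
    fff = list(theta = 5, radius = 1, band_max_hz = 50,
               mode = "contiguous"),
    stats = list(variant = "student", reference = "WT"),
    seed = 1
  )
}

#' Read a run configuration from YAML
#'
#' Reads a flat, human-editable YAML file and merges it over
#' [erg_default_config()]; unknown top-level sections raise an error so
#' typos do not silently fall back to defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Resolved configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- erg_default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration section(s): ",
                 paste(unknown, collapse = ", ")),
          class = "ergkit_error_bad_config")
  }
  for (sec in names(user)) {
    if (is.list(cfg[[sec]])) {
      cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  cfg
}
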