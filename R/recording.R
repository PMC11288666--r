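#' A single ERG recording
#'
#' Container for one uniformly sampled corneal ERG voltage trace together
#' with the stimulus parameters needed to analyse it. Time is implicit:
#' sample `i` (1-based) sits at `t = (i - 1) * 1000 / sampling_rate` ms.
#'
#' @param voltage Numeric vector of voltages in uV, all finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param stimulus_onset Light-onset time in ms from the start of the trace.
#' @param stimulus_duration Stimulus duration in ms.
#' @param irradiance Stimulus irradiance in uW cm^-2 (may be `NA`).
#' @param genotype,eye_id Optional labels carried through to outputs.
#' @param seed Integer seed used to generate the trace, if synthetic.
#' @param meta Named list of additional provenance metadata.
#'
#' @return An object of class `erg_recording`.
#' @seealso [compute_bwave_metrics()], [power_spectrum()], [read_trace()]
#' @export
erg_recording <- function(voltage, sampling_rate,
                          stimulus_onset = 0, stimulus_duration = NA_real_,
                          irradiance = NA_real_,
                          genotype = NA_character_, eye_id = NA_character_,
                          seed = NA_integer_, meta = list()) {
  if (!is.numeric(voltage) || length(voltage) < 2L) {
    abort("`voltage` must be a numeric vector with at least two samples.",
          class = "ergkit_error_bad_trace")
  }
  if (any(!is.finite(voltage))) {
    abort("`voltage` contains non-finite values.",
          class = "ergkit_error_bad_trace")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number (Hz).",
          class = "ergkit_error_bad_trace")
  }
  structure(
    list(
      voltage = as.numeric(voltage),
      sampling_rate = as.numeric(sampling_rate),
      stimulus_onset = as.numeric(stimulus_onset),
      stimulus_duration = as.numeric(stimulus_duration),
      irradiance = as.numeric(irradiance),
      genotype = as.character(genotype),
      eye_id = as.character(eye_id),
      seed = seed,
      meta = meta
    ),
    class = "erg_recording"
  )
}

#' Sample times of a recording
#'
#' @param rec An [erg_recording()].
#' @return Numeric vector of sample times in ms.
#' @export
recording_time <- function(rec) {
  stopifnot(inherits(rec, "erg_recording"))
  (seq_along(rec$voltage) - 1) * 1000 / rec$sampling_rate
}

#' Duration of a recording in ms
#' @param rec An [erg_recording()].
#' @return Trace duration in ms (number of samples times the sample period).
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "erg_recording"))
  length(rec$voltage) * 1000 / rec$sampling_rate
}

#' @export
print.erg_recording <- function(x, ...) {
  cat(sprintf(
    "<erg_recording> %d samples @ %g Hz (%.0f ms), onset %g ms, irradiance %s uW/cm2\n",
    length(x$voltage), x$sampling_rate, recording_duration(x),
    x$stimulus_onset,
    if (is.na(x$irradiance)) "NA" else format(x$irradiance, digits = 4)
  ))
  if (!is.na(x$genotype)) cat("  genotype:", x$genotype,
                              " eye:", x$eye_id, "\n")
  invisible(x)
}
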