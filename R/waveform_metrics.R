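#' Baseline of an ERG recording
#'
#' Arithmetic mean of all samples in the first `window` ms of the trace
#' (the pre-stimulus segment).
#'
#' @param rec An [erg_recording()].
#' @param window Baseline window length in ms (default 50).
#' @return Baseline voltage in uV.
#' @export
compute_baseline <- function(rec, window = 50) {
  stopifnot(inherits(rec, "erg_recording"))
  if (window <= 0) {
    abort("`window` must be positive.", class = "ergkit_error_bad_window")
  }
  t <- recording_time(rec)
  idx <- t < window
  if (!any(idx)) {
    abort("Baseline window contains no samples.",
          class = "ergkit_error_bad_window")
  }
  mean(rec$voltage[idx])
}

#' B-wave amplitude and peak time
#'
#' Baseline-to-peak amplitude: the maximum voltage inside the search
#' window minus the baseline. Ties are broken by the earliest time. The
#' a-wave trough is deliberately not involved (baseline-to-peak, not
#' trough-to-peak).
#'
#' @param rec An [erg_recording()].
#' @param baseline Baseline voltage in uV (from [compute_baseline()]).
#' @param search_window Length-2 vector of ms `(from, to)` within the
#'   recording; defaults to light onset to onset + 300 ms.
#' @return List with `amplitude` (uV) and `peak_time` (ms).
#' @export
compute_b_wave_amplitude <- function(rec, baseline, search_window = NULL) {
  stopifnot(inherits(rec, "erg_recording"))
  if (is.null(search_window)) {
    search_window <- c(rec$stimulus_onset, rec$stimulus_onset + 300)
  }
  t <- recording_time(rec)
  if (search_window[1] < 0 || search_window[2] > t[length(t)] ||
      search_window[1] >= search_window[2]) {
    abort("`search_window` must lie inside the recording.",
          class = "ergkit_error_bad_window")
  }
  idx <- which(t >= search_window[1] & t <= search_window[2])
  i <- idx[which.max(rec$voltage[idx])]
  list(amplitude = rec$voltage[i] - baseline, peak_time = t[i])
}

#' Time of a fractional amplitude crossing on the rising limb
#'
#' Finds the latest time at or before `peak_time` at which the
#' baseline-subtracted trace crosses `fraction * amplitude` from below,
#' by linear interpolation between the bracketing samples. Taking the last
#' upward crossing selects the final rising limb into the b-wave peak, so
#' the a-wave recovery limb can never be picked.
#'
#' @param rec An [erg_recording()].
#' @param baseline Baseline voltage, uV.
#' @param amplitude B-wave amplitude, uV (> 0).
#' @param fraction Fraction of the amplitude in (0, 1) (0.2 or 0.8 for the
#'   implicit-time construction).
#' @param peak_time Time of the b-wave peak, ms.
#' @return Crossing time in ms.
#' @export
find_fraction_crossing <- function(rec, baseline, amplitude, fraction,
                                   peak_time) {
  stopifnot(inherits(rec, "erg_recording"))
  if (!is.finite(amplitude) || amplitude <= 0) {
    abort("`amplitude` must be positive.",
          class = "ergkit_error_nonpositive_amplitude")
  }
  if (fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie in (0, 1).", class = "ergkit_error_bad_params")
  }
  t <- recording_time(rec)
  y <- rec$voltage - baseline
  level <- fraction * amplitude
  last <- max(which(t <= peak_time))
  if (last < 2L) {
    abort("No upward crossing before the peak.", class = "ergkit_no_crossing")
  }
  lo <- y[seq_len(last - 1L)]
  hi <- y[seq.int(2L, last)]
  cross <- which(lo < level & hi >= level)
  if (length(cross) == 0L) {
    abort("No upward crossing before the peak.", class = "ergkit_no_crossing")
  }
  i <- cross[length(cross)]
  t[i] + (level - y[i]) / (y[i + 1L] - y[i]) * (t[i + 1L] - t[i])
}

#' B-wave metrics of one flash recording
#'
#' Full quantification of a flash ERG: baseline (mean of the first
#' `baseline_window` ms), baseline-to-peak b-wave amplitude, the 20% and
#' 80% rising-phase crossing times, and the implicit time defined by
#' extrapolating the straight line through the 20% and 80% points down to
#' the baseline level; the implicit time is that intersection minus light
#' onset. In closed form `implicit_time = t20 - (t80 - t20)/3 - onset`.
#' Values below 50 ms or above 230 ms are flagged invalid (`below_filter` /
#' `above_filter`); boundary values are kept. Other invalidity reasons are
#' `nonpositive_amplitude`, `no_crossing` and `degenerate_rise`.
#'
#' @param rec An [erg_recording()].
#' @param baseline_window Baseline window in ms (default 50).
#' @param search_window Peak search window, ms; default onset to
#'   onset + 300 ms.
#' @param filter_bounds Implicit-time validity band in ms (default
#'   `c(50, 230)`, inclusive).
#' @return A `bwave_metrics` list with fields `baseline`, `amplitude`,
#'   `peak_time`, `t20`, `t80`, `implicit_time`, `valid`, `invalid_reason`.
#' @export
compute_bwave_metrics <- function(rec, baseline_window = 50,
                                  search_window = NULL,
                                  filter_bounds = c(50, 230)) {
  stopifnot(inherits(rec, "erg_recording"))
  baseline <- compute_baseline(rec, baseline_window)
  pk <- compute_b_wave_amplitude(rec, baseline, search_window)

  m <- list(baseline = baseline, amplitude = pk$amplitude,
            peak_time = pk$peak_time,
            t20 = NA_real_, t80 = NA_real_, implicit_time = NA_real_,
            valid = FALSE, invalid_reason = NA_character_)

  if (!is.finite(pk$amplitude) || pk$amplitude <= 0) {
    m$invalid_reason <- "nonpositive_amplitude"
    return(structure(m, class = "bwave_metrics"))
  }

  t20 <- tryCatch(
    find_fraction_crossing(rec, baseline, pk$amplitude, 0.2, pk$peak_time),
    ergkit_no_crossing = function(e) NA_real_)
  t80 <- tryCatch(
    find_fraction_crossing(rec, baseline, pk$amplitude, 0.8, pk$peak_time),
    ergkit_no_crossing = function(e) NA_real_)
  if (is.na(t20) || is.na(t80)) {
    m$invalid_reason <- "no_crossing"
    return(structure(m, class = "bwave_metrics"))
  }
  m$t20 <- t20
  m$t80 <- t80
  if (t80 <= t20) {
    m$invalid_reason <- "degenerate_rise"
    return(structure(m, class = "bwave_metrics"))
  }

  m$implicit_time <- t20 - (t80 - t20) / 3 - rec$stimulus_onset
  if (m$implicit_time < filter_bounds[1]) {
    m$invalid_reason <- "below_filter"
  } else if (m$implicit_time > filter_bounds[2]) {
    m$invalid_reason <- "above_filter"
  } else {
    m$valid <- TRUE
  }
  structure(m, class = "bwave_metrics")
}

#' @export
print.bwave_metrics <- function(x, ...) {
  cat(sprintf(
    "<bwave_metrics> baseline %.2f uV, amplitude %.2f uV @ %.1f ms, IT %.2f ms [%s]\n",
    x$baseline, x$amplitude, x$peak_time, x$implicit_time,
    if (x$valid) "valid" else x$invalid_reason))
  invisible(x)
}

#' @method as_tibble bwave_metrics
#' @export
as_tibble.bwave_metrics <- function(x, ...) {
  tibble(baseline = x$baseline, amplitude = x$amplitude,
         peak_time = x$peak_time, t20 = x$t20, t80 = x$t80,
         implicit_time = x$implicit_time, valid = x$valid,
         invalid_reason = x$invalid_reason)
}

#' B-wave metrics for a list of recordings
#'
#' @param recs List of [erg_recording()] objects.
#' @param ... Passed to [compute_bwave_metrics()].
#' @return A tibble, one row per recording, with metric columns plus the
#'   recording labels (`genotype`, `eye_id`, `irradiance_uW_cm2`,
#'   `attenuation`, `seed`).
#' @export
bwave_metrics_table <- function(recs, ...) {
  rows <- lapply(recs, function(r) {
    m <- as_tibble(compute_bwave_metrics(r, ...))
    att <- r$meta$attenuation %||% NA_real_
    tibble(genotype = r$genotype, eye_id = r$eye_id,
           attenuation = att, irradiance_uW_cm2 = r$irradiance,
           seed = if (is.null(r$seed)) NA_integer_ else r$seed)[
             rep(1, nrow(m)), ] |> cbind(m) |> as_tibble()
  })
  do.call(rbind, rows)
}
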