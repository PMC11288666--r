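#' One-sided power spectrum of a recording
#'
#' Mean-detrended, un-windowed discrete one-sided power spectrum restricted
#' to `[0, band_max]` Hz. Convention: a pure sinusoid of amplitude `a` with
#' an integer number of cycles in the record yields power `a^2/2` at its
#' bin, and the one-sided powers over the full band sum to the mean square
#' of the detrended signal (Parseval). With 2 s records the bin resolution
#' is 0.5 Hz, so integer-Hz stimuli fall exactly on bins.
#'
#' @param rec An [erg_recording()].
#' @param band_max Analysis ceiling in Hz (default 50); must not exceed the
#'   Nyquist frequency. `Inf` keeps the full one-sided spectrum.
#' @return A `power_spectrum` tibble with columns `frequency_hz` and
#'   `power_uV2`, with the bin `resolution_hz` as an attribute.
#' @export
power_spectrum <- function(rec, band_max = 50) {
  stopifnot(inherits(rec, "erg_recording"))
  n <- length(rec$voltage)
  fs <- rec$sampling_rate
  nyq <- fs / 2
  if (is.finite(band_max) && band_max > nyq + 1e-9) {
    abort("`band_max` is above the Nyquist frequency.",
          class = "ergkit_error_bad_band")
  }
  x <- rec$voltage - mean(rec$voltage)
  X <- fft(x)
  nb <- n %/% 2
  k <- 0:nb
  pow <- Mod(X[k + 1])^2 / n^2
  dbl <- k > 0 & !(n %% 2 == 0 & k == nb)   # interior bins count twice
  pow[dbl] <- 2 * pow[dbl]
  freq <- k * fs / n
  keep <- freq <= band_max + 1e-9
  out <- tibble(frequency_hz = freq[keep], power_uV2 = pow[keep])
  attr(out, "resolution_hz") <- fs / n
  attr(out, "n_samples") <- n
  class(out) <- c("power_spectrum", class(out))
  out
}

#' Is a stimulus frequency temporally resolved?
#'
#' A frequency counts as resolved when the spectrum shows a peak at its
#' bin: the power there must exceed `theta` times the noise floor, taken
#' as the median band power over all bins excluding DC, the stimulus bin
#' and its `radius` neighbours, and the bins (with the same radius) at the
#' stimulus harmonics. Harmonics are excluded from the floor but never
#' counted as evidence of resolvability.
#'
#' The default `theta = 5` is calibrated analytically: for white noise the
#' bin powers are exponentially distributed, so the probability that a bin
#' exceeds `theta` times the median is `2^-theta`, i.e. ~3.1% at the
#' default — below the 5% false-positive budget.
#'
#' @param spec A [power_spectrum()].
#' @param f_stim Stimulus frequency in Hz; must fall on a spectral bin.
#' @param theta Peak threshold as a multiple of the noise floor.
#' @param radius Number of neighbouring bins excluded around the stimulus
#'   bin and each harmonic.
#' @return List with `resolvable` (flag), `power` (uV^2 at the stimulus
#'   bin) and `noise_floor` (uV^2).
#' @export
is_resolvable <- function(spec, f_stim, theta = 5, radius = 1) {
  res <- attr(spec, "resolution_hz")
  freq <- spec$frequency_hz
  pow <- spec$power_uV2
  j <- f_stim / res
  if (abs(j - round(j)) > 1e-6) {
    abort("`f_stim` does not fall on a spectral bin; sweep and record duration are misaligned.",
          class = "ergkit_error_off_bin")
  }
  j <- as.integer(round(j)) + 1L
  if (j < 1L || j > length(pow)) {
    abort("`f_stim` lies outside the analysed band.",
          class = "ergkit_error_bad_band")
  }
  excl <- unique(unlist(lapply(
    seq_len(floor(freq[length(freq)] / f_stim)),
    function(m) {
      jm <- as.integer(round(m * f_stim / res)) + 1L
      seq.int(jm - radius, jm + radius)
    })))
  excl <- excl[excl >= 1L & excl <= length(pow)]
  floor_bins <- setdiff(seq_along(pow)[-1L], excl)   # also drop DC
  if (length(floor_bins) < 5L) {
    abort("Too few bins left to estimate a noise floor.",
          class = "ergkit_error_bad_band")
  }
  nf <- median(pow[floor_bins])
  list(resolvable = pow[j] > theta * nf, power = pow[j], noise_floor = nf)
}

#' Flicker fusion frequency of a sweep
#'
#' Evaluates [is_resolvable()] at each swept stimulus frequency in
#' ascending order and reports the flicker fusion frequency (FFF) under
#' two rules: the default contiguity rule (the last resolvable frequency
#' before the first unresolvable one — robust to isolated spurious peaks
#' above fusion) and the literal highest-resolvable-overall rule. Both are
#' returned. When every swept frequency is resolvable the result is
#' censored at the sweep maximum; when none is, the FFF is `NA`.
#'
#' @param series A `flicker_series` from [simulate_flicker_series()] or
#'   assembled from recordings (see [flicker_series_from_recordings()]).
#' @param theta,radius Peak criterion, see [is_resolvable()].
#' @param band_max Spectral analysis ceiling in Hz.
#' @param mode Which rule fills the `fff` field: `"contiguous"` (default)
#'   or `"highest"`.
#' @return An `fff_result`: list with `table` (per-frequency tibble of
#'   power, floor and flag), `fff`, `fff_contiguous`, `fff_highest`,
#'   `censored`, and the criterion parameters.
#' @export
compute_fff <- function(series, theta = 5, radius = 1, band_max = 50,
                        mode = c("contiguous", "highest")) {
  stopifnot(inherits(series, "flicker_series"))
  mode <- match.arg(mode)
  if (length(series$entries) == 0L) {
    abort("Empty flicker sweep.", class = "ergkit_error_bad_protocol")
  }
  freqs <- vapply(series$entries, `[[`, numeric(1), "frequency")
  if (is.unsorted(freqs, strictly = TRUE)) {
    abort("Sweep frequencies must be strictly ascending.",
          class = "ergkit_error_bad_protocol")
  }
  rows <- lapply(series$entries, function(e) {
    sp <- power_spectrum(e$recording, band_max = band_max)
    r <- is_resolvable(sp, e$frequency, theta = theta, radius = radius)
    tibble(stimulus_frequency = e$frequency, power_uV2 = r$power,
           noise_floor_uV2 = r$noise_floor, resolvable = r$resolvable)
  })
  tab <- do.call(rbind, rows)

  flags <- tab$resolvable
  first_fail <- match(FALSE, flags)
  fff_contig <- if (is.na(first_fail)) {
    freqs[length(freqs)]
  } else if (first_fail == 1L) {
    NA_real_
  } else {
    freqs[first_fail - 1L]
  }
  fff_highest <- if (any(flags)) max(freqs[flags]) else NA_real_
  censored <- all(flags)

  structure(
    list(table = tab,
         fff = if (mode == "contiguous") fff_contig else fff_highest,
         fff_contiguous = fff_contig,
         fff_highest = fff_highest,
         censored = censored,
         criterion = list(theta = theta, radius = radius,
                          band_max = band_max, mode = mode)),
    class = "fff_result"
  )
}

#' @export
print.fff_result <- function(x, ...) {
  cat(sprintf(
    "<fff_result> FFF = %s Hz (%s rule)%s; %d/%d frequencies resolvable\n",
    format(x$fff), x$criterion$mode, if (x$censored) " [censored]" else "",
    sum(x$table$resolvable), nrow(x$table)))
  invisible(x)
}

#' Assemble a flicker series from recordings
#'
#' Builds the sweep container consumed by [compute_fff()] from separate
#' per-frequency recordings (e.g. read from disk with [read_trace()]; the
#' stimulus frequency must be present in each recording's
#' `meta$stimulus_frequency` or given explicitly).
#'
#' @param recordings List of [erg_recording()] objects.
#' @param frequencies Optional numeric vector of stimulus frequencies, Hz.
#' @return A `flicker_series` object.
#' @export
flicker_series_from_recordings <- function(recordings, frequencies = NULL) {
  if (is.null(frequencies)) {
    frequencies <- vapply(recordings, function(r) {
      f <- r$meta$stimulus_frequency
      if (is.null(f)) NA_real_ else as.numeric(f)
    }, numeric(1))
  }
  if (any(is.na(frequencies))) {
    abort("Stimulus frequency missing for some recordings.",
          class = "ergkit_error_bad_protocol")
  }
  ord <- order(frequencies)
  entries <- lapply(ord, function(i) {
    list(frequency = frequencies[i], recording = recordings[[i]])
  })
  structure(list(entries = entries),
            frequencies = frequencies[ord],
            record_duration = recording_duration(recordings[[1]]),
            class = "flicker_series")
}
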