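#' Temporal fusion model for flicker simulation
#'
#' Ground truth of the simulated flicker response: the periodic response
#' amplitude at stimulus frequency `f` is
#' `response_gain / (1 + exp(rolloff_sharpness * (f - cutoff_frequency)))`,
#' a logistic rolloff that is ~1 well below the cutoff and ~0 above it.
#' With the default sharpness the amplitude one step (1 Hz) above the
#' cutoff is below 2% of the gain, i.e. the fusion cutoff is effectively
#' hard at the sweep resolution.
#'
#' @param cutoff_frequency Ground-truth flicker fusion frequency, Hz;
#'   should lie inside the sweep band (7-50 Hz).
#' @param rolloff_sharpness Logistic steepness per Hz (> 0).
#' @param response_gain Peak amplitude of the unit response in uV (>= 0).
#' @return A `fusion_model` object.
#' @export
fusion_model <- function(cutoff_frequency = 25, rolloff_sharpness = 4,
                         response_gain = 30) {
  if (cutoff_frequency <= 0 || rolloff_sharpness <= 0 || response_gain < 0) {
    abort("Cutoff and sharpness must be positive; gain non-negative.",
          class = "ergkit_error_bad_params")
  }
  structure(list(cutoff_frequency = cutoff_frequency,
                 rolloff_sharpness = rolloff_sharpness,
                 response_gain = response_gain),
            class = "fusion_model")
}

#' Fusion rolloff factor
#'
#' @param fusion A [fusion_model()].
#' @param freq Stimulus frequency(ies), Hz.
#' @return Amplitude multiplier(s) in `[0, 1]`.
#' @export
fusion_rolloff <- function(fusion, freq) {
  1 / (1 + exp(fusion$rolloff_sharpness * (freq - fusion$cutoff_frequency)))
}

#' Simulate a flicker-ERG frequency sweep
#'
#' For each stimulus frequency of the sweep (7 Hz start, 1 Hz steps by
#' default), builds a 2 s train by superposing a unit pulse response at
#' every stimulus time. The pulse response is a unit-peak rise--decay
#' kernel with fast kinetics, its amplitude set by the fusion rolloff at
#' that frequency, so trains above the fusion cutoff contain essentially
#' noise only. Superposition is computed by discrete convolution of the
#' stimulus impulse train with the sampled kernel.
#'
#' @param fusion A [fusion_model()] (ground-truth cutoff, gain).
#' @param start_freq,step,max_freq Sweep definition in Hz.
#' @param pulse_duration Stimulus pulse length in ms (metadata; the kernel
#'   is the response to one such pulse).
#' @param record_duration Recording length per frequency in ms (default
#'   2000, giving 0.5 Hz spectral resolution).
#' @param sampling_rate Sampling rate in Hz.
#' @param kinetics List with `latency`, `rise_tau`, `decay_tau` (ms) of the
#'   unit pulse response.
#' @param noise_sd Additive white-noise SD in uV.
#' @param seed Master seed; each frequency gets a [child_seed()].
#' @return A `flicker_series` object: list of entries
#'   `(frequency, recording)` plus sweep parameters and the ground-truth
#'   cutoff as attributes.
#' @export
simulate_flicker_series <- function(fusion = fusion_model(),
                                    start_freq = 7, step = 1, max_freq = 40,
                                    pulse_duration = 15,
                                    record_duration = 2000,
                                    sampling_rate = 1000,
                                    kinetics = list(latency = 15,
                                                    rise_tau = 8,
                                                    decay_tau = 30),
                                    noise_sd = 5, seed = NULL) {
  stopifnot(inherits(fusion, "fusion_model"))
  if (step <= 0) {
    abort("`step` must be positive.", class = "ergkit_error_bad_protocol")
  }
  if (start_freq > max_freq) {
    abort("`start_freq` must not exceed `max_freq`.",
          class = "ergkit_error_bad_protocol")
  }
  if (max_freq > sampling_rate / 2) {
    abort("`max_freq` is above the Nyquist frequency.",
          class = "ergkit_error_bad_protocol")
  }
  if (record_duration < 4 * 1000 / start_freq) {
    abort("`record_duration` must cover several periods at `start_freq`.",
          class = "ergkit_error_bad_protocol")
  }

  freqs <- seq(start_freq, max_freq, by = step)
  dt <- 1000 / sampling_rate
  n <- round(record_duration / dt)
  t <- (seq_len(n) - 1) * dt
  # sampled unit-peak pulse response, truncated where it has decayed away
  kern_len <- min(n, ceiling((kinetics$latency + 8 * kinetics$decay_tau) / dt))
  kern <- kernel_rise_decay((seq_len(kern_len) - 1) * dt,
                            kinetics$latency, kinetics$rise_tau,
                            kinetics$decay_tau)

  entries <- lapply(seq_along(freqs), function(k) {
    f <- freqs[k]
    amp <- fusion$response_gain * fusion_rolloff(fusion, f)
    impulses <- numeric(n)
    stim_idx <- unique(round(seq(0, record_duration - 1e-9,
                                 by = 1000 / f) / dt)) + 1L
    stim_idx <- stim_idx[stim_idx <= n]
    impulses[stim_idx] <- amp
    clean <- convolve_train(impulses, kern)
    sd_k <- if (is.null(seed)) NULL else child_seed(seed, k)
    noise <- if (noise_sd > 0) {
      with_seed_if(sd_k, rnorm(n, 0, noise_sd))
    } else numeric(n)
    rec <- erg_recording(
      voltage = clean + noise, sampling_rate = sampling_rate,
      stimulus_onset = 0, stimulus_duration = pulse_duration,
      seed = if (is.null(sd_k)) NA_integer_ else sd_k,
      meta = list(stimulus_frequency = f, response_amp = amp,
                  noise_sd = noise_sd)
    )
    list(frequency = f, recording = rec)
  })

  structure(
    list(entries = entries),
    frequencies = freqs,
    start_freq = start_freq, step = step, max_freq = max_freq,
    pulse_duration = pulse_duration, record_duration = record_duration,
    cutoff_true = fusion$cutoff_frequency,
    seed = seed,
    class = "flicker_series"
  )
}

# Linear (non-circular) convolution of an impulse train with a kernel,
# truncated to the train length.
convolve_train <- function(impulses, kern) {
  n <- length(impulses)
  full <- stats::convolve(impulses, rev(kern), type = "open")
  full[seq_len(n)]
}

#' @export
print.flicker_series <- function(x, ...) {
  f <- attr(x, "frequencies")
  cat(sprintf("<flicker_series> %d frequencies (%g-%g Hz), %g ms records\n",
              length(f), f[1], f[length(f)], attr(x, "record_duration")))
  invisible(x)
}
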