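#' Flash stimulation protocol
#'
#' The white-light flash protocol: a series of stimuli of increasing
#' intensity given as decadic log-unit attenuations of the full source
#' intensity (log -4 .. log 0 by default), 100 ms flashes with 7 s
#' inter-stimulus intervals.
#'
#' @param attenuations Log-unit attenuations, non-positive and strictly
#'   increasing. `0` is the unattenuated source.
#' @param stimulus_duration Flash duration in ms (> 0).
#' @param inter_stimulus_interval Interval between flashes in ms.
#' @param source_intensity Unattenuated source intensity in uW cm^-2.
#' @return A `flash_protocol` object.
#' @export
flash_protocol <- function(attenuations = c(-4, -3, -2, -1, 0),
                           stimulus_duration = 100,
                           inter_stimulus_interval = 7000,
                           source_intensity = 1874.4) {
  if (length(attenuations) < 1L || any(attenuations > 0)) {
    abort("`attenuations` must be non-positive log units.",
          class = "ergkit_error_bad_protocol")
  }
  if (length(attenuations) > 1L && any(diff(attenuations) <= 0)) {
    abort("`attenuations` must be strictly increasing.",
          class = "ergkit_error_bad_protocol")
  }
  if (stimulus_duration <= 0) {
    abort("`stimulus_duration` must be positive.",
          class = "ergkit_error_bad_protocol")
  }
  if (source_intensity <= 0) {
    abort("`source_intensity` must be positive.",
          class = "ergkit_error_bad_protocol")
  }
  structure(
    list(
      n_intensities = length(attenuations),
      attenuations = as.numeric(attenuations),
      stimulus_duration = stimulus_duration,
      inter_stimulus_interval = inter_stimulus_interval,
      source_intensity = source_intensity
    ),
    class = "flash_protocol"
  )
}

#' Synthetic flash-ERG waveform parameters
#'
#' Ground-truth parameters of the phenomenological flash response: a
#' negative a-wave (alpha kernel) followed by a positive b-wave built from
#' a fast (metabotropic-like) and a slow (transporter-like) rise--decay
#' component; the slow component onsets later, so its presence or absence
#' shifts the b-wave onset. Component amplitudes are scaled by a saturating
#' Naka-Rushton function of stimulus irradiance and white Gaussian noise is
#' added on top.
#'
#' Defaults emulate a bright-flash larval zebrafish ERG: a ~30 uV a-trough,
#' a combined b-wave in the 100-150 uV range peaking 150-200 ms after light
#' onset, and an implicit time (20/80 line construction) around 90-110 ms,
#' comfortably inside the 50-230 ms validity band.
#'
#' @param a_amp A-wave trough depth in uV (>= 0).
#' @param a_latency,a_tau A-wave onset delay and time-to-peak, ms.
#' @param b_amp_fast,b_amp_slow Peak amplitudes of the fast and slow b-wave
#'   components in uV (>= 0).
#' @param b_latency_fast,b_latency_slow Component onset delays after light
#'   onset, ms; the slow latency must not precede the fast one.
#' @param rise_tau_fast,rise_tau_slow,decay_tau Component rise and shared
#'   decay time constants, ms (> 0).
#' @param half_sat_irradiance Half-saturating irradiance, uW cm^-2.
#' @param hill_exponent Hill exponent of the intensity-response function.
#' @param noise_sd Additive white-noise standard deviation, uV (>= 0).
#' @param seed Default seed for noise generation (may be `NULL`).
#' @return A `waveform_params` object.
#' @export
waveform_params <- function(a_amp = 30, a_latency = 25, a_tau = 15,
                            b_amp_fast = 100, b_amp_slow = 50,
                            b_latency_fast = 80, b_latency_slow = 110,
                            rise_tau_fast = 40, rise_tau_slow = 60,
                            decay_tau = 300,
                            half_sat_irradiance = 18.7, hill_exponent = 1,
                            noise_sd = 5, seed = NULL) {
  taus <- c(a_tau, rise_tau_fast, rise_tau_slow, decay_tau)
  if (any(taus <= 0)) {
    abort("All time constants must be positive.",
          class = "ergkit_error_bad_params")
  }
  if (any(c(a_amp, b_amp_fast, b_amp_slow) < 0) || noise_sd < 0) {
    abort("Amplitudes and `noise_sd` must be non-negative.",
          class = "ergkit_error_bad_params")
  }
  if (b_latency_slow < b_latency_fast) {
    abort("`b_latency_slow` must be >= `b_latency_fast`.",
          class = "ergkit_error_bad_params")
  }
  structure(
    list(a_amp = a_amp, a_latency = a_latency, a_tau = a_tau,
         b_amp_fast = b_amp_fast, b_amp_slow = b_amp_slow,
         b_latency_fast = b_latency_fast, b_latency_slow = b_latency_slow,
         rise_tau_fast = rise_tau_fast, rise_tau_slow = rise_tau_slow,
         decay_tau = decay_tau,
         half_sat_irradiance = half_sat_irradiance,
         hill_exponent = hill_exponent,
         noise_sd = noise_sd, seed = seed),
    class = "waveform_params"
  )
}

# Broadcast a scalar amplitude scale to the three components.
norm_amp_scale <- function(amp_scale) {
  if (length(amp_scale) == 1L) {
    amp_scale <- c(a = amp_scale, fast = amp_scale, slow = amp_scale)
  }
  if (length(amp_scale) != 3L) {
    abort("`amp_scale` must be length 1 or 3 (a, fast, slow).",
          class = "ergkit_error_bad_params")
  }
  if (is.null(names(amp_scale)) || !all(c("a", "fast", "slow") %in% names(amp_scale))) {
    names(amp_scale) <- c("a", "fast", "slow")
  }
  amp_scale[c("a", "fast", "slow")]
}

#' Noiseless flash waveform
#'
#' Evaluates the deterministic part of the synthetic flash response (sum of
#' the a-wave and the two b-wave component kernels, each times its
#' intensity-scaled amplitude) at arbitrary times after light onset.
#'
#' @param t_rel Times in ms relative to light onset.
#' @param params A [waveform_params()] object.
#' @param intensity_scale Saturation scale in `[0, 1]` (from
#'   [naka_rushton()]).
#' @param amp_scale Scalar or named length-3 vector (`a`, `fast`, `slow`) of
#'   per-component amplitude multipliers.
#' @param latency_shift Rigid time shift of the whole response, ms.
#' @return Numeric vector of voltages in uV (baseline = 0).
#' @export
flash_signal <- function(t_rel, params, intensity_scale = 1,
                         amp_scale = 1, latency_shift = 0) {
  s <- norm_amp_scale(amp_scale)
  with(params, intensity_scale * (
    -a_amp * s[["a"]] *
      kernel_alpha(t_rel, a_latency + latency_shift, a_tau) +
    b_amp_fast * s[["fast"]] *
      kernel_rise_decay(t_rel, b_latency_fast + latency_shift,
                        rise_tau_fast, decay_tau) +
    b_amp_slow * s[["slow"]] *
      kernel_rise_decay(t_rel, b_latency_slow + latency_shift,
                        rise_tau_slow, decay_tau)
  ))
}

#' Simulate one flash-ERG recording
#'
#' Builds a uniformly sampled trace: flat (zero) baseline before light
#' onset, then the noiseless flash waveform of [flash_signal()] with the
#' component amplitudes scaled by the saturating intensity-response of the
#' attenuated irradiance, plus additive white Gaussian noise. The analytic
#' ground truth (attenuation, saturation scale, and the noiseless b-wave
#' peak evaluated on a 20x finer grid) is stored in the recording metadata.
#'
#' @param params A [waveform_params()] object.
#' @param protocol A [flash_protocol()] object.
#' @param attenuation One of `protocol$attenuations` (log units).
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Trace length in ms.
#' @param stimulus_onset Light onset in ms from trace start; the
#'   pre-stimulus segment holds the baseline window.
#' @param amp_scale,latency_shift Passed to [flash_signal()] (used by the
#'   cohort simulator for genotype and eye effects).
#' @param search_window Length of the post-onset analysis window in ms the
#'   trace must cover (also used for the ground-truth peak search).
#' @param seed Seed for the noise stream; `NULL` uses the current RNG state.
#' @param genotype,eye_id Labels stored on the recording.
#' @return An [erg_recording()] with ground truth in `$meta`.
#' @export
simulate_flash_response <- function(params, protocol = flash_protocol(),
                                    attenuation = 0,
                                    sampling_rate = 1000, duration = 1000,
                                    stimulus_onset = 100,
                                    amp_scale = 1, latency_shift = 0,
                                    search_window = 300,
                                    seed = params$seed,
                                    genotype = NA_character_,
                                    eye_id = NA_character_) {
  stopifnot(inherits(params, "waveform_params"),
            inherits(protocol, "flash_protocol"))
  if (sampling_rate <= 0) {
    abort("`sampling_rate` must be positive.",
          class = "ergkit_error_bad_trace")
  }
  if (!any(abs(protocol$attenuations - attenuation) < 1e-9)) {
    abort("`attenuation` is not one of the protocol attenuations.",
          class = "ergkit_error_bad_protocol")
  }
  if (duration < stimulus_onset + search_window) {
    abort("Trace too short: must cover stimulus onset plus the analysis window.",
          class = "ergkit_error_short_trace")
  }

  irradiance <- attenuated_intensity(protocol$source_intensity, attenuation)
  scale_i <- naka_rushton(irradiance, params$half_sat_irradiance,
                          params$hill_exponent)

  dt <- 1000 / sampling_rate
  t <- seq(0, duration - dt, by = dt)
  clean <- flash_signal(t - stimulus_onset, params, scale_i,
                        amp_scale, latency_shift)
  noise <- if (params$noise_sd > 0) {
    with_seed_if(seed, rnorm(length(t), 0, params$noise_sd))
  } else {
    numeric(length(t))
  }

  # analytic peak of the noiseless b-wave, on a 20x finer grid
  tf <- seq(stimulus_onset, stimulus_onset + search_window, by = dt / 20)
  fine <- flash_signal(tf - stimulus_onset, params, scale_i,
                       amp_scale, latency_shift)
  i_max <- which.max(fine)

  erg_recording(
    voltage = clean + noise,
    sampling_rate = sampling_rate,
    stimulus_onset = stimulus_onset,
    stimulus_duration = protocol$stimulus_duration,
    irradiance = irradiance,
    genotype = genotype, eye_id = eye_id,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    meta = list(
      attenuation = attenuation,
      intensity_scale = scale_i,
      amp_scale = norm_amp_scale(amp_scale),
      latency_shift = latency_shift,
      noise_sd = params$noise_sd,
      b_amp_true = fine[i_max],
      b_peak_time_true = tf[i_max]
    )
  )
}
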