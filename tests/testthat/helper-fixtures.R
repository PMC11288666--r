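# Shared fixture builders. Everything is generated in code; no files.

# A recording holding a linear ramp from `v0` at `t_start` to `v1` at
# `t_end` (ms), constant outside, at 1 kHz.
ramp_recording <- function(t_start, t_end, v0 = 0, v1 = 100,
                           duration = 1000, onset = 100) {
  t <- seq(0, duration - 1, by = 1)
  v <- ifelse(t < t_start, v0,
              ifelse(t > t_end, v1,
                     v0 + (v1 - v0) * (t - t_start) / (t_end - t_start)))
  erg_recording(v, 1000, stimulus_onset = onset)
}

# Logistic rise A / (1 + exp(-(t - t0)/tau)) at 1 kHz.
logistic_recording <- function(t0, tau, A = 100, duration = 1000,
                               onset = 100) {
  t <- seq(0, duration - 1, by = 1)
  erg_recording(A / (1 + exp(-(t - t0) / tau)), 1000,
                stimulus_onset = onset)
}

# Independent re-derivation of the waveform kernels (closed-form peak
# normalisation), used to check superposition pointwise.
ref_rise_decay <- function(t, lat, r, d) {
  x <- t - lat
  xs <- r * log((r + d) / r)
  fm <- (1 - exp(-xs / r)) * exp(-xs / d)
  ifelse(x > 0, (1 - exp(-x / r)) * exp(-x / d) / fm, 0)
}
ref_alpha <- function(t, lat, tau) {
  x <- (t - lat) / tau
  ifelse(x > 0, x * exp(1 - x), 0)
}

# Brute-force last-upward-crossing scan with linear interpolation, over
# all sample pairs at or before the peak.
brute_force_crossing <- function(rec, baseline, level, peak_time) {
  t <- recording_time(rec)
  y <- rec$voltage - baseline
  best <- NA_real_
  for (i in seq_len(length(t) - 1)) {
    if (t[i + 1] > peak_time) break
    if (y[i] < level && y[i + 1] >= level) {
      best <- t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
    }
  }
  best
}

# Two-genotype null cohort config (identical parameters) for calibration.
null_cohort_config <- function(n_eyes, master_seed) {
  gt <- tibble::tibble(genotype = c("WT", "WT2"),
                       scale_a = 1, scale_fast = 1, scale_slow = 1,
                       latency_shift = 0)
  cohort_config(gt, eyes_per_genotype = n_eyes, master_seed = master_seed)
}
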