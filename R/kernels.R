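# Phenomenological waveform kernels. Both are smooth, unimodal, zero before
# `latency`, and normalised to unit peak so that the multiplying amplitude
# parameter is the peak deflection in uV.

#' Unit-peak rise--decay kernel
#'
#' `(1 - exp(-x/rise_tau)) * exp(-x/decay_tau)` for `x = t - latency > 0`,
#' scaled to peak at exactly 1. The peak location has the closed form
#' `x* = rise_tau * log((rise_tau + decay_tau) / rise_tau)`.
#'
#' @param t Times in ms at which to evaluate.
#' @param latency Onset delay in ms; the kernel is 0 for `t <= latency`.
#' @param rise_tau,decay_tau Rise and decay time constants in ms (> 0).
#' @return Numeric vector of kernel values in `[0, 1]`.
#' @export
kernel_rise_decay <- function(t, latency, rise_tau, decay_tau) {
  stopifnot(rise_tau > 0, decay_tau > 0)
  out <- numeric(length(t))
  x <- t - latency
  pos <- x > 0
  if (any(pos)) {
    xs <- rise_tau * log((rise_tau + decay_tau) / rise_tau)
    fmax <- (1 - exp(-xs / rise_tau)) * exp(-xs / decay_tau)
    xp <- x[pos]
    out[pos] <- (1 - exp(-xp / rise_tau)) * exp(-xp / decay_tau) / fmax
  }
  out
}

#' Unit-peak alpha-function kernel
#'
#' `x/tau * exp(1 - x/tau)` for `x = t - latency > 0`; peaks at 1 when
#' `x = tau`. Used (negated) for the a-wave trough.
#'
#' @inheritParams kernel_rise_decay
#' @param tau Time-to-peak in ms (> 0).
#' @return Numeric vector of kernel values in `[0, 1]`.
#' @export
kernel_alpha <- function(t, latency, tau) {
  stopifnot(tau > 0)
  out <- numeric(length(t))
  x <- (t - latency) / tau
  pos <- x > 0
  out[pos] <- x[pos] * exp(1 - x[pos])
  out
}

#' Saturating intensity--response scaling
#'
#' Naka-Rushton-style hyperbolic saturation
#' `I^n / (I^n + half_sat^n)`, mapping stimulus irradiance to a response
#' scale in `[0, 1)`.
#'
#' @param irradiance Stimulus irradiance(s) in uW cm^-2 (>= 0).
#' @param half_sat Irradiance giving a half-maximal response, uW cm^-2.
#' @param exponent Hill exponent (> 0); 1 gives the classical hyperbola.
#' @return Response scale(s) in `[0, 1)`.
#' @export
naka_rushton <- function(irradiance, half_sat, exponent = 1) {
  stopifnot(half_sat > 0, exponent > 0)
  if (any(irradiance < 0)) {
    abort("`irradiance` must be non-negative.",
          class = "ergkit_error_bad_irradiance")
  }
  irradiance^exponent / (irradiance^exponent + half_sat^exponent)
}
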