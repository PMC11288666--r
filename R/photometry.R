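#' Spectral irradiance of a light source
#'
#' A measured (or simulated) source spectrum: wavelength in nm against
#' spectral irradiance in uW cm^-2 nm^-1.
#'
#' @param wavelength Strictly ascending wavelengths, nm (>= 2 points).
#' @param irradiance Non-negative spectral irradiance, uW cm^-2 nm^-1.
#' @param source Optional source label.
#' @return A `spectral_irradiance` object (a tibble with attributes).
#' @export
spectral_irradiance <- function(wavelength, irradiance, source = NA_character_) {
  if (length(wavelength) < 2L || length(wavelength) != length(irradiance)) {
    abort("Need >= 2 (wavelength, irradiance) pairs of equal length.",
          class = "ergkit_error_bad_spectrum")
  }
  if (any(diff(wavelength) <= 0)) {
    abort("`wavelength` must be strictly ascending.",
          class = "ergkit_error_bad_spectrum")
  }
  if (any(!is.finite(irradiance)) || any(irradiance < 0)) {
    abort("`irradiance` must be finite and non-negative.",
          class = "ergkit_error_bad_spectrum")
  }
  out <- tibble(wavelength_nm = as.numeric(wavelength),
                spectral_irradiance_uW_cm2_nm = as.numeric(irradiance))
  attr(out, "source") <- source
  class(out) <- c("spectral_irradiance", class(out))
  out
}

#' Integrate a spectrum into a light intensity
#'
#' Source intensity as the area under the spectral-irradiance curve,
#' computed by the trapezoidal rule on the native wavelength grid and
#' restricted to `[lambda_min, lambda_max]` with linear interpolation at
#' the clip boundaries. Exact for piecewise-linear spectra.
#'
#' @param spec A [spectral_irradiance()] object (or a two-column data frame
#'   of wavelength and spectral irradiance).
#' @param lambda_min,lambda_max Integration bounds in nm (default the
#'   189-800 nm band of the spectrometer).
#' @return Intensity in uW cm^-2.
#' @export
integrate_spectrum <- function(spec, lambda_min = 189, lambda_max = 800) {
  wl <- spec[[1]]
  ir <- spec[[2]]
  if (any(diff(wl) <= 0)) {
    abort("Spectrum wavelengths must be strictly ascending.",
          class = "ergkit_error_bad_spectrum")
  }
  if (lambda_min >= lambda_max) {
    abort("`lambda_min` must be below `lambda_max`.",
          class = "ergkit_error_bad_band")
  }
  lo <- max(lambda_min, wl[1])
  hi <- min(lambda_max, wl[length(wl)])
  if (lo >= hi) {
    abort("Integration band does not overlap the spectrum support.",
          class = "ergkit_error_bad_band")
  }
  inside <- wl > lo & wl < hi
  x <- c(lo, wl[inside], hi)
  y <- c(approx(wl, ir, xout = lo)$y, ir[inside], approx(wl, ir, xout = hi)$y)
  pracma::trapz(x, y)
}

#' Attenuate a source intensity by decadic log units
#'
#' @param source_intensity Unattenuated intensity, uW cm^-2 (>= 0).
#' @param attenuation Attenuation in log units (<= 0); `-k` multiplies the
#'   intensity by `10^-k`.
#' @return Attenuated irradiance in uW cm^-2.
#' @export
attenuated_intensity <- function(source_intensity, attenuation) {
  if (any(source_intensity < 0)) {
    abort("`source_intensity` must be non-negative.",
          class = "ergkit_error_bad_irradiance")
  }
  if (any(attenuation > 0)) {
    abort("`attenuation` must be <= 0 log units.",
          class = "ergkit_error_bad_irradiance")
  }
  source_intensity * 10^attenuation
}

#' Build the log-attenuation stimulus ladder
#'
#' Applies [attenuated_intensity()] to each step of a log-unit attenuation
#' series (default the five-step log -4 .. log 0 ladder).
#'
#' @param source_intensity Unattenuated intensity, uW cm^-2.
#' @param attenuations Ascending, non-positive log units.
#' @return An `intensity_series` tibble with columns `attenuation` and
#'   `irradiance_uW_cm2`, with the source intensity as an attribute.
#' @export
build_intensity_series <- function(source_intensity,
                                   attenuations = c(-4, -3, -2, -1, 0)) {
  if (length(attenuations) == 0L) {
    abort("`attenuations` must not be empty.",
          class = "ergkit_error_bad_protocol")
  }
  if (length(attenuations) > 1L && any(diff(attenuations) <= 0)) {
    abort("`attenuations` must be strictly increasing.",
          class = "ergkit_error_bad_protocol")
  }
  out <- tibble(
    attenuation = as.numeric(attenuations),
    irradiance_uW_cm2 = attenuated_intensity(source_intensity, attenuations)
  )
  attr(out, "source_intensity") <- source_intensity
  class(out) <- c("intensity_series", class(out))
  out
}
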