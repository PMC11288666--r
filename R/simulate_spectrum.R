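#' Simulate a light-source spectrum
#'
#' Generates a non-negative spectral-irradiance curve of a chosen shape on
#' a wavelength grid inside the 189-800 nm spectrometer band, scaled so
#' that [integrate_spectrum()] over that band returns exactly the
#' requested total intensity (the normalisation uses the same trapezoid on
#' the same grid, so the contract holds to floating-point precision).
#'
#' Shapes: `"rectangular"` (flat over 250-750 nm), `"triangular"` (linear
#' ramp up to a 480 nm apex over a 200-760 nm base), `"xenon"` (smooth
#' continuum plus narrow emission-like peaks, loosely resembling a xenon
#' arc lamp).
#'
#' @param shape One of `"rectangular"`, `"triangular"`, `"xenon"`.
#' @param total_intensity Requested band intensity in uW cm^-2 (> 0).
#' @param wavelength_grid Ascending grid in nm within `[189, 800]`.
#' @return A [spectral_irradiance()] object.
#' @export
simulate_spectrum <- function(shape = c("xenon", "rectangular", "triangular"),
                              total_intensity = 1874.4,
                              wavelength_grid = seq(189, 800, by = 1)) {
  shape <- match.arg(shape)
  wl <- wavelength_grid
  if (any(wl < 189 - 1e-9) || any(wl > 800 + 1e-9)) {
    abort("`wavelength_grid` must lie within [189, 800] nm.",
          class = "ergkit_error_bad_spectrum")
  }
  if (any(diff(wl) <= 0) || length(wl) < 2L) {
    abort("`wavelength_grid` must be strictly ascending with >= 2 points.",
          class = "ergkit_error_bad_spectrum")
  }
  if (total_intensity <= 0) {
    abort("`total_intensity` must be positive.",
          class = "ergkit_error_bad_spectrum")
  }
  y <- switch(shape,
    rectangular = as.numeric(wl >= 250 & wl <= 750),
    triangular = {
      up <- (wl - 200) / (480 - 200)
      down <- (760 - wl) / (760 - 480)
      pmax(0, pmin(up, down))
    },
    xenon = {
      cont <- exp(-((wl - 520) / 180)^2)
      peaks <- 0.9 * exp(-((wl - 467) / 4)^2) +
        1.1 * exp(-((wl - 492) / 4)^2) +
        0.8 * exp(-((wl - 764) / 5)^2)
      cont + peaks
    })
  raw <- spectral_irradiance(wl, y, source = paste0("synthetic_", shape))
  area <- integrate_spectrum(raw, 189, 800)
  spectral_irradiance(wl, y * total_intensity / area,
                      source = paste0("synthetic_", shape))
}
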