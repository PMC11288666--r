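#' Per-genotype effect table
#'
#' Default genotype effects used by [cohort_config()], emulating the
#' phenotype structure of ON-bipolar cell glutamate-transporter knockouts:
#' the wild type expresses both b-wave components; loss of the slow
#' (transporter-like) component reduces the b-wave and advances its onset;
#' a rigid latency shift delays or advances the whole response.
#'
#' @return A tibble with columns `genotype`, `scale_a`, `scale_fast`,
#'   `scale_slow`, `latency_shift`.
#' @export
genotype_effects <- function() {
  tibble(
    genotype      = c("WT", "eaat5b", "eaat7", "double"),
    scale_a       = c(1, 1, 1, 1),
    scale_fast    = c(1, 1, 1, 0.8),
    scale_slow    = c(1, 0, 1, 0),
    latency_shift = c(0, 0, 15, 0)
  )
}

#' Cohort simulation configuration
#'
#' Defines a simulated cohort: which genotypes with which per-component
#' amplitude scales and whole-response latency shifts, how many eyes per
#' genotype, and how much eye-to-eye variability. Eye-level variability is
#' a multiplicative log-normal amplitude factor (median 1) plus a normal
#' latency jitter applied as a rigid shift, both drawn once per eye. All
#' child seeds derive from `master_seed` by a fixed rule, so any cohort is
#' exactly reproducible.
#'
#' @param genotypes Data frame like [genotype_effects()]; a character
#'   vector is also accepted and subsets the default table.
#' @param eyes_per_genotype Number of eyes per genotype (>= 2).
#' @param amplitude_cv Eye-level coefficient of variation of the
#'   multiplicative amplitude factor (log-normal `sdlog`); 0 disables.
#' @param latency_sd Eye-level SD of the latency jitter in ms; 0 disables.
#' @param master_seed Master seed (non-negative integer < 2^31).
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(genotypes = genotype_effects(),
                          eyes_per_genotype = 8,
                          amplitude_cv = 0.15, latency_sd = 5,
                          master_seed = 1) {
  if (is.character(genotypes)) {
    tab <- genotype_effects()
    missing <- setdiff(genotypes, tab$genotype)
    if (length(missing) > 0) {
      abort(paste0("Unknown genotype label(s): ",
                   paste(missing, collapse = ", ")),
            class = "ergkit_error_bad_config")
    }
    genotypes <- tab[match(genotypes, tab$genotype), ]
  }
  genotypes <- as_tibble(genotypes)
  if (nrow(genotypes) == 0L) {
    abort("`genotypes` must not be empty.",
          class = "ergkit_error_bad_config")
  }
  need <- c("genotype", "scale_a", "scale_fast", "scale_slow",
            "latency_shift")
  if (!all(need %in% names(genotypes))) {
    abort(paste0("`genotypes` must have columns: ",
                 paste(need, collapse = ", ")),
          class = "ergkit_error_bad_config")
  }
  scales <- unlist(genotypes[, c("scale_a", "scale_fast", "scale_slow")])
  if (any(scales < 0 | scales > 1)) {
    abort("Amplitude scales must lie in [0, 1].",
          class = "ergkit_error_bad_config")
  }
  if (eyes_per_genotype < 2) {
    abort("`eyes_per_genotype` must be at least 2.",
          class = "ergkit_error_bad_config")
  }
  structure(
    list(genotypes = genotypes,
         eyes_per_genotype = as.integer(eyes_per_genotype),
         amplitude_cv = amplitude_cv, latency_sd = latency_sd,
         master_seed = as.integer(master_seed)),
    class = "cohort_config"
  )
}

#' Simulate a cohort of eyes
#'
#' One flash recording per eye per protocol intensity. Each eye draws its
#' multiplicative amplitude factor and latency jitter from an eye-level
#' seed, then each trace adds white noise from a trace-level seed; both
#' seeds derive deterministically from the master seed and are recorded in
#' the manifest.
#'
#' @param config A [cohort_config()].
#' @param protocol A [flash_protocol()].
#' @param params A [waveform_params()] shared by all genotypes before
#'   genotype scaling.
#' @param ... Passed to [simulate_flash_response()] (e.g. `sampling_rate`,
#'   `duration`, `stimulus_onset`).
#' @return An `erg_cohort`: list with `recordings` (list of
#'   [erg_recording()]) and `manifest` (tibble, one row per recording,
#'   with genotype, eye, attenuation, seeds and the realized eye effects).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            protocol = flash_protocol(),
                            params = waveform_params(), ...) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(protocol, "flash_protocol"))
  gt <- config$genotypes
  recs <- list()
  rows <- list()
  idx <- 0L
  for (g in seq_len(nrow(gt))) {
    for (e in seq_len(config$eyes_per_genotype)) {
      eye_seed <- child_seed(config$master_seed,
                             g * 100000L + e * 100L)
      eye_eff <- with_seed_if(eye_seed, {
        list(amp_factor = if (config$amplitude_cv > 0) {
               exp(rnorm(1, 0, config$amplitude_cv))
             } else 1,
             latency_jitter = if (config$latency_sd > 0) {
               rnorm(1, 0, config$latency_sd)
             } else 0)
      })
      eye_id <- sprintf("%s_eye%02d", gt$genotype[g], e)
      for (a in seq_along(protocol$attenuations)) {
        idx <- idx + 1L
        trace_seed <- child_seed(eye_seed, a)
        amp_scale <- c(a = gt$scale_a[g], fast = gt$scale_fast[g],
                       slow = gt$scale_slow[g]) * eye_eff$amp_factor
        shift <- gt$latency_shift[g] + eye_eff$latency_jitter
        recs[[idx]] <- simulate_flash_response(
          params, protocol, protocol$attenuations[a],
          amp_scale = amp_scale, latency_shift = shift,
          seed = trace_seed, genotype = gt$genotype[g], eye_id = eye_id,
          ...)
        rows[[idx]] <- tibble(
          genotype = gt$genotype[g], eye_id = eye_id,
          attenuation = protocol$attenuations[a],
          irradiance_uW_cm2 = recs[[idx]]$irradiance,
          eye_seed = eye_seed, trace_seed = trace_seed,
          amp_factor = eye_eff$amp_factor,
          latency_jitter = eye_eff$latency_jitter,
          latency_shift_total = shift)
      }
    }
  }
  structure(list(recordings = recs, manifest = do.call(rbind, rows),
                 master_seed = config$master_seed),
            class = "erg_cohort")
}

#' @export
print.erg_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<erg_cohort> %d recordings: %d genotypes x %d eyes x %d intensities (seed %d)\n",
    nrow(m), length(unique(m$genotype)), length(unique(m$eye_id)) /
      length(unique(m$genotype)), length(unique(m$attenuation)),
    x$master_seed))
  invisible(x)
}
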