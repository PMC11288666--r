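# Text formats: comment-prefixed "# key: value" metadata headers followed
# by a tab-separated numeric table. Diff-able, fixture-friendly, and
# byte-reproducible (numbers written with 9 significant digits).

fmt_num <- function(x) {
  out <- formatC(x, digits = 9, format = "g")
  out[is.na(x)] <- "NA"
  out
}

trace_meta_keys <- c("sampling_rate_hz", "stimulus_onset_ms",
                     "stimulus_duration_ms", "irradiance_uW_cm2",
                     "genotype", "eye_id", "seed")

#' Write an ERG recording to a trace file
#'
#' Tab-separated text: `# key: value` metadata header lines, then the
#' columns `time_ms` and `voltage_uV`.
#'
#' @param rec An [erg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(rec, path) {
  stopifnot(inherits(rec, "erg_recording"))
  meta <- c(
    sampling_rate_hz = fmt_num(rec$sampling_rate),
    stimulus_onset_ms = fmt_num(rec$stimulus_onset),
    stimulus_duration_ms = fmt_num(rec$stimulus_duration),
    irradiance_uW_cm2 = fmt_num(rec$irradiance),
    genotype = rec$genotype,
    eye_id = rec$eye_id,
    seed = fmt_num(as.numeric(rec$seed %||% NA))
  )
  if (!is.null(rec$meta$stimulus_frequency)) {
    meta <- c(meta,
              stimulus_frequency_hz = fmt_num(rec$meta$stimulus_frequency))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste0("# ", names(meta), ": ", meta),
               "time_ms\tvoltage_uV",
               paste(fmt_num(recording_time(rec)), fmt_num(rec$voltage),
                     sep = "\t")),
             con)
  invisible(path)
}

#' Read an ERG recording from a trace file
#'
#' Parses the trace dialect written by [write_trace()]: `# key: value`
#' header lines, then two numeric columns `time_ms`, `voltage_uV`. The
#' time grid must be uniform within a relative tolerance of 1e-6. Missing
#' metadata keys are filled from `defaults` with a warning.
#'
#' @param path Trace file path.
#' @param defaults Named list of fallback metadata values (e.g.
#'   `list(sampling_rate_hz = 1000, stimulus_onset_ms = 100)`).
#' @return An [erg_recording()].
#' @export
read_trace <- function(path, defaults = list()) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    mt <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(mt) == 3) meta[[trimws(mt[2])]] <- trimws(mt[3])
  }
  body <- lines[!hdr]
  tab <- tryCatch(
    read.table(text = body, header = TRUE, sep = "\t",
               colClasses = "numeric"),
    error = function(e) {
      abort("Trace body is not a two-column numeric table.",
            class = "ergkit_error_bad_trace", parent = e)
    })
  if (!all(c("time_ms", "voltage_uV") %in% names(tab))) {
    abort("Trace file must have columns `time_ms` and `voltage_uV`.",
          class = "ergkit_error_bad_trace")
  }
  t <- tab$time_ms
  dt <- diff(t)
  if (length(dt) == 0L || any(dt <= 0) ||
      max(abs(dt - median(dt))) > 1e-6 * abs(median(dt))) {
    abort("Trace time grid is not uniform.",
          class = "ergkit_error_nonuniform_grid")
  }

  get_meta <- function(key, as_num = TRUE) {
    v <- meta[[key]]
    if (is.null(v) || identical(v, "NA")) {
      if (!is.null(defaults[[key]])) {
        warn(paste0("Trace header lacks `", key,
                    "`; using the configured default."),
             class = "ergkit_warning_meta_fallback")
        return(defaults[[key]])
      }
      return(NA)
    }
    if (as_num) as.numeric(v) else v
  }
  fs_header <- get_meta("sampling_rate_hz")
  fs_grid <- 1000 / median(dt)
  fs <- if (is.na(fs_header)) fs_grid else fs_header
  meta_extra <- list()
  if (!is.null(meta$stimulus_frequency_hz)) {
    meta_extra$stimulus_frequency <- as.numeric(meta$stimulus_frequency_hz)
  }
  erg_recording(
    voltage = tab$voltage_uV,
    sampling_rate = fs,
    stimulus_onset = as.numeric(get_meta("stimulus_onset_ms") %||% 0),
    stimulus_duration = as.numeric(get_meta("stimulus_duration_ms")),
    irradiance = as.numeric(get_meta("irradiance_uW_cm2")),
    genotype = as.character(get_meta("genotype", as_num = FALSE)),
    eye_id = as.character(get_meta("eye_id", as_num = FALSE)),
    seed = suppressWarnings(as.integer(get_meta("seed"))),
    meta = meta_extra
  )
}

#' Write a metrics (or any homogeneous) table
#'
#' Tab-separated text with a header row, stable column order, numbers at 9
#' significant digits, and provenance comment lines (seed and a hash of
#' the analysis configuration). Writing the same records twice produces
#' byte-identical files.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @param config Optional configuration object; its [rlang::hash()] is
#'   recorded in the header.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path, seed = NULL, config = NULL) {
  records <- as.data.frame(records)
  hdr <- c(
    if (!is.null(seed)) paste0("# seed: ", fmt_num(as.numeric(seed))),
    if (!is.null(config)) paste0("# config_hash: ", rlang::hash(config))
  )
  cols <- vapply(records, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }, character(nrow(records)))
  if (nrow(records) == 1L) cols <- matrix(cols, nrow = 1)
  body <- if (nrow(records) == 0L) {
    character(0)
  } else {
    apply(cols, 1L, paste, collapse = "\t")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(names(records), collapse = "\t"), body), con)
  invisible(path)
}

#' Read a metrics table written by [write_metrics()]
#'
#' @param path File path.
#' @return A tibble (comment header lines are skipped).
#' @export
read_metrics <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       comment.char = "#", stringsAsFactors = FALSE))
}

#' Write a spectrum file
#'
#' Two tab-separated columns: `wavelength_nm`,
#' `spectral_irradiance_uW_cm2_nm`.
#'
#' @param spec A [spectral_irradiance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  src <- attr(spec, "source")
  writeLines(c(
    if (!is.null(src) && !is.na(src)) paste0("# source: ", src),
    "wavelength_nm\tspectral_irradiance_uW_cm2_nm",
    paste(fmt_num(spec[[1]]), fmt_num(spec[[2]]), sep = "\t")), con)
  invisible(path)
}

#' Read a spectrum file
#'
#' @param path File path.
#' @return A [spectral_irradiance()].
#' @export
read_spectrum <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("wavelength_nm", "spectral_irradiance_uW_cm2_nm") %in%
           names(tab))) {
    abort("Spectrum file must have columns `wavelength_nm` and `spectral_irradiance_uW_cm2_nm`.",
          class = "ergkit_error_bad_spectrum")
  }
  spectral_irradiance(tab$wavelength_nm, tab$spectral_irradiance_uW_cm2_nm)
}
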