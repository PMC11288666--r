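Package: ergkit
Title: Quantification and Simulation of Larval Zebrafish Electroretinograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies flash electroretinogram (ERG) recordings of the
    larval zebrafish eye: b-wave baseline and amplitude, implicit time by
    20-80 percent rising-phase line extrapolation with a 50-230 ms validity
    filter, flicker fusion frequency from one-sided FFT power spectra in the
    0-50 Hz band, and light-source photometry by trapezoidal integration of
    spectral irradiance with a decadic log-attenuation stimulus ladder.
    Cohorts of eyes are compared per stimulus intensity with two-tailed
    two-sample t-tests and box-and-whisker summaries. A synthetic ERG
    generator produces flash traces, flicker trains, cohorts and source
    spectra with recorded ground truth so every analysis stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
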