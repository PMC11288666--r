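test_that("baseline is the mean of the pre-stimulus window", {
  rec <- erg_recording(rep(12, 1000), 1000, stimulus_onset = 100)
  expect_equal(compute_baseline(rec), 12)

  v <- rep(c(0, 2), 500)
  rec2 <- erg_recording(v, 1000, stimulus_onset = 100)
  expect_equal(compute_baseline(rec2), 1)

  set.seed(7)
  v3 <- rnorm(1000, 5, 3)
  rec3 <- erg_recording(v3, 1000, stimulus_onset = 100)
  expect_equal(compute_baseline(rec3), sum(v3[1:50]) / 50)

  expect_error(compute_baseline(rec, window = 0),
               class = "ergkit_error_bad_window")
})

test_that("b-wave amplitude is baseline-to-peak with earliest-tie breaking", {
  rec <- logistic_recording(t0 = 250, tau = 10, A = 150)
  m <- compute_b_wave_amplitude(rec, baseline = 0)
  expect_equal(m$amplitude, 150, tolerance = 1e-3)

  m2 <- compute_b_wave_amplitude(rec, baseline = 10)
  expect_equal(m2$amplitude, 140, tolerance = 1e-3)

  # a-trough then positive peak: amplitude measured from baseline, not
  # from the trough
  t <- seq(0, 999)
  v <- -30 * ref_alpha(t - 100, 25, 15) +
    120 * ref_rise_decay(t - 100, 80, 40, 300)
  rec3 <- erg_recording(v, 1000, stimulus_onset = 100)
  m3 <- compute_b_wave_amplitude(rec3, baseline = 0)
  expect_equal(m3$amplitude, 120, tolerance = 0.2)
  expect_gt(m3$amplitude, 100)  # clearly not 150 = trough-to-peak

  # ties broken by earliest time
  v4 <- rep(0, 1000); v4[301] <- 50; v4[351] <- 50
  rec4 <- erg_recording(v4, 1000, stimulus_onset = 100)
  expect_equal(compute_b_wave_amplitude(rec4, 0)$peak_time, 300)

  expect_error(compute_b_wave_amplitude(rec, 0, c(500, 2000)),
               class = "ergkit_error_bad_window")
})

test_that("fraction crossings interpolate linearly on the final rising limb", {
  rec <- ramp_recording(100, 200, 0, 100)
  expect_equal(find_fraction_crossing(rec, 0, 100, 0.2, 200), 120)
  expect_equal(find_fraction_crossing(rec, 0, 100, 0.8, 200), 180)

  # step between adjacent samples: interpolation convention
  v <- c(rep(0, 150), rep(100, 850))
  rec2 <- erg_recording(v, 1000, stimulus_onset = 100)
  expect_equal(find_fraction_crossing(rec2, 0, 100, 0.5, 200), 149.5)

  expect_error(find_fraction_crossing(rec, 0, 100, 0.2, peak_time = 0),
               class = "ergkit_no_crossing")
  expect_error(find_fraction_crossing(rec, 0, -5, 0.2, 200),
               class = "ergkit_error_nonpositive_amplitude")
})

test_that("crossing selection matches a brute-force scan on noisy traces", {
  set.seed(21)
  for (i in 1:20) {
    t <- seq(0, 999)
    clean <- 120 * ref_rise_decay(t - 100, 80, 40, 300) -
      25 * ref_alpha(t - 100, 25, 15)
    rec <- erg_recording(clean + rnorm(1000, 0, 8), 1000,
                         stimulus_onset = 100)
    b <- compute_baseline(rec)
    pk <- compute_b_wave_amplitude(rec, b)
    for (fr in c(0.2, 0.8)) {
      got <- tryCatch(
        find_fraction_crossing(rec, b, pk$amplitude, fr, pk$peak_time),
        ergkit_no_crossing = function(e) NA_real_)
      want <- brute_force_crossing(rec, b, fr * pk$amplitude, pk$peak_time)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("implicit time follows the 20/80 line construction and filter", {
  # ramp starting 80 ms after onset: the 20/80 line coincides with the
  # ramp, so the implicit time is exactly the ramp start
  rec <- ramp_recording(180, 330)
  m <- compute_bwave_metrics(rec, search_window = c(100, 500))
  expect_equal(m$implicit_time, 80, tolerance = 1e-6)
  expect_true(m$valid)

  # ramp starting exactly at onset: implicit time 0, filtered out
  rec0 <- ramp_recording(100, 250)
  m0 <- compute_bwave_metrics(rec0, search_window = c(100, 500))
  expect_equal(m0$implicit_time, 0, tolerance = 1e-6)
  expect_false(m0$valid)
  expect_equal(m0$invalid_reason, "below_filter")

  # logistic rise closed form: IT = 150 - (5/3) tau log 4
  recl <- logistic_recording(t0 = 250, tau = 10)
  ml <- compute_bwave_metrics(recl, search_window = c(100, 500))
  expect_equal(ml$implicit_time, 150 - 5 / 3 * 10 * log(4),
               tolerance = 0.05)
  expect_true(ml$valid)
  expect_lt(ml$t20, ml$t80)
  expect_lte(ml$t80, ml$peak_time)

  # flat trace: no positive amplitude
  flat <- erg_recording(rep(0, 1000), 1000, stimulus_onset = 100)
  mf <- compute_bwave_metrics(flat)
  expect_false(mf$valid)
  expect_equal(mf$invalid_reason, "nonpositive_amplitude")
})

test_that("metrics are scale invariant and shift equivariant", {
  p <- waveform_params(noise_sd = 0)
  base <- simulate_flash_response(p, attenuation = 0)
  m0 <- compute_bwave_metrics(base)

  for (c_ in c(0.5, 2, 7.3)) {
    rec <- base
    rec$voltage <- base$voltage * c_
    m <- compute_bwave_metrics(rec)
    expect_equal(m$amplitude, c_ * m0$amplitude, tolerance = 1e-9)
    expect_equal(m$t20, m0$t20, tolerance = 1e-9)
    expect_equal(m$t80, m0$t80, tolerance = 1e-9)
    expect_equal(m$implicit_time, m0$implicit_time, tolerance = 1e-9)
  }

  # delaying the response by an integer number of samples shifts the
  # implicit time by exactly that delay
  for (delta in c(10, 25, 40)) {
    rec <- simulate_flash_response(p, attenuation = 0,
                                   latency_shift = delta)
    m <- compute_bwave_metrics(rec)
    expect_equal(m$implicit_time, m0$implicit_time + delta,
                 tolerance = 1e-6)
  }

  # shifting onset and response together leaves the implicit time alone
  rec2 <- simulate_flash_response(p, attenuation = 0,
                                  stimulus_onset = 150, latency_shift = 0)
  m2 <- compute_bwave_metrics(rec2)
  expect_equal(m2$implicit_time, m0$implicit_time, tolerance = 1e-6)
})

test_that("exactly the implicit times within 50-230 ms are flagged valid", {
  set.seed(13)
  starts <- runif(40, 10, 320)   # ramp onsets straddling both bounds
  for (s in starts) {
    rec <- ramp_recording(100 + s, 100 + s + 120)
    m <- compute_bwave_metrics(rec, search_window = c(100, 900))
    expect_equal(m$implicit_time, s, tolerance = 1e-6)
    expect_identical(m$valid,
                     m$implicit_time >= 50 && m$implicit_time <= 230)
    if (!m$valid) {
      expect_true(m$invalid_reason %in% c("below_filter", "above_filter"))
    }
  }
})
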