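test_that("power spectrum follows the one-sided sinusoid convention", {
  t <- seq(0, 1.999, by = 0.001)
  rec <- erg_recording(sin(2 * pi * 10 * t), 1000)
  sp <- power_spectrum(rec)
  expect_equal(attr(sp, "resolution_hz"), 0.5)
  expect_equal(sp$power_uV2[sp$frequency_hz == 10], 0.5,
               tolerance = 1e-12)
  expect_lt(max(sp$power_uV2[sp$frequency_hz != 10]), 1e-12)

  # constant trace: everything vanishes after mean detrending
  spc <- power_spectrum(erg_recording(rep(3.7, 2000), 1000))
  expect_lt(max(spc$power_uV2), 1e-24)

  expect_error(power_spectrum(rec, band_max = 600),
               class = "ergkit_error_bad_band")
})

test_that("power spectrum agrees bin-wise with a direct O(N^2) transform", {
  set.seed(5)
  for (n in c(1000, 1024, 999)) {
    v <- rnorm(n, 2, 4)
    rec <- erg_recording(v, 1000)
    sp <- power_spectrum(rec, band_max = Inf)
    x <- v - mean(v)
    k <- 0:(n %/% 2)
    direct <- vapply(k, function(kk) {
      X <- sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))
      p <- Mod(X)^2 / n^2
      if (kk > 0 && !(n %% 2 == 0 && kk == n %/% 2)) 2 * p else p
    }, numeric(1))
    expect_equal(sp$power_uV2, direct, tolerance = 1e-9)
    # Parseval under the one-sided convention
    expect_equal(sum(sp$power_uV2), mean(x^2), tolerance = 1e-9)
  }
})

test_that("resolvability criterion behaves at the trivial extremes", {
  t <- seq(0, 1.999, by = 0.001)
  sine <- erg_recording(sin(2 * pi * 12 * t), 1000)
  r <- is_resolvable(power_spectrum(sine), 12)
  expect_true(r$resolvable)
  expect_equal(r$power, 0.5, tolerance = 1e-9)

  zero <- erg_recording(rep(0, 2000), 1000)
  expect_false(is_resolvable(power_spectrum(zero), 12)$resolvable)

  expect_error(is_resolvable(power_spectrum(sine), 12.3),
               class = "ergkit_error_off_bin")
})

test_that("raising the periodic amplitude never makes a frequency unresolvable", {
  set.seed(9)
  noise <- rnorm(2000, 0, 5)
  t <- seq(0, 1.999, by = 0.001)
  flags <- vapply(c(0.05, 0.2, 1, 5, 25), function(a) {
    rec <- erg_recording(noise + a * sin(2 * pi * 15 * t), 1000)
    is_resolvable(power_spectrum(rec), 15)$resolvable
  }, logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("FFF determination covers censoring, sentinel and both rules", {
  # all resolvable up to the sweep top: censored at the maximum
  s_all <- simulate_flicker_series(fusion_model(cutoff_frequency = 60),
                                   max_freq = 40, noise_sd = 0.5, seed = 2)
  r_all <- compute_fff(s_all)
  expect_equal(r_all$fff, 40)
  expect_true(r_all$censored)

  # nothing resolvable: below-range sentinel
  s_none <- simulate_flicker_series(fusion_model(cutoff_frequency = 2),
                                    noise_sd = 1, seed = 2)
  r_none <- compute_fff(s_none)
  expect_true(is.na(r_none$fff))
  expect_false(r_none$censored)

  # hand-built sweep with an isolated spurious peak above fusion:
  # contiguity stops before the gap, the literal rule takes the top peak
  t <- seq(0, 1.999, by = 0.001)
  mk <- function(f, on) {
    set.seed(100 + f)
    v <- rnorm(2000, 0, 1) + if (on) 10 * sin(2 * pi * f * t) else 0
    r <- erg_recording(v, 1000)
    r$meta$stimulus_frequency <- f
    r
  }
  on <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  series <- flicker_series_from_recordings(
    mapply(mk, 7:12, on, SIMPLIFY = FALSE))
  r <- compute_fff(series)
  expect_equal(r$fff_contiguous, 9)
  expect_equal(r$fff_highest, 11)
  expect_equal(r$fff, 9)
  expect_equal(compute_fff(series, mode = "highest")$fff, 11)
})

test_that("recovered FFF is monotone in the simulated cutoff (noiseless)", {
  ffs <- vapply(c(10, 15, 20, 25, 30, 35), function(cut) {
    s <- simulate_flicker_series(fusion_model(cutoff_frequency = cut),
                                 noise_sd = 0.2, seed = 4)
    compute_fff(s)$fff
  }, numeric(1))
  expect_true(all(diff(ffs) >= 0))
})

test_that("WT-vs-WT FFF comparison is not anticonservative", {
  # small Monte-Carlo: two identically distributed groups of eyes, the
  # t-test on per-eye FFF should reject about nominally or less
  n_rep <- 30
  rejections <- vapply(seq_len(n_rep), function(r) {
    fff_vals <- vapply(1:8, function(e) {
      s <- simulate_flicker_series(
        fusion_model(cutoff_frequency = 25, response_gain = 18),
        start_freq = 20, max_freq = 30, noise_sd = 10,
        seed = child_seed(r, e))
      compute_fff(s)$fff
    }, numeric(1))
    p <- tryCatch(
      two_tailed_t_test(fff_vals[1:4], fff_vals[5:8])$p,
      ergkit_error_degenerate_variance = function(e) NA_real_)
    isTRUE(p < 0.05)
  }, logical(1))
  expect_lte(mean(rejections), 0.2)
})
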