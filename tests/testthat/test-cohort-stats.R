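test_that("the two-sample t-test matches hand computation", {
  same <- two_tailed_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # pooled variance 2.5, SE 1: t = -1, df = 8
  ht <- two_tailed_t_test(1:5, 2:6)
  expect_equal(ht$t, -1)
  expect_equal(ht$df, 8)
  expect_equal(ht$p, 2 * stats::pt(-1, 8), tolerance = 1e-12)
  expect_equal(round(ht$p, 4), 0.3466)

  expect_error(two_tailed_t_test(c(1, 1), c(2, 2)),
               class = "ergkit_error_degenerate_variance")
  expect_error(two_tailed_t_test(1, c(2, 3)),
               class = "ergkit_error_small_group")

  w <- two_tailed_t_test(1:5, c(2, 4, 6, 8, 10), variant = "welch")
  expect_lt(w$df, 8)  # Welch loses degrees of freedom here
})

test_that("swapping groups negates t and preserves p", {
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(6, 10, 2)
    b <- rnorm(8, 12, 3)
    for (v in c("student", "welch")) {
      ab <- two_tailed_t_test(a, b, v)
      ba <- two_tailed_t_test(b, a, v)
      expect_equal(ab$t, -ba$t, tolerance = 1e-12)
      expect_equal(ab$p, ba$p, tolerance = 1e-12)
      expect_equal(sign(ab$t), sign(ab$mean_a - ab$mean_b))
    }
  }
})

test_that("box summaries use Tukey hinges with whiskers at the extremes", {
  b <- box_whisker_summary(c(0, 1, 2, 3, 4))
  expect_equal(unlist(b[1, 1:5]), c(min = 0, q1 = 1, median = 2,
                                    q3 = 3, max = 4))
  expect_equal(unlist(box_whisker_summary(7)[1, 1:5]),
               c(min = 7, q1 = 7, median = 7, q3 = 7, max = 7))
  expect_error(box_whisker_summary(numeric(0)),
               class = "ergkit_error_empty")

  # independent sorted-halves hinge oracle
  median_of <- function(x) {
    x <- sort(x); n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else mean(x[n / 2 + 0:1])
  }
  set.seed(17)
  for (n in c(4, 5, 9, 12, 30)) {
    x <- round(rnorm(n, 50, 20), 3)
    s <- sort(x)
    half <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
    b <- box_whisker_summary(x)
    expect_equal(b$min, min(x))
    expect_equal(b$max, max(x))
    expect_equal(b$median, median_of(x))
    expect_equal(b$q1, median_of(s[1:half]))
    expect_equal(b$q3, median_of(s[(n - half + 1):n]))
  }

  # location/scale equivariance
  x <- c(3, 9, 1, 14, 6, 2)
  b0 <- box_whisker_summary(x)
  b1 <- box_whisker_summary(2.5 * x + 7)
  expect_equal(unlist(b1[1, 1:5]), 2.5 * unlist(b0[1, 1:5]) + 7)
})

test_that("noiseless cohort comparisons recover the programmed effects", {
  pr <- flash_protocol(attenuations = c(-1, 0))
  p0 <- waveform_params(noise_sd = 0)

  # whole-response scaling by 0.5: amplitude ratio exactly 0.5
  gt <- tibble::tibble(genotype = c("WT", "mut"),
                       scale_a = c(1, 0.5), scale_fast = c(1, 0.5),
                       scale_slow = c(1, 0.5), latency_shift = 0)
  co <- simulate_cohort(cohort_config(gt, 3, amplitude_cv = 0,
                                      latency_sd = 0), pr, p0)
  s <- summarize_cohort(bwave_metrics_table(co$recordings), "amplitude")
  expect_equal(s$mean_ratio, rep(0.5, 2), tolerance = 1e-12)

  # rigid latency shift of -20 ms with realistic noise, n = 10
  gt2 <- tibble::tibble(genotype = c("WT", "mut"), scale_a = 1,
                        scale_fast = 1, scale_slow = 1,
                        latency_shift = c(0, -20))
  co2 <- simulate_cohort(cohort_config(gt2, 10, master_seed = 8),
                         flash_protocol(attenuations = 0),
                         waveform_params())
  s2 <- summarize_cohort(bwave_metrics_table(co2$recordings),
                         "implicit_time")
  expect_equal(s2$mean_diff, -20, tolerance = 2)

  expect_error(summarize_cohort(bwave_metrics_table(co$recordings),
                                "amplitude", reference = "missing"),
               class = "ergkit_error_missing_reference")
})

test_that("detection power increases with the amplitude effect size", {
  pr <- flash_protocol(attenuations = 0)
  rates <- vapply(c(1, 0.8, 0.6), function(sc) {
    gt <- tibble::tibble(genotype = c("WT", "mut"), scale_a = sc,
                         scale_fast = sc, scale_slow = sc,
                         latency_shift = 0)
    gt$scale_a[1] <- gt$scale_fast[1] <- gt$scale_slow[1] <- 1
    mean(vapply(1:60, function(r) {
      co <- simulate_cohort(cohort_config(gt, 8, master_seed =
                                            child_seed(900, r)), pr)
      s <- summarize_cohort(bwave_metrics_table(co$recordings),
                            "amplitude")
      isTRUE(s$p < 0.05)
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_lt(rates[1], 0.15)   # near-nominal at zero effect
  expect_gt(rates[3], 0.8)    # strong effect almost always detected
})

test_that("per-cell box summaries and exclusion counts are reported", {
  pr <- flash_protocol(attenuations = c(-1, 0))
  gt <- genotype_effects()[1:2, ]
  co <- simulate_cohort(cohort_config(gt, 4, master_seed = 3), pr)
  mt <- bwave_metrics_table(co$recordings)
  bx <- cohort_box_summaries(mt, "amplitude")
  expect_equal(nrow(bx), 4)  # 2 genotypes x 2 intensities
  expect_true(all(bx$min <= bx$q1 & bx$q1 <= bx$median &
                    bx$median <= bx$q3 & bx$q3 <= bx$max))
  s <- summarize_cohort(mt, "implicit_time")
  expect_true(all(s$n + s$excluded == 4))
})
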