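test_that("trapezoidal AUC matches closed forms and is additive", {
  fs <- 600
  expect_equal(compute_auc(rep(0, 100), fs), 0)
  ## constant |f| = c over (b - a) seconds -> c (b - a)
  expect_equal(compute_auc(rep(3, 601), fs), 3 * 1, tolerance = 1e-12)
  ## one period of a 10 Hz unit sine: integral of |sin| = 2 / (10 pi)
  t <- seq(0, 0.1, by = 1 / fs)
  expect_equal(compute_auc(sin(2 * pi * 10 * t), fs), 2 / (10 * pi),
               tolerance = 0.01)
  ## concatenation additivity within one trapezoid panel
  x <- stats::rnorm(301)
  expect_equal(compute_auc(x, fs),
               compute_auc(x[1:101], fs) + compute_auc(x[101:301], fs),
               tolerance = 1e-12)
  ## linear amplitude scaling
  expect_equal(compute_auc(5 * x, fs), 5 * compute_auc(x, fs),
               tolerance = 1e-12)
  expect_error(compute_auc(1, fs), "2 samples")
})

test_that("waveform features recover an analytic tone", {
  fs <- 600
  n_cyc <- 50
  t <- (1:(n_cyc * 12)) / fs                # 50 Hz tone, integer cycles
  x <- sin(2 * pi * 50 * t)
  f <- waveform_features(x, fs)
  expect_equal(f$amplitude, 1, tolerance = 0.05)
  expect_equal(f$mean_freq_hz, 50, tolerance = 1)
  expect_equal(f$power, 0.5, tolerance = 1e-6)
  expect_lte(abs(f$n_peaks - n_cyc), 1)
  ## constant trace
  fc <- waveform_features(rep(2, 100), fs)
  expect_equal(fc$power, 4)
  expect_equal(fc$n_peaks, 0L)
  ## equal-amplitude 100 + 200 Hz mix: first moment at 150 Hz
  t2 <- (1:1200) / fs
  fm <- waveform_features(sin(2 * pi * 100 * t2) + sin(2 * pi * 200 * t2),
                          fs)
  expect_equal(fm$mean_freq_hz, 150, tolerance = 2)
})

test_that("wavelet sharp-wave frequency is the power-weighted mean", {
  fs <- 600
  t <- (0:(10 * fs - 1)) / fs
  expect_equal(sw_frequency(sin(2 * pi * 8 * t), fs, 5, 4.7, 5.3), 8,
               tolerance = 2)
  ## equal power at 5 and 15 Hz averages to ~10 Hz
  mix <- sin(2 * pi * 5 * t) + sin(2 * pi * 15 * t)
  expect_equal(sw_frequency(mix, fs, 5, 4.7, 5.3), 10, tolerance = 2)
  z <- sw_frequency(rep(0, 10 * fs), fs, 5, 4.9, 5.1)
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_error(sw_frequency(rep(0, 100), fs, 50, 49, 51), "outside")
})

test_that("log-log fits recover exact and noisy power laws", {
  x <- seq(1, 100, length.out = 50)
  f1 <- loglog_fit(x, x)
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$intercept, 0, tolerance = 1e-12)
  expect_equal(f1$r, 1, tolerance = 1e-12)
  f2 <- loglog_fit(x, 10 * x^2)
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 1, tolerance = 1e-12)
  set.seed(2)
  xs <- stats::runif(500, 1, 1000)
  ys <- 3 * xs^1.5 * 10^stats::rnorm(500, 0, 0.1)
  f3 <- loglog_fit(xs, ys)
  expect_equal(f3$slope, 1.5, tolerance = 0.05)
  ## zeros dropped with count
  f4 <- loglog_fit(c(x, 0), c(x, 5))
  expect_equal(f4$n_dropped, 1)
  expect_error(loglog_fit(c(1, 2), c(1, 2)), "fewer than 3")
})

test_that("Fisher z-comparison of correlations behaves analytically", {
  same <- compare_correlation_slopes(0.7, 50, 0.7, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- compare_correlation_slopes(0.9, 100, 0.5, 100)
  expect_equal(ab$z, (atanh(0.9) - atanh(0.5)) / sqrt(2 / 97),
               tolerance = 1e-12)
  expect_equal(ab$z, 6.4, tolerance = 0.1)
  ba <- compare_correlation_slopes(0.5, 100, 0.9, 100)
  expect_equal(ba$z, -ab$z)
  expect_error(compare_correlation_slopes(1, 10, 0.5, 10), "< 1")
})

test_that("median-amplitude selection keeps the closest events", {
  ev <- data.frame(amplitude = c(1, 2, 3, 4, 100), peak_s = 1:5)
  sel <- select_median_events(ev, 3)
  expect_setequal(sel$amplitude, c(2, 3, 4))
  expect_equal(nrow(select_median_events(ev, 10)), 5)
  ## ties broken by earlier peak time
  tie <- data.frame(amplitude = rep(7, 5), peak_s = c(5, 1, 4, 2, 3))
  expect_setequal(select_median_events(tie, 2)$peak_s, c(1, 2))
  expect_equal(nrow(select_median_events(ev[0, ], 3)), 0)
})

test_that("density contours enclose equal mass fractions", {
  set.seed(3)
  x <- stats::rnorm(2000); y <- stats::rnorm(2000)
  dc <- density_contours(x, y, n_levels = 3)
  cell <- diff(dc$x[1:2]) * diff(dc$y[1:2])
  for (i in 1:3) {
    mass <- sum(dc$z[dc$z >= dc$levels[i]]) * cell
    expect_equal(mass, i / 3, tolerance = 0.05)
  }
  ## single level encloses (essentially) all mass
  d1 <- density_contours(x, y, n_levels = 1)
  expect_equal(sum(d1$z[d1$z >= d1$levels[1]]) * cell, 1, tolerance = 0.05)
  expect_error(density_contours(x, 2 * x, 3), "degenerate")
})

test_that("feature windows follow the ripple for compound events", {
  sim <- fixture_sim(duration_s = 600, seed = 7)
  rec <- sim$recording
  hyp <- gt_hypnogram(sim, 600)
  det <- detect_events(rec, hyp)
  ev <- det$events[det$events$state == "NREM_like", ]
  ft <- event_feature_table(ev, det$sp_filtered, det$sr_filtered, rec$fs_hz,
                            sw_freq = FALSE)
  expect_equal(nrow(ft), nrow(ev))
  expect_equal(ft$duration_ms,
               (ev$end_s - ev$start_s)[match(ft$event_id, ev$event_id)] * 1000)
  ## compound events: radiatum AUC grows with the number of sharp waves
  expect_gt(mean(ft$sr_auc[ft$type == "cSWR"]),
            mean(ft$sr_auc[ft$type == "R"]))
  expect_true(all(ft$sp_auc >= 0 & ft$sr_auc >= 0))
})
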