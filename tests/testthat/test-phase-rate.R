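test_that("slow-oscillation phase follows the cosine convention", {
  fs <- 600
  dur <- 120
  t <- (0:(dur * fs - 1)) / fs
  x <- cos(2 * pi * 1 * t)
  hyp <- hypnogram(rep("NREM_like", dur / 10), epoch_s = 10)
  ph <- compute_so_phase(x, fs, hyp)
  core <- t > 5 & t < dur - 5
  ## peaks at integer seconds -> 0 deg; troughs -> 180; ascending zero
  ## crossings (t = k + 0.75) -> 270
  at <- function(sec) ph[round(sec * fs) + 1]
  for (k in c(10, 20, 50)) {
    expect_lt(min(abs(at(k) - c(0, 360))), 2)
    expect_lt(abs(at(k + 0.5) - 180), 2)
    expect_lt(abs(at(k + 0.75) - 270), 5)
  }
  ## monotonically increasing modulo 360 for a pure tone
  d <- diff(ph[core]) %% 360
  expect_true(all(d[d < 350] >= 0))
  ## cumulative phase advances 360 deg per period
  expect_equal(sum(diff(ph[core]) %% 360), 360 * 1 * (sum(core) - 1) / fs,
               tolerance = 1)
  ## REM samples carry no phase
  hyp2 <- hypnogram(rep(c("NREM_like", "REM_like"), each = 6), epoch_s = 10)
  ph2 <- compute_so_phase(x, fs, hyp2)
  expect_true(all(is.na(ph2[t >= 70 & t < 110])))
  expect_error(compute_so_phase(x, fs,
                                hypnogram(rep("REM_like", 12), 10)),
               "NonREM")
})

test_that("event phase statistics summarize circular structure", {
  fs <- 600
  ph <- rep(180, fs * 100)
  ev <- data.frame(event_id = 1:20, type = "SWR",
                   peak_s = seq(5, 90, length.out = 20))
  st <- event_phase_stats(ev, ph, fs)
  expect_equal(st$summary$mean_deg, 180, tolerance = 1e-6)
  expect_equal(st$summary$resultant, 1, tolerance = 1e-9)
  ## uniform phases: resultant near zero
  set.seed(11)
  ph_u <- stats::runif(fs * 100, 0, 360)
  st_u <- event_phase_stats(data.frame(event_id = 1:500, type = "R",
                                       peak_s = stats::runif(500, 1, 99)),
                            ph_u, fs)
  expect_lt(st_u$summary$resultant, 0.15)
  ## events outside the phase vector are excluded with a count
  st_o <- event_phase_stats(data.frame(event_id = 1:2, type = "R",
                                       peak_s = c(5, 150)), ph, fs)
  expect_equal(st_o$n_excluded, 1)
})

test_that("injected event phases are recovered per type", {
  sim <- fixture_sim(duration_s = 1200, seed = 2)
  rec <- sim$recording
  fs <- rec$fs_hz
  hyp <- gt_hypnogram(sim, 1200)
  det <- detect_events(rec, hyp)
  ev <- det$events[det$events$state == "NREM_like", ]
  ph <- compute_so_phase(
    rec$samples[swrlamina:::layer_channel(rec, "PFC_shallow"), ], fs, hyp)
  st <- event_phase_stats(ev, ph, fs)
  target <- c(R = 0, SW = 270, SWR = 270, cSWR = 270)
  for (ty in intersect(names(target), st$summary$type)) {
    got <- st$summary$mean_deg[st$summary$type == ty]
    err <- abs(((got - target[[ty]] + 180) %% 360) - 180)
    expect_lt(err, 20)
    expect_gt(st$summary$resultant[st$summary$type == ty], 0.8)
  }
})

test_that("delta-wave detector honors thresholds and duration bounds", {
  fs <- 600
  dw0 <- detect_delta_waves(rep(0, fs * 60), fs)
  expect_equal(nrow(dw0$waves), 0)
  set.seed(12)
  t <- (0:(fs * 120 - 1)) / fs
  base <- generate_noise(length(t), fs, 1, 3)
  ## one biphasic 3 Hz wave (positive peak then trough), ~333 ms
  wave <- 60 * sin(2 * pi * 3 * (t - 60)) * (t >= 60 & t < 60 + 1 / 3)
  dw <- detect_delta_waves(base + wave, fs)
  hit <- dw$waves[abs(dw$waves$peak_s - 60.08) < 0.2, ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$peak_s < hit$trough_s)
  expect_true(hit$duration_ms >= 150 && hit$duration_ms <= 550)
  ## a 700 ms wave is rejected by the duration bound
  slow <- 60 * sin(2 * pi * (1 / 0.7) * (t - 30)) * (t >= 30 & t < 30.7)
  dw_slow <- detect_delta_waves(base + slow, fs)
  expect_equal(nrow(dw_slow$waves[abs(dw_slow$waves$peak_s - 30.2) < 0.3, ]),
               0)
  ## count never increases when thresholds rise
  x <- base + wave
  n1 <- nrow(detect_delta_waves(x, fs, peak_threshold_sd = 1.5)$waves)
  n2 <- nrow(detect_delta_waves(x, fs, peak_threshold_sd = 3)$waves)
  expect_lte(n2, n1)
  expect_error(detect_delta_waves(x, fs, peak_threshold_uv = -1,
                                  trough_threshold_uv = -10), "degenerate")
})

test_that("bout-edge ripple rates use only long bouts and 10% segments", {
  ## 10-min bout excluded, 20-min bout kept
  labs <- c(rep("NREM_like", 60), rep("REM_like", 6),
            rep("NREM_like", 120), rep("REM_like", 6))
  hyp <- hypnogram(labs, epoch_s = 10)
  ## bout 2: [660, 1860); edges are 120 s each
  ev <- data.frame(event_id = 1:13, type = "R",
                   peak_s = c(seq(665, 770, length.out = 12), 1800))
  r <- bout_edge_ripple_rate(ev, hyp, min_bout_min = 15, edge_frac = 0.10)
  expect_equal(nrow(r), 1)
  expect_equal(r$start_rate_hz, 12 / 120)
  expect_equal(r$end_rate_hz, 1 / 120)
  ## homogeneous Poisson events: start and end rates agree on average
  set.seed(13)
  labs2 <- rep("NREM_like", 360)                 # one 60-min bout
  hyp2 <- hypnogram(labs2, epoch_s = 10)
  lam <- 0.5
  peaks <- cumsum(stats::rexp(4000, lam))
  peaks <- peaks[peaks < 3600]
  r2 <- bout_edge_ripple_rate(data.frame(event_id = seq_along(peaks),
                                         type = "SWR", peak_s = peaks),
                              hyp2)
  expect_equal(r2$start_rate_hz, lam, tolerance = 0.15)
  expect_equal(r2$end_rate_hz, lam, tolerance = 0.15)
})

test_that("long/short ratio counts ripple-bearing events around the cutoff", {
  mk <- function(n_long, n_short) {
    data.frame(event_id = seq_len(n_long + n_short), type = "R",
               start_s = 0,
               peak_s = 0.05,
               end_s = c(rep(0.15, n_long), rep(0.08, n_short)))
  }
  expect_equal(long_short_ratio(mk(30, 60))$ratio, 0.5)
  expect_equal(long_short_ratio(mk(10, 10))$ratio, 1)
  all_long <- long_short_ratio(mk(10, 0))
  expect_true(is.na(all_long$ratio))
  expect_false(all_long$defined)
  ## SW events are not ripples and never enter the ratio
  ev <- mk(5, 5)
  ev$type[1:5] <- "SW"
  expect_equal(long_short_ratio(ev)$n_long, 0)
})
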