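test_that("background noise has the requested RMS and spectral slope", {
  ## exact per-realization RMS normalization
  x <- generate_noise(60000, 600, beta = 2, rms_uv = 30, seed = 1)
  expect_equal(sqrt(mean(x^2)), 30, tolerance = 1e-12)
  expect_identical(generate_noise(100, 600, 2, 0), numeric(100))
  ## doubling rms doubles the trace exactly (same seed)
  x2 <- generate_noise(60000, 600, beta = 2, rms_uv = 60, seed = 1)
  expect_equal(x2, 2 * x, tolerance = 1e-12)
  ## log-log periodogram slope ~ -beta (binned fit, averaged over seeds)
  slope_of <- function(beta, seed) {
    y <- generate_noise(36000, 600, beta, 30, seed = seed)
    n <- length(y)
    P <- Mod(stats::fft(y)[2:(n / 2)])^2
    f <- (1:(n / 2 - 1)) * 600 / n
    keep <- f >= 1 & f <= 200
    lb <- cut(log10(f[keep]), 40)
    lp <- tapply(log10(P[keep]), lb, mean)
    lf <- tapply(log10(f[keep]), lb, mean)
    unname(stats::coef(stats::lm(lp ~ lf))[2])
  }
  for (beta in c(0, 2)) {
    slopes <- vapply(1:6, function(s) slope_of(beta, s), 0)
    expect_lt(abs(mean(slopes) + beta), 0.15)
  }
  expect_error(generate_noise(0, 600), "positive")
  expect_error(generate_noise(100, 600, rms_uv = -1), "non-negative")
})

test_that("event templates obey the layer/gain contract", {
  p <- swrlamina:::template_params(600)
  layer <- p$layer_map
  ## SW with zero radiatum gain is an all-zero snippet (no SLM component)
  sw0 <- generate_event_templates("SW", 600, sr_input_gain = 0, 1, p)
  expect_true(all(sw0$snippet == 0))
  ## cSWR annotates >= 2 radiatum components under one pyramidale burst
  cs <- generate_event_templates("cSWR", 600, 1, 1, p)
  expect_gte(sum(cs$components$component == "sr_sharp_wave"), 2)
  expect_equal(sum(cs$components$component == "sp_burst"), 1)
  ## doubling sr gain doubles the SR trough (up to sub-1e-3 leakage of the
  ## other components' depth-profile tails), leaves the SP burst unchanged
  s0 <- generate_event_templates("SWR", 600, 0, 1, p)
  s1 <- generate_event_templates("SWR", 600, 1, 1, p)
  s2 <- generate_event_templates("SWR", 600, 2, 1, p)
  sr_ch <- which(layer == "SR")[4]
  sp_ch <- which(layer == "SP")[2]
  expect_equal(min(s2$snippet[sr_ch, ]), 2 * min(s1$snippet[sr_ch, ]),
               tolerance = 1e-3)
  expect_equal(s2$snippet[sp_ch, ], s1$snippet[sp_ch, ], tolerance = 1e-3)
  ## exact linearity of the radiatum component itself
  expect_equal(s2$snippet - s1$snippet, s1$snippet - s0$snippet,
               tolerance = 1e-12)
  ## PFC rows stay silent
  expect_true(all(s1$snippet[layer %in% c("PFC_shallow", "PFC_deep"), ] == 0))
  expect_error(generate_event_templates("XX", 600), "unknown")
})

test_that("recordings are reproducible and events respect the schedule", {
  sim1 <- fixture_sim(duration_s = 600, seed = 7)
  sim2 <- generate_recording(sim_config(duration_s = 600, seed = 7))
  expect_identical(sim1$recording$samples, sim2$recording$samples)
  expect_identical(sim1$ground_truth$events, sim2$ground_truth$events)

  gt <- sim1$ground_truth
  expect_false(is.unsorted(gt$events$start_s))
  ## every event interval lies inside a NonREM-like bout
  sch <- gt$state_schedule
  nrem <- sch[sch$state == "NREM_like", ]
  inside <- vapply(seq_len(nrow(gt$events)), function(i) {
    any(gt$events$start_s[i] >= nrem$start_s &
          gt$events$end_s[i] <= nrem$end_s)
  }, TRUE)
  expect_true(all(inside))
  ## component-count invariants per type
  with(gt$events, {
    expect_true(all(n_sw_components[type == "R"] == 0))
    expect_true(all(n_sw_components[type %in% c("SW", "SWR")] == 1))
    expect_true(all(n_sw_components[type == "cSWR"] >= 2))
  })
})

test_that("zero rates give no events; counts stay in the Poisson band", {
  sim0 <- generate_recording(sim_config(
    duration_s = 300, seed = 1,
    event_rates = c(R = 0, SW = 0, SWR = 0, cSWR = 0)))
  expect_equal(nrow(sim0$ground_truth$events), 0)

  sim <- fixture_sim(duration_s = 1800, seed = 7)
  sch <- sim$ground_truth$state_schedule
  nrem_min <- sum(sch$end_s[sch$state == "NREM_like"] -
                    sch$start_s[sch$state == "NREM_like"]) / 60
  rates <- c(R = 2, SW = 2, SWR = 3, cSWR = 1)
  for (ty in names(rates)) {
    lam <- rates[[ty]] * nrem_min
    n <- sum(sim$ground_truth$events$type == ty)
    expect_gte(n, stats::qpois(0.005, lam))
    expect_lte(n, stats::qpois(0.995, lam))
  }
})

test_that("radiatum gain rescales components without moving event times", {
  a <- generate_recording(sim_config(duration_s = 400, seed = 5))
  b <- generate_recording(sim_config(duration_s = 400, seed = 5,
                                     sr_input_gain = 0.6,
                                     couple_ripple_duration = FALSE))
  expect_identical(a$ground_truth$events$peak_s, b$ground_truth$events$peak_s)
  ## difference is exactly the 40% of the radiatum components: restricted to
  ## SR-profile channels, zero on the PFC rows
  d <- a$recording$samples - b$recording$samples
  pfc <- a$recording$layer_map %in% c("PFC_shallow", "PFC_deep")
  expect_true(all(d[pfc, ] == 0))
  ## with gain 0 the full radiatum component drops out; the 0.6-gain
  ## difference must be exactly 0.4 of it (linear gain)
  c0 <- generate_recording(sim_config(duration_s = 400, seed = 5,
                                      sr_input_gain = 0,
                                      couple_ripple_duration = FALSE))
  full <- a$recording$samples - c0$recording$samples
  expect_equal(d, 0.4 * full, tolerance = 1e-10)
  expect_gt(max(abs(full)), 0)
})

test_that("artifact injection is recorded and avoids events", {
  sim <- generate_recording(sim_config(duration_s = 400, seed = 9,
                                       n_artifacts = 3))
  gt <- sim$ground_truth
  expect_equal(length(gt$artifact_times), 3)
  for (ta in gt$artifact_times) {
    expect_true(all(abs(gt$events$peak_s - ta) > 1))
  }
})
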