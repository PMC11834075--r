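test_that("threshold estimation is mean + k SD of the magnitude", {
  set.seed(1)
  m <- stats::rnorm(1e6)
  lv <- estimate_threshold(m, threshold_sd = 5)
  expect_equal(lv$detect_level, 5, tolerance = 0.05)
  expect_equal(lv$boundary_level, lv$detect_level / 2)
  expect_equal(estimate_threshold(m, threshold_sd = 0)$detect_level,
               mean(m), tolerance = 1e-12)
  expect_error(estimate_threshold(rep(2, 100)), "zero-variance")
})

test_that("ripple detector finds an injected burst with oracle edges", {
  fs <- 600
  set.seed(4)
  n <- fs * 120
  noise <- bandpass_filter(generate_noise(n, fs, 1, 1), fs, c(90, 200))
  t <- (0:(n - 1)) / fs
  env0 <- 10 * stats::sd(noise) *
    exp(-(t - 60)^2 / (2 * (0.12 / 2.355)^2))     # 120 ms FWHM burst at 60 s
  x <- noise + env0 * sin(2 * pi * 150 * t)
  expect_equal(nrow(detect_ripples(rep(0, 600), fs)), 0)
  ev <- detect_ripples(x, fs)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$peak_s - 60), 0.02)
  ## oracle: walk outward from the peak to the contiguous half-threshold
  ## crossings of the envelope magnitude
  mag <- Mod(analytic_signal(x))
  lv <- estimate_threshold(mag)
  i <- which.max(mag * (abs(t - 60) < 0.3))
  a <- i; while (a > 1 && mag[a - 1] >= lv$boundary_level) a <- a - 1
  b <- i; while (b < length(mag) && mag[b + 1] >= lv$boundary_level) b <- b + 1
  expect_lt(abs(ev$start_s - t[a]), 0.010)
  expect_lt(abs(ev$end_s - t[b]), 0.010)
})

test_that("the 80 ms closeness rule merges nearby bursts", {
  fs <- 600
  set.seed(5)
  base <- bandpass_filter(generate_noise(fs * 60, fs, 1, 1), fs, c(90, 200))
  s <- stats::sd(base)
  t <- (0:(fs * 60 - 1)) / fs
  burst <- function(at, dur = 0.06) {
    10 * s * exp(-(t - at)^2 / (2 * (dur / 2.355)^2)) * sin(2 * pi * 150 * t)
  }
  two_close <- base + burst(30) + burst(30.12)       # ~60 ms gap
  two_far <- base + burst(30) + burst(30.30)         # ~180+ ms gap
  expect_equal(nrow(detect_ripples(two_close, fs)), 1)
  expect_equal(nrow(detect_ripples(two_far, fs)), 2)
})

test_that("raising the threshold never increases the ripple count", {
  sim <- fixture_sim(duration_s = 600, seed = 7)
  rec <- sim$recording
  sp <- bandpass_filter(rec$samples[swrlamina:::layer_channel(rec, "SP"), ],
                        rec$fs_hz, c(90, 200))
  counts <- vapply(c(3, 5, 7, 9), function(k) {
    nrow(detect_ripples(sp, rec$fs_hz, detection_params(threshold_sd = k)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("sharp-wave detector keeps only troughs below the threshold", {
  fs <- 600
  expect_equal(nrow(detect_sharp_waves(rep(0, 600), fs)), 0)
  set.seed(6)
  x <- bandpass_filter(generate_noise(fs * 120, fs, 1, 1), fs, c(2, 20))
  s <- stats::sd(x)
  t <- (0:(fs * 120 - 1)) / fs
  bump <- 8 * s * swrlamina:::hann_bump(t, 60, 0.07)
  sws <- detect_sharp_waves(x - bump, fs)
  hit <- which(abs(sws$peak_s - 60) < 0.05)
  expect_equal(length(hit), 1)
  ## peak is the sample of the minimum
  i <- which.min(x - bump)
  expect_equal(sws$peak_s[hit], (i - 1) / fs, tolerance = 1e-9)
  ## purely positive deflection of the same size: no detection there
  sws_pos <- detect_sharp_waves(x + bump, fs)
  expect_false(any(abs(sws_pos$peak_s - 60) < 0.2))
})

test_that("overlap classification matches the paper's endpoint cases", {
  ## ripple with no sharp waves -> R
  r <- data.frame(start_s = 0, peak_s = 0.05, end_s = 0.1)
  none <- data.frame(start_s = numeric(), peak_s = numeric(),
                     end_s = numeric())
  ev <- classify_events(r, none)
  expect_equal(ev$type, "R")
  ## two sharp waves inside the ripple -> cSWR with 2 overlaps
  sw2 <- data.frame(start_s = c(0.01, 0.05), peak_s = c(0.02, 0.07),
                    end_s = c(0.04, 0.09))
  ev2 <- classify_events(r, sw2)
  expect_equal(ev2$type[1], "cSWR")
  expect_equal(ev2$n_sw_overlaps[1], 2L)
  expect_equal(nrow(ev2), 1)                 # both SWs absorbed
  ## sharp wave strictly containing the ripple: literal rule sees NO overlap
  big <- data.frame(start_s = -0.05, peak_s = 0.05, end_s = 0.15)
  lit <- classify_events(r, big)
  expect_setequal(lit$type, c("R", "SW"))
  ## ... but the intersection mode classifies it as an overlap
  its <- classify_events(r, big, rule = "intersect")
  expect_equal(its$type, "SWR")
})

test_that("every detection lands in exactly one class (random stress)", {
  set.seed(9)
  for (rep in 1:20) {
    nr <- sample(0:6, 1); ns <- sample(0:6, 1)
    mk <- function(k) {
      s <- sort(stats::runif(2 * k, 0, 10))
      if (k == 0) return(data.frame(start_s = numeric(), peak_s = numeric(),
                                    end_s = numeric()))
      data.frame(start_s = s[seq(1, 2 * k, 2)],
                 peak_s = (s[seq(1, 2 * k, 2)] + s[seq(2, 2 * k, 2)]) / 2,
                 end_s = s[seq(2, 2 * k, 2)])
    }
    rips <- mk(nr); sws <- mk(ns)
    ev <- classify_events(rips, sws)
    expect_equal(sum(ev$type %in% c("R", "SWR", "cSWR")), nrow(rips))
    ## each classified ripple's overlap count equals the brute-force oracle
    rip_ev <- ev[ev$type %in% c("R", "SWR", "cSWR"), ]
    for (i in seq_len(nrow(rip_ev))) {
      expect_equal(rip_ev$n_sw_overlaps[i],
                   oracle_overlap_count(rip_ev$start_s[i], rip_ev$end_s[i],
                                        sws$start_s, sws$end_s))
    }
    ## standalone SWs are exactly those the oracle attaches to no ripple
    used <- vapply(seq_len(nrow(sws)), function(k) {
      any((sws$end_s[k] >= rip_ev$start_s & sws$end_s[k] <= rip_ev$end_s) |
            (sws$start_s[k] >= rip_ev$start_s &
               sws$start_s[k] <= rip_ev$end_s))
    }, TRUE)
    expect_equal(sum(ev$type == "SW"), sum(!used))
  }
})

test_that("state and bin annotations are attached to events", {
  hyp <- hypnogram(rep(c("NREM_like", "REM_like"), each = 30), epoch_s = 10)
  r <- data.frame(start_s = c(10, 400), peak_s = c(10.1, 400.1),
                  end_s = c(10.2, 400.2))
  none <- data.frame(start_s = numeric(), peak_s = numeric(),
                     end_s = numeric())
  ev <- classify_events(r, none, hyp, bin_fn = function(t) floor(t / 120))
  expect_equal(ev$state, c("NREM_like", "REM_like"))
  expect_equal(ev$bin_index, c(0, 3))
})
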