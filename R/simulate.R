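## Synthetic laminar-LFP generator: seeded recordings with ground-truth event
## annotations, a NonREM-like/REM-like state schedule, and layer-specific
## input gains emulating CA3 (stratum radiatum) vs mEC (SLM) drive.

EVENT_TYPES <- c("R", "SW", "SWR", "cSWR")

#' Simulation configuration
#'
#' Defaults describe a vehicle-like 30-min urethane recording: 32 laminar CA1
#' channels at 50 um spacing plus two prefrontal channels, 1/f^2 background at
#' 30 uV RMS, NonREM-like bouts carrying a 0.5-1 Hz cortical slow oscillation
#' and REM-like bouts carrying 3.5-5.5 Hz theta. Hippocampal events are
#' injected only during NonREM-like bouts, phase-locked to the slow
#' oscillation (ripples at the upstate peak, sharp-wave-bearing types at the
#' down-to-up transition). Event amplitudes are set as multiples of the
#' background SD in the respective detection band (`ripple_snr`, `sw_snr`);
#' `sr_input_gain < 1` scales down every stratum-radiatum component
#' ("CBD-like"), `slm_input_gain` scales the SLM components.
#'
#' @param duration_s recording length, seconds.
#' @param fs_hz sampling rate, Hz.
#' @param n_channels number of hippocampal laminar channels.
#' @param channel_spacing_um inter-channel spacing, um.
#' @param noise_beta exponent of the 1/f^beta background.
#' @param noise_rms_uv background RMS per channel, uV.
#' @param event_rates named per-type event rates, events/min of NonREM-like.
#' @param sr_input_gain multiplier on stratum-radiatum event components.
#' @param slm_input_gain multiplier on SLM event components.
#' @param ripple_snr ripple envelope peak, in units of 90-200 Hz background SD.
#' @param sw_snr sharp-wave trough depth, in units of 2-20 Hz background SD.
#' @param state_bout_s named mean bout durations, seconds (`nrem`, `rem`).
#' @param so_amp_uv slow-oscillation amplitude on the shallow PFC channel, uV.
#' @param theta_amp_uv REM-like theta amplitude on hippocampal channels, uV.
#' @param event_phase_deg named per-type injection phase of the slow
#'   oscillation (cosine convention: upstate peak = 0, trough = 180).
#' @param couple_ripple_duration when TRUE, ripple burst durations scale with
#'   `sr_input_gain` (radiatum drive sustains long ripples).
#' @param allow_rem_events place events in REM-like bouts too (negative tests).
#' @param epoch_s scoring epoch length; bout edges snap to this grid.
#' @param n_artifacts number of large square artifacts to inject.
#' @param seed RNG seed; fixes every output bit.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 1800, fs_hz = 600, n_channels = 32,
                       channel_spacing_um = 50, noise_beta = 2,
                       noise_rms_uv = 30,
                       event_rates = c(R = 2, SW = 2, SWR = 3, cSWR = 1),
                       sr_input_gain = 1, slm_input_gain = 1,
                       ripple_snr = 12, sw_snr = 9,
                       state_bout_s = c(nrem = 240, rem = 120),
                       so_amp_uv = 120, theta_amp_uv = 60,
                       state_noise_gain = c(nrem = 1.3, rem = 0.75),
                       noise_space_sigma_um = 250,
                       event_phase_deg = c(R = 0, SW = 270, SWR = 270,
                                           cSWR = 270),
                       couple_ripple_duration = TRUE,
                       allow_rem_events = FALSE,
                       epoch_s = 10, n_artifacts = 0, seed = 1) {
  stopifnot(duration_s > 0, fs_hz > 400, n_channels >= 8,
            channel_spacing_um > 0, noise_beta >= 0, noise_rms_uv >= 0,
            sr_input_gain >= 0, slm_input_gain >= 0,
            all(event_rates >= 0), all(state_bout_s > 0))
  if (!all(EVENT_TYPES %in% names(event_rates))) {
    stop("event_rates must be named with R, SW, SWR, cSWR")
  }
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 n_channels = n_channels,
                 channel_spacing_um = channel_spacing_um,
                 noise_beta = noise_beta, noise_rms_uv = noise_rms_uv,
                 event_rates = event_rates[EVENT_TYPES],
                 sr_input_gain = sr_input_gain,
                 slm_input_gain = slm_input_gain,
                 ripple_snr = ripple_snr, sw_snr = sw_snr,
                 state_bout_s = state_bout_s,
                 so_amp_uv = so_amp_uv, theta_amp_uv = theta_amp_uv,
                 state_noise_gain = state_noise_gain,
                 noise_space_sigma_um = noise_space_sigma_um,
                 event_phase_deg = event_phase_deg[EVENT_TYPES],
                 couple_ripple_duration = couple_ripple_duration,
                 allow_rem_events = allow_rem_events,
                 epoch_s = epoch_s, n_artifacts = n_artifacts,
                 seed = seed),
            class = "sim_config")
}

#' Default laminar layer assignment
#'
#' Shallow-to-deep CA1 layers on an `n_channels`-site single-shank probe, plus
#' two prefrontal channels appended at the end.
#'
#' @param n_channels hippocampal channel count.
#' @return character vector of length `n_channels + 2` with levels
#'   SO/SP/SR/SLM/other/PFC_shallow/PFC_deep.
#' @export
default_layer_map <- function(n_channels = 32) {
  stopifnot(n_channels >= 8)
  frac <- (seq_len(n_channels) - 0.5) / n_channels
  hpc <- ifelse(frac < 0.16, "SO",
         ifelse(frac < 0.28, "SP",
         ifelse(frac < 0.53, "SR",
         ifelse(frac < 0.78, "SLM", "other"))))
  c(hpc, "PFC_shallow", "PFC_deep")
}

#' Generate 1/f^beta background noise
#'
#' Frequency-domain shaping: a white complex spectrum is multiplied by
#' f^(-beta/2) and inverted, giving exact slope control; the trace is then
#' rescaled to the requested RMS. Below `f_lo_hz` the spectrum is flat,
#' mimicking the AC-coupling corner of extracellular amplifiers (without it,
#' a steep 1/f^beta puts most of the variance into a per-channel random
#' drift over any long recording).
#'
#' @param n_samples trace length.
#' @param fs_hz sampling rate, Hz.
#' @param beta spectral exponent (power ~ f^-beta); 0 = white.
#' @param rms_uv target RMS amplitude, uV.
#' @param seed optional RNG seed.
#' @param f_lo_hz low-frequency shaping corner, Hz.
#' @return numeric vector of length `n_samples`.
#' @export
generate_noise <- function(n_samples, fs_hz, beta = 2, rms_uv = 30,
                           seed = NULL, f_lo_hz = 0.1) {
  if (n_samples <= 0) stop("n_samples must be positive")
  if (rms_uv < 0) stop("rms_uv must be non-negative")
  if (beta < 0) stop("beta must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_samples)
  if (rms_uv == 0) return(numeric(n))
  if (n < 4L) return(stats::rnorm(n, sd = rms_uv))
  full <- complex(length.out = n)
  if (n %% 2L == 0L) {
    nh <- n %/% 2L
    f <- (1:nh) * fs_hz / n
    amp <- pmax(f, f_lo_hz)^(-beta / 2)
    ph <- stats::runif(nh, 0, 2 * pi)
    full[2:nh] <- complex(modulus = amp[1:(nh - 1)], argument = ph[1:(nh - 1)])
    full[nh + 1L] <- amp[nh] * cos(ph[nh])
    full[(nh + 2L):n] <- Conj(full[nh:2])
  } else {
    nh <- (n - 1L) %/% 2L
    f <- (1:nh) * fs_hz / n
    amp <- pmax(f, f_lo_hz)^(-beta / 2)
    ph <- stats::runif(nh, 0, 2 * pi)
    full[2:(nh + 1L)] <- complex(modulus = amp, argument = ph)
    full[(nh + 2L):n] <- Conj(full[(nh + 1L):2])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * rms_uv / sqrt(mean(x^2))
}

## Expected SD of the 1/f^beta background inside a frequency band, given the
## shaping actually used by generate_noise (per-realization RMS normalization
## makes this exact in expectation up to O(1/n) fluctuations).
band_noise_sd <- function(fs_hz, n_samples, beta, rms_uv, band,
                          f_lo_hz = 0.1) {
  n <- as.integer(n_samples)
  nh <- if (n %% 2L == 0L) n %/% 2L else (n - 1L) %/% 2L
  f <- (1:nh) * fs_hz / n
  p <- pmax(f, f_lo_hz)^(-beta)
  frac <- sum(p[f >= band[1] & f <= band[2]]) / sum(p)
  rms_uv * sqrt(frac)
}

## Gaussian depth profile, peak-normalized.
depth_profile <- function(depth_um, center_um, sigma_um) {
  exp(-(depth_um - center_um)^2 / (2 * sigma_um^2))
}

## Hann bump of full width w_s centered at c_s, evaluated on time grid t.
hann_bump <- function(t, c_s, w_s) {
  u <- (t - c_s) / w_s
  ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

## Trough attenuation of a Hann bump of width w_ms through the zero-phase
## 2-20 Hz detection band-pass; used to calibrate sharp-wave amplitudes so
## sw_amp_uv states the post-filter trough depth.
sw_band_attenuation <- local({
  cache <- new.env(parent = emptyenv())
  function(w_ms, fs_hz, band = c(2, 20)) {
    key <- sprintf("%.1f_%g", w_ms, fs_hz)
    if (!is.null(cache[[key]])) return(cache[[key]])
    t <- seq(-1, 1, by = 1 / fs_hz)
    bump <- -hann_bump(t, 0, w_ms / 1000)
    att <- min(bandpass_filter(bump, fs_hz, band)) / min(bump)
    cache[[key]] <- att
    att
  }
})

#' Build one laminar event snippet
#'
#' Phenomenological templates for the four event types: a Gaussian-windowed
#' ripple-band burst on stratum pyramidale (R), a negative Hann half-wave on
#' stratum radiatum (SW), their combination (SWR), or one long burst over 2-3
#' radiatum deflections (cSWR). Each ripple-bearing type also carries a small
#' dipolar SLM deflection scaled by `slm_input_gain`; every radiatum component
#' is scaled by `sr_input_gain`. Depth profiles are Gaussian bumps so the
#' second spatial difference yields one sink flanked by sources.
#'
#' @param type one of "R", "SW", "SWR", "cSWR".
#' @param fs_hz sampling rate, Hz.
#' @param sr_input_gain stratum-radiatum component multiplier.
#' @param slm_input_gain SLM component multiplier.
#' @param params list of template settings, see [template_params()].
#' @return list with `snippet` (channels x samples matrix, uV), `t_s` (time
#'   grid relative to the event peak), `peak_offset_s`, and `components`
#'   (data.frame of component annotations).
#' @export
generate_event_templates <- function(type, fs_hz = 600, sr_input_gain = 1,
                                     slm_input_gain = 1,
                                     params = template_params(fs_hz)) {
  if (!type %in% EVENT_TYPES) stop("unknown event type: ", type)
  p <- params
  depth <- p$depth_um
  n_ch <- length(depth)
  layer <- p$layer_map
  sp_center <- stats::median(depth[layer == "SP"])
  sr_center <- stats::median(depth[layer == "SR"])
  slm_center <- stats::median(depth[layer == "SLM"])
  sp_prof <- depth_profile(depth, sp_center, p$sp_sigma_um)
  sr_prof <- depth_profile(depth, sr_center, p$sr_sigma_um)
  slm_prof <- depth_profile(depth, slm_center - 50, p$slm_sigma_um) -
    depth_profile(depth, slm_center + 100, p$slm_sigma_um)
  sp_prof[layer %in% c("PFC_shallow", "PFC_deep")] <- 0
  sr_prof[layer %in% c("PFC_shallow", "PFC_deep")] <- 0
  slm_prof[layer %in% c("PFC_shallow", "PFC_deep")] <- 0

  ripple_dur <- if (type == "cSWR") p$cswr_dur_ms / 1000 else
    p$ripple_dur_ms / 1000
  n_sw <- switch(type, R = 0L, SW = 1L, SWR = 1L,
                 cSWR = as.integer(p$n_sw_components))
  sw_span <- if (n_sw > 1L) (n_sw - 1L) * p$sw_spacing_ms / 1000 else 0
  half_span <- max(ripple_dur, sw_span + p$sw_dur_ms / 1000) / 2 + 0.2
  t <- seq(-half_span, half_span, by = 1 / fs_hz)
  snippet <- matrix(0, nrow = n_ch, ncol = length(t))
  comp <- list()

  if (type != "SW") {
    sigma_g <- ripple_dur / 2.355           # FWHM -> Gaussian sd
    env <- p$ripple_amp_uv * (if (type == "cSWR") p$cswr_amp_factor else 1) *
      exp(-t^2 / (2 * sigma_g^2))
    burst <- env * sin(2 * pi * p$ripple_freq_hz * t)
    snippet <- snippet + outer(sp_prof, burst)
    comp[[length(comp) + 1L]] <- data.frame(
      component = "sp_burst", layer = "SP", t_center_s = 0,
      amplitude_uv = max(env))
    slm_wave <- p$slm_amp_uv * slm_input_gain * hann_bump(t, 0.02, 0.12)
    snippet <- snippet + outer(slm_prof, slm_wave)
    comp[[length(comp) + 1L]] <- data.frame(
      component = "slm_deflection", layer = "SLM", t_center_s = 0.02,
      amplitude_uv = p$slm_amp_uv * slm_input_gain)
  }
  if (n_sw > 0L) {
    centers <- if (n_sw == 1L) 0 else
      seq(-sw_span / 2, sw_span / 2, length.out = n_sw)
    att <- sw_band_attenuation(p$sw_dur_ms, fs_hz)
    for (cc in centers) {
      wave <- -(p$sw_amp_uv / att) * sr_input_gain *
        hann_bump(t, cc, p$sw_dur_ms / 1000)
      snippet <- snippet + outer(sr_prof, wave)
      comp[[length(comp) + 1L]] <- data.frame(
        component = "sr_sharp_wave", layer = "SR", t_center_s = cc,
        amplitude_uv = p$sw_amp_uv * sr_input_gain)
    }
  }
  list(snippet = snippet, t_s = t, peak_offset_s = 0,
       components = do.call(rbind, comp))
}

#' Template settings for the synthetic event snippets
#'
#' @param fs_hz sampling rate, Hz.
#' @param n_channels hippocampal channel count.
#' @param channel_spacing_um probe spacing, um.
#' @param ripple_freq_hz ripple carrier frequency.
#' @param ripple_dur_ms ripple envelope FWHM (R/SWR).
#' @param cswr_dur_ms burst FWHM for cSWR.
#' @param ripple_amp_uv ripple envelope peak amplitude.
#' @param cswr_amp_factor amplitude multiplier for the long cSWR burst.
#' @param sw_dur_ms sharp-wave full width.
#' @param sw_amp_uv sharp-wave trough depth.
#' @param n_sw_components radiatum deflections under a cSWR burst (>= 2).
#' @param sw_spacing_ms spacing between cSWR radiatum deflections.
#' @param slm_amp_uv SLM dipolar deflection amplitude.
#' @return list of settings consumed by [generate_event_templates()].
#' @export
template_params <- function(fs_hz = 600, n_channels = 32,
                            channel_spacing_um = 50,
                            ripple_freq_hz = 150, ripple_dur_ms = 80,
                            cswr_dur_ms = 220, ripple_amp_uv = 25,
                            cswr_amp_factor = 1.2,
                            sw_dur_ms = 60, sw_amp_uv = 150,
                            n_sw_components = 2, sw_spacing_ms = 115,
                            slm_amp_uv = 60) {
  layer_map <- default_layer_map(n_channels)
  depth_um <- seq_len(n_channels + 2L) * channel_spacing_um
  list(fs_hz = fs_hz, depth_um = depth_um, layer_map = layer_map,
       ripple_freq_hz = ripple_freq_hz, ripple_dur_ms = ripple_dur_ms,
       cswr_dur_ms = cswr_dur_ms, ripple_amp_uv = ripple_amp_uv,
       cswr_amp_factor = cswr_amp_factor,
       sw_dur_ms = sw_dur_ms, sw_amp_uv = sw_amp_uv,
       n_sw_components = n_sw_components, sw_spacing_ms = sw_spacing_ms,
       slm_amp_uv = slm_amp_uv,
       sp_sigma_um = 1.5 * channel_spacing_um,
       sr_sigma_um = 1.5 * channel_spacing_um,
       slm_sigma_um = 1.5 * channel_spacing_um)
}

## Alternating NonREM-like / REM-like schedule, bout edges on the epoch grid.
draw_state_schedule <- function(duration_s, state_bout_s, epoch_s) {
  t <- 0
  state <- "NREM_like"
  rows <- list()
  while (t < duration_s) {
    mean_d <- if (state == "NREM_like") state_bout_s[["nrem"]] else
      state_bout_s[["rem"]]
    d <- max(3 * epoch_s,
             round(stats::rnorm(1, mean_d, 0.3 * mean_d) / epoch_s) * epoch_s)
    end <- min(t + d, duration_s)
    rows[[length(rows) + 1L]] <- data.frame(state = state, start_s = t,
                                            end_s = end)
    t <- end
    state <- if (state == "NREM_like") "REM_like" else "NREM_like"
  }
  do.call(rbind, rows)
}

#' Generate a seeded laminar recording with ground truth
#'
#' Synthesizes the full recording described by a [sim_config()]: 1/f
#' background on every channel, a slow oscillation on the prefrontal channels
#' (and, attenuated and depth-uniform, on the hippocampal channels) during
#' NonREM-like bouts, theta during REM-like bouts, and the four hippocampal
#' event types injected at their configured slow-oscillation phases. All
#' randomness is drawn before the input gains are applied, so recordings that
#' differ only in `sr_input_gain`/`slm_input_gain` share identical event
#' times.
#'
#' @param config a [sim_config()].
#' @return list with `recording` (a `laminar_recording`) and `ground_truth`
#'   (list of `events`, `state_schedule`, `artifact_times`).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$fs_hz
  n <- as.integer(round(config$duration_s * fs))
  n_ch <- config$n_channels + 2L
  params <- template_params(fs_hz = fs, n_channels = config$n_channels,
                            channel_spacing_um = config$channel_spacing_um)

  ## band-referenced event amplitudes (fixed SNR conditions)
  sd_ripple_band <- band_noise_sd(fs, n, config$noise_beta,
                                  config$noise_rms_uv, c(90, 200))
  sd_sw_band <- band_noise_sd(fs, n, config$noise_beta,
                              config$noise_rms_uv, c(2, 20))
  ## events occur in NonREM-like bouts, whose background carries the NonREM
  ## broadband gain; amplitudes are referenced to that local background
  nrem_gain <- config$state_noise_gain[["nrem"]]
  params$ripple_amp_uv <- config$ripple_snr * sd_ripple_band * nrem_gain
  params$sw_amp_uv <- config$sw_snr * sd_sw_band * nrem_gain
  params$slm_amp_uv <- 0.5 * params$sw_amp_uv

  schedule <- draw_state_schedule(config$duration_s, config$state_bout_s,
                                  config$epoch_s)

  ## per-bout slow-oscillation / theta parameters
  schedule$osc_freq <- ifelse(schedule$state == "NREM_like",
                              stats::runif(nrow(schedule), 0.5, 1),
                              stats::runif(nrow(schedule), 3.5, 5.5))
  schedule$osc_phase0 <- stats::runif(nrow(schedule), 0, 2 * pi)

  ## --- draw events (gain-independent randomness) -------------------------
  event_bouts <- schedule[schedule$state == "NREM_like" |
                            config$allow_rem_events, , drop = FALSE]
  events <- list()
  for (bi in seq_len(nrow(event_bouts))) {
    bout <- event_bouts[bi, ]
    bout_len <- bout$end_s - bout$start_s
    if (bout_len < 20) next
    phase_at <- function(t) {
      (2 * pi * bout$osc_freq * (t - bout$start_s) + bout$osc_phase0)
    }
    for (type in EVENT_TYPES) {
      rate <- config$event_rates[[type]]
      if (rate <= 0) next
      n_ev <- stats::rpois(1, rate * bout_len / 60)
      if (n_ev == 0) next
      for (k in seq_len(n_ev)) {
        dur_ms <- if (type == "cSWR") stats::runif(1, 180, 300) else
          stats::runif(1, 70, 150)
        freq <- stats::runif(1, 120, 180)
        n_comp <- switch(type, R = 0L, SW = 1L, SWR = 1L,
                         cSWR = sample(2:3, 1))
        sw_w <- stats::runif(1, 50, 90)
        spacing <- stats::runif(1, 100, 130)
        half <- max(dur_ms / 1000,
                    (max(n_comp - 1, 0) * spacing + sw_w) / 1000) / 2 + 0.15
        target <- config$event_phase_deg[[type]] * pi / 180
        placed <- FALSE
        for (try in 1:25) {
          t0 <- stats::runif(1, bout$start_s + half + 2,
                             bout$end_s - half - 2)
          dphi <- (target - phase_at(t0)) %% (2 * pi)
          if (dphi > pi) dphi <- dphi - 2 * pi
          t0 <- t0 + dphi / (2 * pi * bout$osc_freq)
          if (t0 - half < bout$start_s + 1.6 ||
              t0 + half > bout$end_s - 1.6) next
          ok <- TRUE
          for (ev in events) {
            if (abs(ev$t0 - t0) < ev$half + half + 0.25) { ok <- FALSE; break }
          }
          if (ok) { placed <- TRUE; break }
        }
        if (!placed) next
        events[[length(events) + 1L]] <- list(
          type = type, t0 = t0, half = half, dur_ms = dur_ms, freq = freq,
          n_comp = n_comp, sw_w = sw_w, spacing = spacing)
      }
    }
  }
  if (length(events)) {
    events <- events[order(vapply(events, `[[`, 0, "t0"))]
  }

  ## artifacts (kept clear of event windows)
  artifact_times <- numeric(0)
  if (config$n_artifacts > 0) {
    for (k in seq_len(config$n_artifacts)) {
      for (try in 1:50) {
        ta <- stats::runif(1, 5, config$duration_s - 5)
        clear <- all(vapply(events, function(ev)
          abs(ev$t0 - ta) > ev$half + 4.5, TRUE))
        if (clear && all(abs(artifact_times - ta) > 9)) {
          artifact_times <- c(artifact_times, ta)
          break
        }
      }
    }
    artifact_times <- sort(artifact_times)
  }

  ## --- synthesis ----------------------------------------------------------
  samples <- matrix(0, nrow = n_ch, ncol = n)
  for (ch in seq_len(n_ch)) {
    samples[ch, ] <- generate_noise(n, fs, config$noise_beta,
                                    config$noise_rms_uv)
  }
  tgrid <- (seq_len(n) - 1) / fs

  ## volume conduction: laminar LFP noise is strongly correlated across
  ## neighboring sites; smooth the hippocampal noise across depth with an
  ## RMS-preserving Gaussian kernel so the background CSD is realistic
  if (config$noise_space_sigma_um > 0) {
    hpc_rows <- which(!params$layer_map %in% c("PFC_shallow", "PFC_deep"))
    d <- params$depth_um[hpc_rows]
    K <- exp(-outer(d, d, "-")^2 / (2 * config$noise_space_sigma_um^2))
    K <- K / sqrt(rowSums(K^2))
    samples[hpc_rows, ] <- K %*% samples[hpc_rows, , drop = FALSE]
  }

  ## broadband state comodulation: NonREM-like background is globally louder
  ## (smoothed per-bout gain applied to the noise floor of every channel)
  gain <- numeric(n)
  for (bi in seq_len(nrow(schedule))) {
    sel <- tgrid >= schedule$start_s[bi] & tgrid < schedule$end_s[bi]
    gain[sel] <- if (schedule$state[bi] == "NREM_like")
      config$state_noise_gain[["nrem"]] else config$state_noise_gain[["rem"]]
  }
  if (n > 1L) {
    w <- min(n, as.integer(2 * fs) + 1L)          # ~2 s boxcar smoothing
    cs <- cumsum(c(0, gain))
    lo <- pmax(0L, seq_len(n) - (w + 1L) %/% 2L)
    hi <- pmin(n, seq_len(n) + w %/% 2L)
    gain <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
  samples <- sweep(samples, 2L, gain, "*")
  layer <- params$layer_map
  hpc_idx <- which(!layer %in% c("PFC_shallow", "PFC_deep"))
  pfc_sh <- which(layer == "PFC_shallow")
  pfc_dp <- which(layer == "PFC_deep")

  for (bi in seq_len(nrow(schedule))) {
    bout <- schedule[bi, ]
    sel <- tgrid >= bout$start_s & tgrid < bout$end_s
    tt <- tgrid[sel]
    ph <- 2 * pi * bout$osc_freq * (tt - bout$start_s) + bout$osc_phase0
    ## amplitude ramps at bout edges avoid broadband steps in the background
    ramp <- pmin(1, (tt - bout$start_s) / 1.5, (bout$end_s - tt) / 1.5)
    ramp <- pmax(ramp, 0)
    if (bout$state == "NREM_like") {
      so <- ramp * cos(ph)
      samples[pfc_sh, sel] <- samples[pfc_sh, sel] + config$so_amp_uv * so
      samples[pfc_dp, sel] <- samples[pfc_dp, sel] -
        0.7 * config$so_amp_uv * so
      ## depth-uniform hippocampal echo (contributes no CSD)
      samples[hpc_idx, sel] <- samples[hpc_idx, sel] +
        rep(0.3 * config$so_amp_uv * so, each = length(hpc_idx))
    } else {
      th <- ramp * cos(ph)
      samples[hpc_idx, sel] <- samples[hpc_idx, sel] +
        rep(config$theta_amp_uv * th, each = length(hpc_idx))
      samples[pfc_sh, sel] <- samples[pfc_sh, sel] +
        0.3 * config$theta_amp_uv * th
      samples[pfc_dp, sel] <- samples[pfc_dp, sel] +
        0.3 * config$theta_amp_uv * th
    }
  }

  gt_rows <- list()
  for (ev in events) {
    p_ev <- params
    p_ev$ripple_freq_hz <- ev$freq
    dur_factor <- if (config$couple_ripple_duration) config$sr_input_gain else 1
    if (ev$type == "cSWR") p_ev$cswr_dur_ms <- ev$dur_ms * dur_factor
    else p_ev$ripple_dur_ms <- ev$dur_ms * dur_factor
    p_ev$sw_dur_ms <- ev$sw_w
    p_ev$sw_spacing_ms <- ev$spacing
    if (ev$n_comp > 1L) p_ev$n_sw_components <- ev$n_comp
    tpl <- generate_event_templates(ev$type, fs, config$sr_input_gain,
                                    config$slm_input_gain, p_ev)
    i0 <- as.integer(round(ev$t0 * fs)) + 1L
    idx <- i0 + seq_along(tpl$t_s) - 1L -
      as.integer((length(tpl$t_s) - 1L) / 2L)
    keep <- idx >= 1L & idx <= n
    samples[, idx[keep]] <- samples[, idx[keep]] + tpl$snippet[, keep]
    gt_rows[[length(gt_rows) + 1L]] <- data.frame(
      type = ev$type,
      start_s = ev$t0 - ev$half + 0.1,
      peak_s = ev$t0,
      end_s = ev$t0 + ev$half - 0.1,
      n_sw_components = switch(ev$type, R = 0L, SW = 1L, SWR = 1L,
                               cSWR = ev$n_comp))
  }
  for (ta in artifact_times) {
    ia <- as.integer(round(ta * fs)) + 1L
    idx <- ia:min(ia + as.integer(0.05 * fs), n)
    samples[, idx] <- samples[, idx] + 20 * max(config$noise_rms_uv, 1)
  }

  gt_events <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    data.frame(type = character(), start_s = numeric(), peak_s = numeric(),
               end_s = numeric(), n_sw_components = integer())

  rec <- laminar_recording(
    samples = samples, fs_hz = fs,
    channel_labels = sprintf("ch%02d", seq_len(n_ch)),
    depth_um = params$depth_um, layer_map = layer,
    start_clock_s = 0)
  list(recording = rec,
       ground_truth = list(events = gt_events,
                           state_schedule = schedule[, c("state", "start_s",
                                                         "end_s")],
                           artifact_times = artifact_times),
       params = params)
}
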