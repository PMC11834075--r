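## Wavelet spectrograms, Welch PSD, and the aperiodic (1/f) slope/offset
## analysis used as an excitation-inhibition proxy.

#' Morlet wavelet spectrogram
#'
#' Complex Morlet convolution per frequency with a fixed number of cycles
#' (default six, `sigma_t = n_cycles / (2 pi f)`). Wavelets are unit-energy
#' (L2) normalized, so the time-averaged power of stationary noise tracks its
#' power spectral density; a unit tone's peak power then scales as 1/f.
#'
#' @param trace single-channel window.
#' @param fs_hz sampling rate, Hz.
#' @param freqs frequency grid, Hz (default 1-200 in 1 Hz steps).
#' @param n_cycles wavelet cycles (default 6).
#' @return list of class `wavelet_spectrogram`: `power` (frequencies x time),
#'   `freqs`, `fs_hz`, `n_cycles`.
#' @export
morlet_spectrogram <- function(trace, fs_hz, freqs = 1:200, n_cycles = 6) {
  if (any(freqs >= fs_hz / 2)) stop("frequencies must be below Nyquist")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  n <- length(trace)
  power <- matrix(0, nrow = length(freqs), ncol = n)
  dt <- 1 / fs_hz
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sigma_t <- n_cycles / (2 * pi * f)
    half <- min(as.integer(ceiling(5 * sigma_t * fs_hz)),
                as.integer(ceiling(n / 2)) + 1L)
    tk <- (-half:half) * dt
    psi <- exp(-tk^2 / (2 * sigma_t^2)) *
      exp(1i * 2 * pi * f * tk)
    psi <- psi / sqrt(sum(Mod(psi)^2) * dt)        # unit energy
    coef <- fft_convolve_same(trace, Conj(rev(psi))) * dt
    power[k, ] <- Mod(coef)^2
  }
  structure(list(power = power, freqs = freqs, fs_hz = fs_hz,
                 n_cycles = n_cycles),
            class = "wavelet_spectrogram")
}

#' Welch power spectral density with 50 Hz notch
#'
#' 4-s Hann-tapered segments with 0.25-s overlap, averaged; a second-order
#' IIR notch (quality factor 30) removes 50 Hz line noise before the PSD.
#' Output is log10 power on a 0-100 Hz grid in 0.25 Hz steps.
#'
#' @param trace single-channel window (>= 4 s).
#' @param fs_hz sampling rate, Hz.
#' @param seg_s segment length, seconds (default 4; sets the 0.25 Hz grid).
#' @param overlap_s segment overlap, seconds (default 0.25).
#' @param fmax_hz upper frequency bound (default 100).
#' @param notch_hz line frequency to notch (NULL disables).
#' @return data.frame with `freq_hz` and `log10_power`; attribute
#'   `all_zero` flags a degenerate all-zero input.
#' @export
compute_psd <- function(trace, fs_hz, seg_s = 4, overlap_s = 0.25,
                        fmax_hz = 100, notch_hz = 50) {
  nseg <- as.integer(round(seg_s * fs_hz))
  if (length(trace) < nseg) {
    stop("trace shorter than the ", seg_s, " s analysis segment")
  }
  all_zero <- all(trace == 0)
  if (!all_zero && !is.null(notch_hz)) {
    trace <- notch_filter(trace, fs_hz, notch_hz)
  }
  step <- max(1L, nseg - as.integer(round(overlap_s * fs_hz)))
  starts <- seq(1L, length(trace) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  acc <- numeric(nseg %/% 2L + 1L)
  for (s in starts) {
    seg <- trace[s:(s + nseg - 1L)] * w
    X <- stats::fft(seg)
    acc <- acc + Mod(X[seq_len(nseg %/% 2L + 1L)])^2
  }
  psd <- acc / length(starts) / (sum(w^2) * fs_hz)
  freq <- (seq_along(psd) - 1) * fs_hz / nseg
  keep <- freq <= fmax_hz
  eps <- if (all_zero) .Machine$double.xmin else 1e-12 * max(psd)
  structure(data.frame(freq_hz = freq[keep],
                       log10_power = log10(pmax(psd[keep], eps))),
            all_zero = all_zero)
}

#' Aperiodic slope and offset of wavelet power
#'
#' Averages the spectrogram power over a window around `center_s` (default
#' half width 250 ms), then fits a least-squares line of log10 power against
#' log10 frequency. Non-positive power bins are floored at 1e-12 of the
#' maximum (count reported).
#'
#' @param spectrogram a [morlet_spectrogram()].
#' @param center_s window center, seconds from trace start (NULL = whole
#'   trace).
#' @param half_width_s window half width, seconds (default 0.25).
#' @return list of class `spectral_fit`: `slope`, `offset`, `r2`, `window`,
#'   `n_floored`.
#' @export
fit_spectral_slope <- function(spectrogram, center_s = NULL,
                               half_width_s = 0.25) {
  pw <- spectrogram$power
  fs <- spectrogram$fs_hz
  if (is.null(center_s)) {
    cols <- seq_len(ncol(pw))
  } else {
    c0 <- as.integer(round(center_s * fs)) + 1L
    hw <- as.integer(round(half_width_s * fs))
    if (c0 - hw < 1L || c0 + hw > ncol(pw)) {
      stop("analysis window extends beyond the spectrogram")
    }
    cols <- (c0 - hw):(c0 + hw)
  }
  p <- rowMeans(pw[, cols, drop = FALSE])
  eps <- 1e-12 * max(p, .Machine$double.xmin)
  n_floored <- sum(p < eps)
  lp <- log10(pmax(p, eps))
  lf <- log10(spectrogram$freqs)
  fit <- stats::lm.fit(cbind(1, lf), lp)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lp - mean(lp))^2)
  structure(list(slope = unname(fit$coefficients[2L]),
                 offset = unname(fit$coefficients[1L]),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 window = c(center_s = if (is.null(center_s)) NA_real_ else
                   center_s, half_width_s = half_width_s),
                 n_floored = n_floored),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("spectral fit: slope %.3f, offset %.3f, r2 %.3f\n",
              x$slope, x$offset, x$r2))
  invisible(x)
}

#' Slope/offset time course
#'
#' [fit_spectral_slope()] applied per time sample over a sub-sampled column
#' grid (for the peri-event slope traces).
#'
#' @param spectrogram a [morlet_spectrogram()].
#' @param every_s fit spacing, seconds.
#' @return data.frame with `time_s`, `slope`, `offset`, `r2`.
#' @export
spectral_slope_timecourse <- function(spectrogram, every_s = 0.05) {
  fs <- spectrogram$fs_hz
  step <- max(1L, as.integer(round(every_s * fs)))
  cols <- seq(1L, ncol(spectrogram$power), by = step)
  lf <- log10(spectrogram$freqs)
  X <- cbind(1, lf)
  out <- lapply(cols, function(j) {
    p <- spectrogram$power[, j]
    eps <- 1e-12 * max(p, .Machine$double.xmin)
    lp <- log10(pmax(p, eps))
    fit <- stats::lm.fit(X, lp)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((lp - mean(lp))^2)
    c(time_s = (j - 1) / fs, slope = unname(fit$coefficients[2L]),
      offset = unname(fit$coefficients[1L]),
      r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
  })
  as.data.frame(do.call(rbind, out))
}
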