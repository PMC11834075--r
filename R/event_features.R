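## Per-event waveform features in both layers and the cross-layer AUC
## power-law machinery.

#' Area under the curve of an event waveform
#'
#' Trapezoidal numerical integration of the absolute value of the filtered
#' event between its start and end; deliberately not amplitude-normalized, so
#' the value reflects both amplitude and duration.
#'
#' @param wave filtered event trace (numeric, >= 2 samples).
#' @param fs_hz sampling rate, Hz.
#' @return AUC in uV * s.
#' @export
compute_auc <- function(wave, fs_hz) {
  n <- length(wave)
  if (n < 2L) stop("need at least 2 samples")
  a <- abs(wave)
  (sum(a) - (a[1L] + a[n]) / 2) / fs_hz
}

#' Waveform features of a filtered event
#'
#' Amplitude is the maximum of the Hilbert (analytic) envelope; mean
#' frequency the power-weighted first moment of the one-sided periodogram;
#' power the squared Euclidean norm divided by the sample count; `n_peaks`
#' the number of strict local maxima (no prominence requirement).
#'
#' @param wave filtered event trace (>= 3 samples).
#' @param fs_hz sampling rate, Hz.
#' @return list with `amplitude`, `mean_freq_hz`, `power`, `n_peaks`.
#' @export
waveform_features <- function(wave, fs_hz) {
  n <- length(wave)
  if (n < 3L) stop("need at least 3 samples")
  amplitude <- max(Mod(analytic_signal(wave)))
  nhalf <- floor(n / 2) + 1L
  P <- Mod(stats::fft(wave)[seq_len(nhalf)])^2
  f <- (seq_len(nhalf) - 1) * fs_hz / n
  mean_freq <- if (sum(P) > 0) sum(f * P) / sum(P) else 0
  interior <- 2L:(n - 1L)
  n_peaks <- sum(wave[interior] > wave[interior - 1L] &
                   wave[interior] > wave[interior + 1L])
  list(amplitude = amplitude, mean_freq_hz = mean_freq,
       power = sum(wave^2) / n, n_peaks = as.integer(n_peaks))
}

#' Sharp-wave frequency from a wavelet spectrogram
#'
#' A 1-200 Hz Morlet spectrogram (six cycles) of a 6-s radiatum context
#' centered on the sharp-wave peak; power is summed over the event duration,
#' normalized to unit sum, and dotted with the frequency vector.
#'
#' @param sr_trace stratum-radiatum trace (2-20 Hz band or raw).
#' @param fs_hz sampling rate, Hz.
#' @param peak_s sharp-wave peak time, seconds from trace start.
#' @param start_s,end_s event limits, seconds.
#' @param context_s context window length (default 6 s; reflect-padded when
#'   the trace is too short).
#' @return frequency in Hz; 0 (with attribute `degenerate = TRUE`) for an
#'   all-zero trace.
#' @export
sw_frequency <- function(sr_trace, fs_hz, peak_s, start_s, end_s,
                         context_s = 6) {
  n <- length(sr_trace)
  peak_i <- as.integer(round(peak_s * fs_hz)) + 1L
  if (peak_i < 1L || peak_i > n) stop("event peak outside the trace")
  half <- as.integer(round(context_s / 2 * fs_hz))
  idx <- (peak_i - half):(peak_i + half)
  ## reflect-pad out-of-range context
  idx_r <- pmin(pmax(ifelse(idx < 1L, 2L - idx, idx), 1L), n)
  idx_r <- ifelse(idx_r > n, 2L * n - idx_r, idx_r)
  win <- sr_trace[idx_r]
  spec <- morlet_spectrogram(win, fs_hz, freqs = 1:200, n_cycles = 6)
  t_rel <- (idx - peak_i) / fs_hz + peak_s
  cols <- t_rel >= start_s & t_rel <= end_s
  v <- abs(rowSums(spec$power[, cols, drop = FALSE]))
  if (sum(v) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  sum(spec$freqs * v / sum(v))
}

#' Least-squares power-law fit in log10-log10 space
#'
#' @param x,y positive values; non-positive pairs are dropped (count
#'   reported in the result).
#' @return list of class `loglog_fit`: `slope`, `intercept`, `r`, `n`,
#'   `n_dropped`.
#' @export
loglog_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n_dropped <- sum(!ok)
  lx <- log10(x[ok]); ly <- log10(y[ok])
  if (length(lx) < 3L) stop("fewer than 3 positive points after filtering")
  fit <- stats::lm.fit(cbind(1, lx), ly)
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r = stats::cor(lx, ly), n = length(lx),
                 n_dropped = n_dropped),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("log10-log10 fit: slope %.3f, intercept %.3f, r %.3f, n %d",
              x$slope, x$intercept, x$r, x$n))
  if (x$n_dropped > 0) cat(sprintf(" (%d non-positive dropped)", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' Compare two correlation coefficients (Fisher z-test)
#'
#' z-test of the difference of Fisher z-transformed correlations divided by
#' the standard error of the difference,
#' `z = (atanh(rA) - atanh(rB)) / sqrt(1/(nA-3) + 1/(nB-3))`.
#'
#' @param rA,rB correlations (|r| < 1).
#' @param nA,nB sample sizes (> 3).
#' @return list with `z` and two-sided `p`.
#' @export
compare_correlation_slopes <- function(rA, nA, rB, nB) {
  stopifnot(nA > 3, nB > 3)
  if (abs(rA) >= 1 || abs(rB) >= 1) stop("|r| must be < 1")
  z <- (atanh(rA) - atanh(rB)) / sqrt(1 / (nA - 3) + 1 / (nB - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Select the events closest to the median amplitude
#'
#' Ranks events by |amplitude - median(amplitude)| and keeps the `k`
#' smallest (all when fewer); ties break by earlier peak time.
#'
#' @param events data.frame with `amplitude` and `peak_s` columns.
#' @param k number of events to keep (default 2000).
#' @return subset of `events`.
#' @export
select_median_events <- function(events, k = 2000) {
  stopifnot(k >= 1)
  if (!nrow(events)) return(events)
  d <- abs(events$amplitude - stats::median(events$amplitude))
  ord <- order(d, events$peak_s)
  events[sort(ord[seq_len(min(k, nrow(events)))]), , drop = FALSE]
}

#' Bivariate kernel density with equal-mass contour levels
#'
#' Gaussian-kernel density on a regular grid (normal-reference bandwidth);
#' contour levels are chosen so that each encloses an equal fraction of the
#' probability mass.
#'
#' @param x,y numeric vectors (n >= 10).
#' @param n_levels number of equal-mass levels (default 3).
#' @param grid_n grid resolution per axis.
#' @param z_score z-score the density surface (used for type-mixed plots).
#' @return list with `x`, `y`, `z` (density grid) and `levels` (density
#'   values; contour i encloses mass fraction i / n_levels).
#' @export
density_contours <- function(x, y, n_levels = 3, grid_n = 101,
                             z_score = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 10, n_levels >= 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 ||
      abs(stats::cor(x, y)) > 1 - 1e-12) {
    stop("degenerate (collinear or constant) data")
  }
  kd <- MASS::kde2d(x, y, n = grid_n)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  dens <- sort(as.vector(kd$z), decreasing = TRUE)
  cum_mass <- cumsum(dens) * cell
  cum_mass <- cum_mass / cum_mass[length(cum_mass)]
  ## level for mass fraction q: smallest density whose upper set has mass q
  levels <- vapply(seq_len(n_levels) / n_levels, function(q) {
    dens[which(cum_mass >= q)[1L]]
  }, 0)
  z <- kd$z
  if (z_score) z <- (z - mean(z)) / stats::sd(z)
  list(x = kd$x, y = kd$y, z = z, levels = levels)
}

#' Per-event features on both layers
#'
#' For ripple-bearing events (R, SWR, cSWR) the feature window is the
#' ripple's start-end; for standalone sharp waves it is the sharp wave's own
#' window. Features are computed on the simultaneous activity of both the
#' 90-200 Hz pyramidale trace and the 2-20 Hz radiatum trace within that
#' window.
#'
#' @param events event table from [classify_events()].
#' @param sp_filtered 90-200 Hz filtered pyramidale trace.
#' @param sr_filtered 2-20 Hz filtered radiatum trace.
#' @param fs_hz sampling rate, Hz.
#' @param sw_freq also compute the wavelet-based sharp-wave frequency
#'   (slower; default TRUE).
#' @return data.frame keyed by `event_id` with per-layer duration, amplitude,
#'   mean frequency, power, peak count and AUC, plus `sw_freq_hz`.
#' @export
event_feature_table <- function(events, sp_filtered, sr_filtered, fs_hz,
                                sw_freq = TRUE) {
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    a <- events$start_s[i]; b <- events$end_s[i]
    i0 <- max(1L, as.integer(round(a * fs_hz)) + 1L)
    i1 <- min(length(sp_filtered), as.integer(round(b * fs_hz)) + 1L)
    if (i1 - i0 < 2L) next
    wsp <- sp_filtered[i0:i1]
    wsr <- sr_filtered[i0:i1]
    fsp <- waveform_features(wsp, fs_hz)
    fsr <- waveform_features(wsr, fs_hz)
    swf <- if (sw_freq && events$type[i] != "R") {
      sw_frequency(sr_filtered, fs_hz, events$peak_s[i], a, b)
    } else NA_real_
    rows[[i]] <- data.frame(
      event_id = events$event_id[i], type = events$type[i],
      duration_ms = (b - a) * 1000,
      sp_amplitude = fsp$amplitude, sp_mean_freq_hz = fsp$mean_freq_hz,
      sp_power = fsp$power, sp_n_peaks = fsp$n_peaks,
      sp_auc = compute_auc(wsp, fs_hz),
      sr_amplitude = fsr$amplitude, sr_mean_freq_hz = fsr$mean_freq_hz,
      sr_power = fsr$power, sr_n_peaks = fsr$n_peaks,
      sr_auc = compute_auc(wsr, fs_hz),
      sw_freq_hz = as.numeric(swf))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(event_id = integer(), type = character(),
                      duration_ms = numeric(), sp_amplitude = numeric(),
                      sp_mean_freq_hz = numeric(), sp_power = numeric(),
                      sp_n_peaks = integer(), sp_auc = numeric(),
                      sr_amplitude = numeric(), sr_mean_freq_hz = numeric(),
                      sr_power = numeric(), sr_n_peaks = integer(),
                      sr_auc = numeric(), sw_freq_hz = numeric())
  }
  rownames(out) <- NULL
  out
}
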