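## Shared DSP primitives: analytic signal, zero-phase Butterworth wrappers,
## DPSS tapers / multitaper PSD, 50 Hz notch, FFT helpers.

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns the complex analytic signal `x + i * H(x)`; `Mod()` of the result is
#' the instantaneous envelope and `Arg()` the instantaneous phase. The input is
#' reflect-padded to a fast FFT length so arbitrary (including prime) lengths
#' stay O(n log n).
#'
#' @param x numeric vector.
#' @return complex vector, same length as `x`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic_signal() needs at least 2 samples")
  if (anyNA(x)) stop("analytic_signal() requires finite input")
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  pad <- nfft - n
  xp <- if (pad > 0L) c(x, rev(x)[seq_len(pad)]) else x
  X <- stats::fft(xp)
  h <- numeric(nfft)
  if (nfft %% 2L == 0L) {
    h[1L] <- 1; h[nfft / 2L + 1L] <- 1; h[2L:(nfft / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((nfft + 1L) / 2L)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / nfft
  z[seq_len(n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (`filtfilt`) application, so the effective magnitude
#' response is |H|^2 and group delay is zero.
#'
#' @param x numeric vector.
#' @param fs_hz sampling rate in Hz.
#' @param band length-2 numeric, pass band in Hz.
#' @param order filter order (of the analog prototype; default 4).
#' @return filtered vector.
#' @export
bandpass_filter <- function(x, fs_hz, band, order = 4L) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1],
            band[2] < fs_hz / 2)
  bf <- signal::butter(order, band / (fs_hz / 2), type = "pass")
  filtfilt_padded(bf, x, ceiling(20 * fs_hz / band[1]))
}

## filtfilt with odd-reflection edge padding (suppresses the start/end
## transients of a plain forward-backward pass).
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(pad))
  if (pad < 1L) return(signal::filtfilt(bf, x))
  head <- 2 * x[1L] - x[(pad + 1L):2L]
  tail <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(head, x, tail))
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth low-pass filter
#' @inheritParams bandpass_filter
#' @param cutoff_hz cutoff frequency in Hz.
#' @export
lowpass_filter <- function(x, fs_hz, cutoff_hz, order = 3L) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs_hz / 2)
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  filtfilt_padded(bf, x, ceiling(20 * fs_hz / cutoff_hz))
}

## Second-order IIR notch (biquad), standard RBJ design.
notch_filter <- function(x, fs_hz, freq_hz = 50, q = 30) {
  w0 <- 2 * pi * freq_hz / fs_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::filtfilt(signal::Arma(b = b / a[1], a = a / a[1]), x)
}

## Discrete prolate spheroidal sequences via the symmetric tridiagonal
## eigenproblem (Percival & Walden eq. 378). For long windows the tapers are
## computed at a reduced length and spline-interpolated (they are smooth,
## band-limited functions), then renormalized to unit energy.
dpss_tapers <- local({
  cache <- new.env(parent = emptyenv())
  function(n, nw = 4, k = 2 * nw - 1, max_exact_n = 1024L) {
    key <- sprintf("%d_%g_%d", n, nw, k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- dpss_tapers_impl(n, nw, k, max_exact_n)
    cache[[key]] <- v
    v
  }
})

dpss_tapers_impl <- function(n, nw = 4, k = 2 * nw - 1, max_exact_n = 1024L) {
  stopifnot(n >= 16, nw >= 1, k >= 1)
  n_eff <- min(n, max_exact_n)
  w <- nw / n_eff
  t <- seq_len(n_eff) - 1
  diag_main <- ((n_eff - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  m <- diag(diag_main)
  idx <- seq_len(n_eff - 1)
  off <- idx * (n_eff - idx) / 2
  m[cbind(idx, idx + 1L)] <- off
  m[cbind(idx + 1L, idx)] <- off
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  ## sign convention: each taper's mean lobe positive
  for (j in seq_len(k)) {
    if (sum(v[, j]) < 0 || (abs(sum(v[, j])) < 1e-12 && v[2, j] < 0)) {
      v[, j] <- -v[, j]
    }
  }
  if (n_eff < n) {
    xi <- seq(0, 1, length.out = n_eff)
    xo <- seq(0, 1, length.out = n)
    v <- apply(v, 2L, function(col) stats::spline(xi, col, xout = xo)$y)
  }
  sweep(v, 2L, sqrt(colSums(v^2)), "/")
}

#' Multitaper power spectral density of one window
#'
#' Average of `k` DPSS eigenspectra with time-bandwidth product `nw`.
#'
#' @param x numeric vector (one analysis window).
#' @param fs_hz sampling rate in Hz.
#' @param nw time-bandwidth product (default 4).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return list with `freq_hz` (0..Nyquist) and `psd` (power per bin).
#' @export
multitaper_psd <- function(x, fs_hz, nw = 4, k = 2 * nw - 1) {
  n <- length(x)
  tapers <- dpss_tapers(n, nw = nw, k = k)
  nhalf <- floor(n / 2) + 1L
  acc <- numeric(nhalf)
  for (j in seq_len(ncol(tapers))) {
    X <- stats::fft(x * tapers[, j])
    acc <- acc + Mod(X[seq_len(nhalf)])^2
  }
  list(freq_hz = (seq_len(nhalf) - 1) * fs_hz / n,
       psd = acc / ncol(tapers))
}

## Sum of PSD bins whose frequency falls in [band[1], band[2]] (inclusive).
band_power <- function(psd, band) {
  sel <- psd$freq_hz >= band[1] & psd$freq_hz <= band[2]
  sum(psd$psd[sel])
}

## Linear convolution of x with a (short) complex kernel via FFT.
fft_convolve_same <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  nfft <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(nfft - n)))
  K <- stats::fft(c(kernel, complex(real = numeric(nfft - m))))
  y <- stats::fft(X * K, inverse = TRUE) / nfft
  ## centered ("same") alignment
  start <- floor((m - 1L) / 2L) + 1L
  y[start:(start + n - 1L)]
}

## Runs of TRUE in a logical vector -> matrix of [start, end] sample indices
## (inclusive). Zero-row matrix when there are none.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
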