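## Preprocessing: anti-aliased downsampling, artifact detection/blanking,
## head trimming and 45-min binning.

#' Anti-aliased integer downsampling
#'
#' Zero-phase 3rd-order Butterworth low-pass (default cutoff 300 Hz) followed
#' by integer decimation. The decimation factor `fs_hz / target_fs` must be an
#' integer.
#'
#' @param recording a [laminar_recording()].
#' @param target_fs target sampling rate, Hz.
#' @param cutoff_hz low-pass cutoff, Hz (must be < `target_fs / 2`).
#' @param order filter order.
#' @return downsampled [laminar_recording()].
#' @export
antialias_downsample <- function(recording, target_fs = 600,
                                 cutoff_hz = 300, order = 3L) {
  fs <- recording$fs_hz
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("target_fs must divide fs_hz (got factor ", factor, ")")
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(recording)
  if (cutoff_hz > target_fs / 2) {
    stop("cutoff_hz must not exceed the target Nyquist frequency")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  pad <- ceiling(20 * fs / cutoff_hz)
  keep <- seq(1L, ncol(recording$samples), by = factor)
  out <- matrix(0, nrow = nrow(recording$samples), ncol = length(keep))
  for (ch in seq_len(nrow(recording$samples))) {
    out[ch, ] <- filtfilt_padded(bf, recording$samples[ch, ], pad)[keep]
  }
  laminar_recording(out, target_fs, recording$channel_labels,
                    recording$depth_um, recording$layer_map,
                    recording$start_clock_s)
}

#' Detect artifacts on the summed absolute signal
#'
#' Flags samples where the sum over the selected channels of |x| exceeds the
#' threshold; contiguous flagged samples are merged into intervals. The
#' default threshold is mean + 8 SD of the summed-absolute signal.
#'
#' @param traces channels x samples matrix (>= 1 channel).
#' @param fs_hz sampling rate, Hz.
#' @param threshold_uv absolute threshold on the summed |x|; when NULL the
#'   mean + `auto_sd` x SD rule is used.
#' @param auto_sd SD multiplier for the automatic threshold.
#' @return data.frame with `start_s`, `end_s` (half-open, sorted, merged).
#' @export
detect_artifacts <- function(traces, fs_hz, threshold_uv = NULL,
                             auto_sd = 8) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1L)
  stopifnot(nrow(traces) >= 1L)
  s <- colSums(abs(traces))
  if (is.null(threshold_uv)) {
    threshold_uv <- mean(s) + auto_sd * stats::sd(s)
  }
  if (threshold_uv <= 0) stop("threshold_uv must be positive")
  runs <- logical_runs(s > threshold_uv)
  data.frame(start_s = (runs[, "start"] - 1) / fs_hz,
             end_s = runs[, "end"] / fs_hz)
}

#' Blank artifact intervals with the clean-signal mean
#'
#' Each interval is widened by a build-up before and a washout after, and the
#' covered samples are replaced, per channel, with the mean of the remaining
#' (unblanked) samples. Band-pass filtering needed downstream must be applied
#' before blanking to avoid step discontinuities.
#'
#' @param recording a [laminar_recording()].
#' @param artifacts data.frame with `start_s`, `end_s`.
#' @param buildup_s seconds removed before each artifact (default 0.5).
#' @param washout_s seconds removed after each artifact (default 3.5).
#' @return list with `recording` (blanked) and `blank_mask` (logical per
#'   sample, TRUE where replaced).
#' @export
blank_artifacts <- function(recording, artifacts, buildup_s = 0.5,
                            washout_s = 3.5) {
  stopifnot(buildup_s >= 0, washout_s >= 0)
  n <- ncol(recording$samples)
  fs <- recording$fs_hz
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(artifacts))) {
    a <- max(1L, as.integer(floor((artifacts$start_s[i] - buildup_s) * fs)) + 1L)
    b <- min(n, as.integer(ceiling((artifacts$end_s[i] + washout_s) * fs)))
    if (b >= a) mask[a:b] <- TRUE
  }
  if (all(mask)) stop("blanking would cover the entire recording")
  if (any(mask)) {
    for (ch in seq_len(nrow(recording$samples))) {
      m <- mean(recording$samples[ch, !mask])
      recording$samples[ch, mask] <- m
    }
  }
  list(recording = recording, blank_mask = mask)
}

#' Trim the unstable head of a recording and define time bins
#'
#' Removes the first `discard_min` minutes and returns, alongside the trimmed
#' recording, a bin-index function `bin(t) = floor(t / bin_min)` on the
#' trimmed time base.
#'
#' @param recording a [laminar_recording()].
#' @param discard_min minutes discarded at the head (default 15).
#' @param bin_min bin duration in minutes (default 45).
#' @return list with `recording` and `bin_fn` (seconds -> 0-based bin index).
#' @export
trim_and_bin <- function(recording, discard_min = 15, bin_min = 45) {
  n <- ncol(recording$samples)
  fs <- recording$fs_hz
  drop <- as.integer(round(discard_min * 60 * fs))
  if (drop >= n) stop("recording shorter than the discard window")
  if (drop > 0L) {
    recording$samples <- recording$samples[, (drop + 1L):n, drop = FALSE]
    recording$start_clock_s <- recording$start_clock_s + discard_min * 60
  }
  bin_fn <- function(t_s) as.integer(floor(t_s / (bin_min * 60)))
  list(recording = recording, bin_fn = bin_fn)
}

#' Head/tail padding needed to align recordings by time of day
#'
#' Given the start clock times and durations of several recordings, returns
#' the number of missing-value samples to prepend/append to each so all span
#' the same clock interval. Padding is reported as counts; downstream code
#' represents padded samples with an explicit NA mask.
#'
#' @param start_clock_s vector of start times-of-day, seconds.
#' @param duration_s vector of recording durations, seconds.
#' @param fs_hz sampling rate, Hz.
#' @return data.frame with `head_pad` and `tail_pad` sample counts.
#' @export
alignment_padding <- function(start_clock_s, duration_s, fs_hz) {
  stopifnot(length(start_clock_s) == length(duration_s))
  t0 <- min(start_clock_s)
  t1 <- max(start_clock_s + duration_s)
  data.frame(
    head_pad = as.integer(round((start_clock_s - t0) * fs_hz)),
    tail_pad = as.integer(round((t1 - (start_clock_s + duration_s)) * fs_hz)))
}
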