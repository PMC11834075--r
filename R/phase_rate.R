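## Slow-oscillation phase of events, cortical delta waves, bout-edge ripple
## rates and the long/short ripple-duration ratio.

#' Slow-oscillation phase over NonREM-like bouts
#'
#' The prefrontal trace is restricted to the concatenated NonREM-like bouts,
#' band-passed 0.5-4 Hz (3rd-order zero-phase Butterworth), and the analytic
#' phase is mapped to [0, 360) with the cosine convention (signal peak = 0
#' degrees, trough = 180). The concatenated phase is split back to the
#' original time base; samples outside NonREM-like bouts are NA.
#'
#' @param pfc_trace prefrontal trace.
#' @param fs_hz sampling rate, Hz.
#' @param hypnogram a [hypnogram()].
#' @param band filter band, Hz.
#' @return numeric vector of per-sample phase in degrees (NA outside
#'   NonREM-like).
#' @export
compute_so_phase <- function(pfc_trace, fs_hz, hypnogram,
                             band = c(0.5, 4)) {
  t <- (seq_along(pfc_trace) - 1) / fs_hz
  nrem <- state_at(hypnogram, t) == "NREM_like"
  if (!any(nrem)) stop("no NonREM-like samples")
  concat <- pfc_trace[nrem]
  filt <- bandpass_filter(concat, fs_hz, band, order = 3L)
  ph <- (Arg(analytic_signal(filt)) * 180 / pi) %% 360
  out <- rep(NA_real_, length(pfc_trace))
  out[nrem] <- ph
  out
}

#' Slow-oscillation phase of event peaks with circular summaries
#'
#' @param events event table from [classify_events()].
#' @param phase_deg per-sample phase from [compute_so_phase()].
#' @param fs_hz sampling rate, Hz.
#' @return list with `samples` (event_id, type, phase_deg; events without a
#'   defined phase are excluded, count reported) and `summary` (per-type
#'   circular mean direction and resultant length).
#' @export
event_phase_stats <- function(events, phase_deg, fs_hz) {
  idx <- as.integer(round(events$peak_s * fs_hz)) + 1L
  ok <- idx >= 1L & idx <= length(phase_deg)
  ph <- rep(NA_real_, nrow(events))
  ph[ok] <- phase_deg[idx[ok]]
  keep <- !is.na(ph)
  samples <- data.frame(event_id = events$event_id[keep],
                        type = events$type[keep],
                        phase_deg = ph[keep])
  summ <- do.call(rbind, lapply(split(samples$phase_deg, samples$type),
                                function(p) {
    z <- mean(exp(1i * p * pi / 180))
    data.frame(mean_deg = (Arg(z) * 180 / pi) %% 360,
               resultant = Mod(z), n = length(p))
  }))
  summ$type <- rownames(summ)
  rownames(summ) <- NULL
  list(samples = samples, summary = summ[, c("type", "mean_deg",
                                             "resultant", "n")],
       n_excluded = sum(!keep))
}

#' Detect cortical delta waves
#'
#' The trace is band-passed 1-6 Hz; candidate waves are zero-crossing
#' delimited full cycles containing a positive peak followed by a trough,
#' kept when the peak exceeds `peak_threshold`, the trough falls below
#' `trough_threshold`, and the start-to-end duration lies in
#' [`min_dur_ms`, `max_dur_ms`].
#'
#' @param pfc_trace prefrontal trace at the analysis rate.
#' @param fs_hz sampling rate, Hz.
#' @param peak_threshold_sd,trough_threshold_sd thresholds in SD of the
#'   filtered trace (defaults 2 and 1.5; per-animal overrides via
#'   `peak_threshold_uv` / `trough_threshold_uv`).
#' @param peak_threshold_uv,trough_threshold_uv absolute overrides, uV.
#' @param min_dur_ms,max_dur_ms duration bounds (defaults 150 and 550 ms).
#' @param bin_fn optional seconds -> bin index function for per-bin counts.
#' @return list with `waves` (start_s, peak_s, trough_s, end_s, duration_ms)
#'   and `bin_counts` (when `bin_fn` given).
#' @export
detect_delta_waves <- function(pfc_trace, fs_hz,
                               peak_threshold_sd = 2,
                               trough_threshold_sd = 1.5,
                               peak_threshold_uv = NULL,
                               trough_threshold_uv = NULL,
                               min_dur_ms = 150, max_dur_ms = 550,
                               bin_fn = NULL) {
  filt <- bandpass_filter(pfc_trace, fs_hz, c(1, 6), order = 3L)
  s <- stats::sd(filt)
  if (s == 0) {
    return(list(waves = data.frame(start_s = numeric(), peak_s = numeric(),
                                   trough_s = numeric(), end_s = numeric(),
                                   duration_ms = numeric()),
                bin_counts = NULL))
  }
  peak_thr <- if (is.null(peak_threshold_uv)) peak_threshold_sd * s else
    peak_threshold_uv
  trough_thr <- if (is.null(trough_threshold_uv)) -trough_threshold_sd * s
    else trough_threshold_uv
  if (peak_thr <= 0 || trough_thr >= 0) stop("degenerate thresholds")
  up <- which(filt[-length(filt)] < 0 & filt[-1L] >= 0)   # upward crossings
  rows <- list()
  if (length(up) >= 2L) {
    for (k in seq_len(length(up) - 1L)) {
      a <- up[k] + 1L; b <- up[k + 1L]
      seg <- filt[a:b]
      ip <- which.max(seg); it <- which.min(seg)
      if (it <= ip) next                      # need peak then trough
      dur_ms <- (b - a) / fs_hz * 1000
      if (seg[ip] >= peak_thr && seg[it] <= trough_thr &&
          dur_ms >= min_dur_ms && dur_ms <= max_dur_ms) {
        rows[[length(rows) + 1L]] <- data.frame(
          start_s = (a - 1L) / fs_hz,
          peak_s = (a + ip - 2L) / fs_hz,
          trough_s = (a + it - 2L) / fs_hz,
          end_s = (b - 1L) / fs_hz,
          duration_ms = dur_ms)
      }
    }
  }
  waves <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(), peak_s = numeric(),
               trough_s = numeric(), end_s = numeric(),
               duration_ms = numeric())
  bin_counts <- NULL
  if (!is.null(bin_fn) && nrow(waves)) {
    bin_counts <- as.data.frame(table(bin = bin_fn(waves$peak_s)),
                                stringsAsFactors = FALSE)
    names(bin_counts) <- c("bin_index", "n_delta_waves")
  }
  list(waves = waves, bin_counts = bin_counts)
}

#' Ripple rate at the edges of long NonREM-like bouts
#'
#' Bouts longer than `min_bout_min` are kept; ripple peaks are counted in
#' the first and last `edge_frac` of each bout and divided by the segment
#' duration.
#'
#' @param events event table (ripple-bearing types are used).
#' @param hypnogram a [hypnogram()].
#' @param min_bout_min minimum bout duration, minutes (default 15).
#' @param edge_frac edge fraction (default 0.10).
#' @return data.frame with one row per kept bout: `bout_start_s`,
#'   `bout_end_s`, `start_rate_hz`, `end_rate_hz`.
#' @export
bout_edge_ripple_rate <- function(events, hypnogram, min_bout_min = 15,
                                  edge_frac = 0.10) {
  bouts <- state_bouts(hypnogram, "NREM_like")
  bouts <- bouts[bouts$duration_s > min_bout_min * 60, , drop = FALSE]
  peaks <- events$peak_s[events$type %in% c("R", "SWR", "cSWR")]
  if (!nrow(bouts)) {
    return(data.frame(bout_start_s = numeric(), bout_end_s = numeric(),
                      start_rate_hz = numeric(), end_rate_hz = numeric()))
  }
  seg <- bouts$duration_s * edge_frac
  data.frame(
    bout_start_s = bouts$start_s, bout_end_s = bouts$end_s,
    start_rate_hz = vapply(seq_len(nrow(bouts)), function(i)
      sum(peaks >= bouts$start_s[i] &
            peaks < bouts$start_s[i] + seg[i]) / seg[i], 0),
    end_rate_hz = vapply(seq_len(nrow(bouts)), function(i)
      sum(peaks > bouts$end_s[i] - seg[i] &
            peaks <= bouts$end_s[i]) / seg[i], 0))
}

#' Long/short ripple-duration ratio
#'
#' Ratio of ripple-bearing events (R, SWR, cSWR) with duration above the
#' cutoff to those at or below it.
#'
#' @param events event table.
#' @param cutoff_ms duration cutoff, ms (default 100).
#' @return list with `ratio` (NA when undefined), `n_long`, `n_short`,
#'   `defined`.
#' @export
long_short_ratio <- function(events, cutoff_ms = 100) {
  stopifnot(cutoff_ms > 0)
  rip <- events[events$type %in% c("R", "SWR", "cSWR"), , drop = FALSE]
  dur_ms <- (rip$end_s - rip$start_s) * 1000
  n_long <- sum(dur_ms > cutoff_ms)
  n_short <- sum(dur_ms <= cutoff_ms)
  list(ratio = if (n_short > 0) n_long / n_short else NA_real_,
       n_long = n_long, n_short = n_short, defined = n_short > 0)
}
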