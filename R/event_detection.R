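## Independent detection of ripples (stratum pyramidale, 90-200 Hz) and sharp
## waves (stratum radiatum, 2-20 Hz), and overlap-based classification into
## R / SW / SWR / cSWR.

#' Detection parameters
#'
#' @param ripple_band Hz pair for the pyramidale band-pass (default 90-200).
#' @param sw_band Hz pair for the radiatum band-pass (default 2-20).
#' @param threshold_sd detection threshold in SD above (ripples) or below
#'   (sharp waves) the mean (default 5).
#' @param min_dur_ms minimum supra-threshold duration for ripples (default 50).
#' @param merge_ms ripples closer than this are one event (default 80).
#' @param boundary_frac fraction of the detection threshold defining event
#'   edges (default 0.5).
#' @param magnitude ripple detection magnitude: Hilbert envelope of the
#'   filtered trace (default) or a 10-ms sliding RMS.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(ripple_band = c(90, 200), sw_band = c(2, 20),
                             threshold_sd = 5, min_dur_ms = 50,
                             merge_ms = 80, boundary_frac = 0.5,
                             magnitude = c("hilbert", "rms")) {
  stopifnot(ripple_band[1] < ripple_band[2], sw_band[1] < sw_band[2],
            threshold_sd > 0, min_dur_ms >= 0, merge_ms >= 0,
            boundary_frac > 0, boundary_frac <= 1)
  structure(list(ripple_band = ripple_band, sw_band = sw_band,
                 threshold_sd = threshold_sd, min_dur_ms = min_dur_ms,
                 merge_ms = merge_ms, boundary_frac = boundary_frac,
                 magnitude = match.arg(magnitude)),
            class = "detection_params")
}

#' Detection and boundary levels from a magnitude trace
#'
#' `detect_level = mean + threshold_sd * SD` of the detection magnitude over
#' the valid samples; `boundary_level = boundary_frac * detect_level` (event
#' edges at half the detection threshold by default).
#'
#' @param magnitude envelope (or other detection magnitude) of the filtered
#'   trace.
#' @param threshold_sd SD multiplier.
#' @param boundary_frac edge fraction of the detection threshold.
#' @param valid logical mask of baseline samples (e.g. artifact-free
#'   NonREM-like); NULL = all.
#' @return list with `detect_level` and `boundary_level`.
#' @export
estimate_threshold <- function(magnitude, threshold_sd = 5,
                               boundary_frac = 0.5, valid = NULL) {
  m <- if (is.null(valid)) magnitude else magnitude[valid]
  if (!length(m)) stop("no valid baseline samples")
  s <- stats::sd(m)
  if (s == 0) stop("zero-variance magnitude; cannot set a threshold")
  lvl <- mean(m) + threshold_sd * s
  list(detect_level = lvl, boundary_level = boundary_frac * lvl)
}

## 10-ms sliding RMS magnitude.
sliding_rms <- function(x, fs_hz, win_ms = 10) {
  w <- max(1L, as.integer(round(win_ms / 1000 * fs_hz)))
  sq <- stats::filter(x^2, rep(1 / w, w), sides = 2)
  sq[is.na(sq)] <- x[is.na(sq)]^2
  sqrt(as.numeric(sq))
}

## Extend a supra-core interval outward to the boundary-level crossings.
extend_to_boundary <- function(mag, start, end, boundary_level) {
  while (start > 1L && mag[start - 1L] >= boundary_level) start <- start - 1L
  n <- length(mag)
  while (end < n && mag[end + 1L] >= boundary_level) end <- end + 1L
  c(start, end)
}

#' Detect ripples on a band-passed pyramidale trace
#'
#' The detection magnitude (Hilbert envelope by default) must stay above
#' `detect_level` for at least `min_dur_ms`; kept cores are extended outward
#' to the `boundary_level` crossings, and events separated by less than
#' `merge_ms` are merged. The peak is the magnitude maximum within the event.
#'
#' @param sp_trace stratum-pyramidale trace already band-passed to the ripple
#'   band.
#' @param fs_hz sampling rate, Hz.
#' @param params a [detection_params()].
#' @param valid logical baseline mask passed to [estimate_threshold()].
#' @return data.frame with `start_s`, `peak_s`, `end_s`, `peak_magnitude`.
#' @export
detect_ripples <- function(sp_trace, fs_hz, params = detection_params(),
                           valid = NULL) {
  empty <- data.frame(start_s = numeric(), peak_s = numeric(),
                      end_s = numeric(), peak_magnitude = numeric())
  if (stats::sd(sp_trace) == 0) return(empty)
  mag <- if (params$magnitude == "hilbert") Mod(analytic_signal(sp_trace))
         else sliding_rms(sp_trace, fs_hz)
  lv <- estimate_threshold(mag, params$threshold_sd, params$boundary_frac,
                           valid)
  cores <- logical_runs(mag >= lv$detect_level)
  min_n <- as.integer(round(params$min_dur_ms / 1000 * fs_hz))
  keep <- (cores[, "end"] - cores[, "start"] + 1L) >= min_n
  cores <- cores[keep, , drop = FALSE]
  if (!nrow(cores)) return(empty)
  ext <- t(apply(cores, 1L, function(r)
    extend_to_boundary(mag, r[1L], r[2L], lv$boundary_level)))
  ## merge events whose gap is below merge_ms
  gap_n <- as.integer(round(params$merge_ms / 1000 * fs_hz))
  merged <- list(ext[1L, ])
  if (nrow(ext) > 1L) {
    for (i in 2L:nrow(ext)) {
      last <- merged[[length(merged)]]
      if (ext[i, 1L] - last[2L] < gap_n) {
        merged[[length(merged)]] <- c(last[1L], max(last[2L], ext[i, 2L]))
      } else {
        merged[[length(merged) + 1L]] <- ext[i, ]
      }
    }
  }
  m <- do.call(rbind, merged)
  peak_idx <- vapply(seq_len(nrow(m)), function(i) {
    seg <- m[i, 1L]:m[i, 2L]
    seg[which.max(mag[seg])]
  }, 0L)
  data.frame(start_s = (m[, 1L] - 1L) / fs_hz,
             peak_s = (peak_idx - 1L) / fs_hz,
             end_s = (m[, 2L] - 1L) / fs_hz,
             peak_magnitude = mag[peak_idx])
}

#' Detect sharp waves on a band-passed radiatum trace
#'
#' Voltage troughs below `mean - threshold_sd * SD` of the filtered trace;
#' start/end are the threshold-crossing timestamps and the (negative) peak is
#' the minimum within the span.
#'
#' @param sr_trace stratum-radiatum trace already band-passed to 2-20 Hz.
#' @param fs_hz sampling rate, Hz.
#' @param params a [detection_params()].
#' @param valid logical baseline mask.
#' @return data.frame with `start_s`, `peak_s`, `end_s`, `trough_uv`.
#' @export
detect_sharp_waves <- function(sr_trace, fs_hz, params = detection_params(),
                               valid = NULL) {
  empty <- data.frame(start_s = numeric(), peak_s = numeric(),
                      end_s = numeric(), trough_uv = numeric())
  base <- if (is.null(valid)) sr_trace else sr_trace[valid]
  s <- stats::sd(base)
  if (s == 0) return(empty)          # flat trace: nothing to detect
  thr <- mean(base) - params$threshold_sd * s
  runs <- logical_runs(sr_trace < thr)
  if (!nrow(runs)) return(empty)
  peak_idx <- vapply(seq_len(nrow(runs)), function(i) {
    seg <- runs[i, "start"]:runs[i, "end"]
    seg[which.min(sr_trace[seg])]
  }, 0L)
  data.frame(start_s = (runs[, "start"] - 1L) / fs_hz,
             peak_s = (peak_idx - 1L) / fs_hz,
             end_s = (runs[, "end"] - 1L) / fs_hz,
             trough_uv = sr_trace[peak_idx])
}

## Overlap count of each ripple with the sharp-wave intervals, under either
## the literal two-endpoint-cases rule or plain interval intersection.
count_overlaps <- function(ripples, sws, rule = c("endpoint", "intersect")) {
  rule <- match.arg(rule)
  if (!nrow(ripples) || !nrow(sws)) {
    return(list(ripple_overlaps = integer(nrow(ripples)),
                sw_used = logical(nrow(sws))))
  }
  counts <- integer(nrow(ripples))
  used <- logical(nrow(sws))
  for (i in seq_len(nrow(ripples))) {
    a <- ripples$start_s[i]; b <- ripples$end_s[i]
    hit <- if (rule == "endpoint") {
      (sws$end_s >= a & sws$end_s <= b) | (sws$start_s >= a & sws$start_s <= b)
    } else {
      sws$start_s <= b & sws$end_s >= a
    }
    counts[i] <- sum(hit)
    used <- used | hit
  }
  list(ripple_overlaps = counts, sw_used = used)
}

#' Classify detections into R, SW, SWR and cSWR
#'
#' Per ripple, sharp-wave overlaps are counted with the two non-mutually
#' exclusive endpoint-containment cases (sharp-wave start or end inside the
#' ripple, closed intervals): 0 overlaps is an R, 1 an SWR, two or more a
#' cSWR. Sharp waves overlapping no ripple are SWs. Each record carries the
#' state at its peak and the 45-min bin index; analyses downstream keep only
#' NREM_like events. `rule = "intersect"` switches to plain interval
#' intersection (which additionally counts a sharp wave strictly containing a
#' ripple).
#'
#' @param ripples data.frame from [detect_ripples()].
#' @param sws data.frame from [detect_sharp_waves()].
#' @param hypnogram optional [hypnogram()] for state annotation.
#' @param bin_fn optional function seconds -> bin index.
#' @param rule overlap rule, `"endpoint"` (literal, default) or
#'   `"intersect"`.
#' @return data.frame with `event_id`, `type`, `start_s`, `peak_s`, `end_s`,
#'   `n_sw_overlaps`, `state`, `bin_index`.
#' @export
classify_events <- function(ripples, sws, hypnogram = NULL, bin_fn = NULL,
                            rule = c("endpoint", "intersect")) {
  rule <- match.arg(rule)
  fix <- function(df) {
    df <- df[order(df$start_s), , drop = FALSE]
    dup <- duplicated(df[, c("start_s", "end_s")])
    if (any(dup)) {
      warning("removed ", sum(dup), " duplicate interval(s)")
      df <- df[!dup, , drop = FALSE]
    }
    df
  }
  ripples <- fix(ripples)
  sws <- fix(sws)
  ov <- count_overlaps(ripples, sws, rule)
  rows <- list()
  if (nrow(ripples)) {
    type <- ifelse(ov$ripple_overlaps == 0L, "R",
                   ifelse(ov$ripple_overlaps == 1L, "SWR", "cSWR"))
    rows[[1L]] <- data.frame(type = type, start_s = ripples$start_s,
                             peak_s = ripples$peak_s, end_s = ripples$end_s,
                             n_sw_overlaps = ov$ripple_overlaps)
  }
  lone <- which(!ov$sw_used)
  if (length(lone)) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "SW", start_s = sws$start_s[lone], peak_s = sws$peak_s[lone],
      end_s = sws$end_s[lone], n_sw_overlaps = 1L)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), start_s = numeric(), peak_s = numeric(),
               end_s = numeric(), n_sw_overlaps = integer())
  ev <- ev[order(ev$start_s), , drop = FALSE]
  ev$event_id <- seq_len(nrow(ev))
  ev$state <- if (is.null(hypnogram)) rep(NA_character_, nrow(ev)) else
    state_at(hypnogram, ev$peak_s)
  ev$bin_index <- if (is.null(bin_fn)) rep(NA_integer_, nrow(ev)) else
    as.integer(bin_fn(ev$peak_s))
  rownames(ev) <- NULL
  ev[, c("event_id", "type", "start_s", "peak_s", "end_s", "n_sw_overlaps",
         "state", "bin_index")]
}

#' Run both detectors on a recording and classify
#'
#' Convenience wrapper: band-passes the stratum-pyramidale and
#' stratum-radiatum channels, estimates thresholds on artifact-free
#' NonREM-like samples when a hypnogram is given, detects, classifies.
#'
#' @param recording a [laminar_recording()] at the analysis rate.
#' @param hypnogram optional [hypnogram()].
#' @param params a [detection_params()].
#' @param bin_fn optional seconds -> bin index function.
#' @param valid optional logical mask of artifact-free samples.
#' @param rule overlap rule passed to [classify_events()].
#' @return list with `events`, `ripples`, `sws`, and the filtered traces
#'   (`sp_filtered`, `sr_filtered`).
#' @export
detect_events <- function(recording, hypnogram = NULL,
                          params = detection_params(), bin_fn = NULL,
                          valid = NULL, rule = "endpoint") {
  fs <- recording$fs_hz
  sp <- bandpass_filter(recording$samples[layer_channel(recording, "SP"), ],
                        fs, params$ripple_band)
  sr <- bandpass_filter(recording$samples[layer_channel(recording, "SR"), ],
                        fs, params$sw_band)
  base <- valid
  if (!is.null(hypnogram)) {
    t <- (seq_along(sp) - 1) / fs
    nrem <- state_at(hypnogram, t) == "NREM_like"
    base <- if (is.null(base)) nrem else base & nrem
  }
  ripples <- detect_ripples(sp, fs, params, valid = base)
  sws <- detect_sharp_waves(sr, fs, params, valid = base)
  events <- classify_events(ripples, sws, hypnogram, bin_fn, rule = rule)
  list(events = events, ripples = ripples, sws = sws,
       sp_filtered = sp, sr_filtered = sr)
}
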