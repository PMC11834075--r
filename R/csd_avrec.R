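## Current-source-density maps, AVREC time courses and delta-AVREC layer
## contrasts around detected events.

#' Extract peri-event raw windows
#'
#' Raw (unfiltered) channels x samples windows centered on each event's peak
#' (for SWR/cSWR the peak of the pyramidale-layer detection). Events too
#' close to the recording edges are skipped and counted.
#'
#' @param recording a [laminar_recording()].
#' @param events event table from [classify_events()].
#' @param window_s window length, seconds (default 6).
#' @return list with `windows` (list of channels x samples matrices),
#'   `events` (rows kept, same order) and `n_skipped`.
#' @export
extract_peri_event_windows <- function(recording, events, window_s = 6) {
  fs <- recording$fs_hz
  n <- ncol(recording$samples)
  half <- as.integer(round(window_s / 2 * fs))
  windows <- list()
  kept <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    c0 <- as.integer(round(events$peak_s[i] * fs)) + 1L
    if (c0 - half < 1L || c0 + half - 1L > n) next
    kept[i] <- TRUE
    windows[[length(windows) + 1L]] <-
      recording$samples[, (c0 - half):(c0 + half - 1L), drop = FALSE]
  }
  list(windows = windows, events = events[kept, , drop = FALSE],
       n_skipped = sum(!kept))
}

#' Current source density by second spatial difference
#'
#' `CSD_i(t) = theta_{i-1}(t) - 2 theta_i(t) + theta_{i+1}(t)` for interior
#' channels (unit-spacing normalization; sinks negative). Boundary channels
#' are dropped; Vaknin-style edge padding is available behind a flag.
#'
#' @param window channels x samples potential matrix in depth order.
#' @param vaknin pad by duplicating the edge channels so the output keeps
#'   all rows (default FALSE).
#' @return matrix with `channels - 2` rows (or `channels` with
#'   `vaknin = TRUE`).
#' @export
compute_csd <- function(window, vaknin = FALSE) {
  stopifnot(is.matrix(window))
  if (nrow(window) < 3L) stop("CSD needs at least 3 channels")
  if (vaknin) {
    window <- rbind(window[1L, ], window, window[nrow(window), ])
  }
  nch <- nrow(window)
  window[1:(nch - 2L), , drop = FALSE] -
    2 * window[2:(nch - 1L), , drop = FALSE] +
    window[3:nch, , drop = FALSE]
}

#' Average rectified CSD (AVREC)
#'
#' `AVREC(t) = mean_i |CSD_i(t)|` over the channels of the laminar profile;
#' per-layer variants average only that layer's channels.
#'
#' @param csd CSD matrix from [compute_csd()] (interior channels x samples).
#' @param layer_map layer label per CSD row (i.e. per interior channel);
#'   NULL for the overall trace only.
#' @return list with `overall` (numeric trace) and `by_layer` (named list of
#'   traces; layers without channels are omitted with a warning).
#' @export
compute_avrec <- function(csd, layer_map = NULL) {
  stopifnot(is.matrix(csd), nrow(csd) >= 1L)
  overall <- colMeans(abs(csd))
  by_layer <- list()
  if (!is.null(layer_map)) {
    stopifnot(length(layer_map) == nrow(csd))
    for (lay in unique(layer_map)) {
      idx <- which(layer_map == lay)
      by_layer[[lay]] <- colMeans(abs(csd[idx, , drop = FALSE]))
    }
  }
  list(overall = overall, by_layer = by_layer)
}

#' Mean per-layer AVREC for each event type
#'
#' Convenience aggregation: windows -> CSD -> AVREC, averaged over time and
#' events, per layer and event type.
#'
#' @param windows list of peri-event windows (see
#'   [extract_peri_event_windows()]).
#' @param types event type per window.
#' @param layer_map full per-channel layer labels (boundary channels are
#'   dropped to match the CSD rows).
#' @param center_s,half_width_s restrict the time average to peak +/- this
#'   half width (NULL = whole window).
#' @param fs_hz sampling rate (needed when restricting the window).
#' @return data.frame with `type`, `layer`, `mean_avrec`, `n_events`.
#' @export
avrec_by_type <- function(windows, types, layer_map, center_s = NULL,
                          half_width_s = NULL, fs_hz = NULL) {
  stopifnot(length(windows) == length(types))
  interior <- layer_map[2:(length(layer_map) - 1L)]
  acc <- list()
  for (i in seq_along(windows)) {
    csd <- compute_csd(windows[[i]])
    av <- compute_avrec(csd, interior)
    cols <- seq_len(ncol(csd))
    if (!is.null(half_width_s)) {
      mid <- (ncol(csd) + 1) / 2
      hw <- as.integer(round(half_width_s * fs_hz))
      cols <- max(1L, floor(mid - hw)):min(ncol(csd), ceiling(mid + hw))
    }
    for (lay in names(av$by_layer)) {
      key <- paste(types[i], lay, sep = "\r")
      acc[[key]] <- c(acc[[key]], mean(av$by_layer[[lay]][cols]))
    }
  }
  keys <- strsplit(names(acc), "\r", fixed = TRUE)
  data.frame(type = vapply(keys, `[`, "", 1L),
             layer = vapply(keys, `[`, "", 2L),
             mean_avrec = vapply(acc, mean, 0),
             n_events = vapply(acc, length, 0L),
             row.names = NULL)
}

#' Delta-AVREC relative to a reference event type
#'
#' Per layer, the absolute variant is
#' `mean AVREC(type) - mean AVREC(reference)` and the normalized variant
#' divides that difference by the reference mean. The reference rows are
#' identically zero. Both subtraction orientations are emitted
#' (`abs_delta`, and `abs_delta_ref_minus_type = -abs_delta`).
#'
#' @param avrec_table data.frame from [avrec_by_type()].
#' @param reference_type reference event type (default "SWR").
#' @return data.frame with `type`, `layer`, `abs_delta`, `norm_delta`,
#'   `abs_delta_ref_minus_type`.
#' @export
delta_avrec <- function(avrec_table, reference_type = "SWR") {
  if (!reference_type %in% avrec_table$type) {
    stop("reference type ", reference_type, " not present")
  }
  ref <- avrec_table[avrec_table$type == reference_type, ]
  ref_mean <- stats::setNames(ref$mean_avrec, ref$layer)
  out <- avrec_table
  out$abs_delta <- out$mean_avrec - ref_mean[out$layer]
  out$norm_delta <- ifelse(ref_mean[out$layer] > 0,
                           out$abs_delta / ref_mean[out$layer], NA_real_)
  if (any(ref_mean[unique(out$layer)] == 0, na.rm = TRUE)) {
    warning("zero reference AVREC in at least one layer; ",
            "normalized delta undefined there")
  }
  out$abs_delta_ref_minus_type <- -out$abs_delta
  rownames(out) <- NULL
  out[, c("type", "layer", "abs_delta", "norm_delta",
          "abs_delta_ref_minus_type")]
}
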