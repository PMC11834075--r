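## Core containers: laminar_recording (channels x samples + probe metadata)
## and hypnogram (per-epoch state labels).

#' Construct a laminar recording
#'
#' @param samples channels x samples numeric matrix, uV.
#' @param fs_hz sampling rate, Hz.
#' @param channel_labels character vector, one per channel, shallow to deep.
#' @param depth_um per-channel depth, strictly increasing.
#' @param layer_map per-channel layer label
#'   (SO/SP/SR/SLM/other/PFC_shallow/PFC_deep).
#' @param start_clock_s recording start time-of-day in seconds (alignment).
#' @return object of class `laminar_recording`.
#' @export
laminar_recording <- function(samples, fs_hz, channel_labels,
                              depth_um, layer_map, start_clock_s = 0) {
  stopifnot(is.matrix(samples), fs_hz > 0,
            nrow(samples) == length(channel_labels),
            nrow(samples) == length(depth_um),
            nrow(samples) == length(layer_map))
  if (any(diff(depth_um) <= 0)) {
    stop("depth_um must be strictly increasing with channel index")
  }
  structure(list(samples = samples, fs_hz = fs_hz,
                 channel_labels = channel_labels,
                 depth_um = depth_um, layer_map = layer_map,
                 start_clock_s = start_clock_s),
            class = "laminar_recording")
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat(sprintf("laminar_recording: %d channels x %d samples @ %g Hz (%.1f min)\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              ncol(x$samples) / x$fs_hz / 60))
  tab <- table(x$layer_map)
  cat("  layers:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

## First channel index of a layer; errors if the layer is absent.
layer_channel <- function(recording, layer) {
  idx <- which(recording$layer_map == layer)
  if (!length(idx)) stop("no channel labelled ", layer)
  idx[ceiling(length(idx) / 2)]
}

#' Construct a hypnogram
#'
#' @param labels per-epoch factor/character in NREM_like/REM_like/excluded.
#' @param epoch_s epoch duration, seconds.
#' @param pc_coords optional matrix of retained (PC1, PC2) per epoch.
#' @param explained_variance optional PC1+PC2 explained-variance fraction.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_s = 10, pc_coords = NULL,
                      explained_variance = NA_real_) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("NREM_like", "REM_like", "excluded")))
  structure(list(labels = labels, epoch_s = epoch_s,
                 start_s = (seq_along(labels) - 1) * epoch_s,
                 pc_coords = pc_coords,
                 explained_variance = explained_variance),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, c("NREM_like", "REM_like", "excluded")))
  cat(sprintf("hypnogram: %d epochs of %g s (%s)\n", length(x$labels),
              x$epoch_s,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  if (!is.na(x$explained_variance)) {
    cat(sprintf("  PC1+PC2 explained variance: %.1f%%\n",
                100 * x$explained_variance))
  }
  invisible(x)
}

#' State label at given times
#' @param hypnogram a [hypnogram()].
#' @param t_s numeric vector of times, seconds.
#' @return character vector of labels ("excluded" outside the hypnogram).
#' @export
state_at <- function(hypnogram, t_s) {
  idx <- floor(t_s / hypnogram$epoch_s) + 1
  out <- rep("excluded", length(t_s))
  ok <- idx >= 1 & idx <= length(hypnogram$labels)
  out[ok] <- hypnogram$labels[idx[ok]]
  out
}

#' Contiguous single-state bouts of a hypnogram
#' @param hypnogram a [hypnogram()].
#' @param state state label to extract bouts for.
#' @return data.frame with `start_s`, `end_s`, `duration_s`.
#' @export
state_bouts <- function(hypnogram, state = "NREM_like") {
  runs <- logical_runs(hypnogram$labels == state)
  if (!nrow(runs)) {
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_s = numeric()))
  }
  start_s <- (runs[, "start"] - 1) * hypnogram$epoch_s
  end_s <- runs[, "end"] * hypnogram$epoch_s
  data.frame(start_s = start_s, end_s = end_s,
             duration_s = end_s - start_s)
}

## Hypnogram from a ground-truth state schedule (for fixtures / oracles).
schedule_to_hypnogram <- function(schedule, duration_s, epoch_s = 10) {
  n_ep <- floor(duration_s / epoch_s)
  mid <- (seq_len(n_ep) - 0.5) * epoch_s
  lab <- rep("excluded", n_ep)
  for (i in seq_len(nrow(schedule))) {
    sel <- mid >= schedule$start_s[i] & mid < schedule$end_s[i]
    lab[sel] <- schedule$state[i]
  }
  hypnogram(lab, epoch_s)
}
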