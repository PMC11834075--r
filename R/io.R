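## On-disk interchange: little-endian float32 raw binary (channel-major) with
## a JSON sidecar, plus plain-text tables for events, ground truth and states.

#' Write a laminar recording as raw float32 + JSON sidecar
#'
#' Channel-major little-endian float32 (`<name>.dat`) and a JSON sidecar
#' (`<name>.json`) with sampling rate, channel order, depths and layer labels.
#'
#' @param recording a [laminar_recording()].
#' @param path output path without extension.
#' @return invisibly, the two file paths.
#' @export
write_recording <- function(recording, path) {
  dat <- paste0(path, ".dat")
  meta <- paste0(path, ".json")
  con <- file(dat, "wb")
  on.exit(close(con))
  ## channel-major: all samples of channel 1, then channel 2, ...
  writeBin(as.vector(t(recording$samples)), con, size = 4L,
           endian = "little")
  jsonlite::write_json(
    list(fs_hz = recording$fs_hz,
         n_channels = nrow(recording$samples),
         n_samples = ncol(recording$samples),
         channel_labels = recording$channel_labels,
         depth_um = recording$depth_um,
         layer_map = recording$layer_map,
         start_clock_s = recording$start_clock_s,
         units = "uV"),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(dat, meta))
}

#' Read a laminar recording written by [write_recording()]
#' @param path path without extension.
#' @return a [laminar_recording()].
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", size = 4L,
               n = meta$n_channels * meta$n_samples, endian = "little")
  laminar_recording(
    samples = t(matrix(x, nrow = meta$n_samples, ncol = meta$n_channels)),
    fs_hz = meta$fs_hz, channel_labels = meta$channel_labels,
    depth_um = meta$depth_um, layer_map = meta$layer_map,
    start_clock_s = if (is.null(meta$start_clock_s)) 0 else
      meta$start_clock_s)
}

#' Write ground truth tables
#' @param ground_truth the `ground_truth` element of [generate_recording()].
#' @param dir output directory.
#' @export
write_ground_truth <- function(ground_truth, dir) {
  utils::write.csv(ground_truth$events,
                   file.path(dir, "ground_truth_events.csv"),
                   row.names = FALSE)
  utils::write.table(ground_truth$state_schedule,
                     file.path(dir, "state_schedule.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write an event table as CSV
#' @param events data.frame of detected events.
#' @param path output file.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Write a hypnogram as TSV (epoch_index, start_s, label, pc1, pc2)
#' @param hyp a [hypnogram()].
#' @param path output file.
#' @export
write_hypnogram <- function(hyp, path) {
  pc <- hyp$pc_coords
  df <- data.frame(epoch_index = seq_along(hyp$labels) - 1L,
                   start_s = hyp$start_s, label = hyp$labels,
                   pc1 = if (is.null(pc)) NA_real_ else pc[, 1],
                   pc2 = if (is.null(pc)) NA_real_ else pc[, 2])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
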