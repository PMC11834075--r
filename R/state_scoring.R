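## Sleep-like state scoring: multitaper band-power features per 10-s epoch,
## PCA, 2-means clustering in the PC1-PC2 plane.

STATE_BANDS <- list(so = c(0.1, 1), delta = c(1, 3), theta = c(3, 6),
                    low_beta = c(10, 20), low_gamma = c(30, 45),
                    high_gamma = c(55, 80), ripple = c(90, 300))

#' Spectral and amplitude features per scoring epoch
#'
#' For each 10-s epoch and each area (hippocampal and prefrontal channel) the
#' multitaper PSD (time-bandwidth product 4, 7 tapers) is summed over seven
#' bands (slow oscillation 0.1-1 Hz, delta 1-3, theta 3-6, low beta 10-20,
#' low gamma 30-45, high gamma 55-80, ripple 90-300), complemented by the
#' theta/SO ratio and the epoch amplitude max|x|. Epochs whose amplitude is a
#' scaled-MAD outlier (factor 3) in either area are flagged invalid.
#'
#' @param hpc hippocampal (stratum pyramidale) trace.
#' @param pfc prefrontal trace, same length.
#' @param fs_hz sampling rate, Hz.
#' @param epoch_s epoch duration, seconds (default 10).
#' @param nw multitaper time-bandwidth product.
#' @return data.frame, one row per epoch: per-area band powers, ratios,
#'   amplitudes, and `epoch_valid`.
#' @export
compute_epoch_features <- function(hpc, pfc, fs_hz, epoch_s = 10, nw = 4) {
  stopifnot(length(hpc) == length(pfc))
  n_per <- as.integer(epoch_s * fs_hz)
  n_ep <- length(hpc) %/% n_per
  if (n_ep < 1L) stop("need at least one full epoch")
  if (length(hpc) %% n_per != 0L) {
    warning("dropping trailing partial epoch")
  }
  area_features <- function(x) {
    out <- matrix(0, nrow = n_ep, ncol = length(STATE_BANDS) + 2L)
    for (e in seq_len(n_ep)) {
      seg <- x[((e - 1L) * n_per + 1L):(e * n_per)]
      psd <- multitaper_psd(seg, fs_hz, nw = nw)
      bp <- vapply(STATE_BANDS, function(b) band_power(psd, b), 0)
      ratio <- if (bp[["so"]] > 0) bp[["theta"]] / bp[["so"]] else 0
      out[e, ] <- c(bp, ratio, max(abs(seg)))
    }
    colnames(out) <- c(names(STATE_BANDS), "theta_so_ratio", "amplitude")
    out
  }
  fh <- area_features(hpc)
  fp <- area_features(pfc)
  colnames(fh) <- paste0("hpc_", colnames(fh))
  colnames(fp) <- paste0("pfc_", colnames(fp))
  feats <- as.data.frame(cbind(fh, fp))
  ## artifact epochs are large by nature; the outlier rule is one-sided so
  ## that genuinely low-amplitude (REM-like) epochs are never discarded
  mad_out <- function(a) {
    m <- stats::median(a); s <- stats::mad(a)
    if (s == 0) rep(FALSE, length(a)) else (a - m) > 3 * s
  }
  feats$epoch_valid <- !(mad_out(feats$hpc_amplitude) |
                           mad_out(feats$pfc_amplitude))
  feats$epoch_index <- seq_len(n_ep) - 1L
  feats
}

#' Classify epochs into NonREM-like and REM-like states
#'
#' Valid-epoch features are z-scored, projected onto their first two
#' principal components, and split by 2-means (10 restarts, fixed seed). PC1
#' is sign-oriented so the slow-oscillation-power and amplitude loadings sum
#' positive; the cluster with the higher mean PC1 is labelled NREM_like.
#'
#' @param features table from [compute_epoch_features()].
#' @param seed RNG seed for k-means restarts.
#' @param epoch_s epoch duration, seconds.
#' @return a [hypnogram()] with PC coordinates and explained variance.
#' @export
classify_states <- function(features, seed = 0, epoch_s = 10) {
  fcols <- setdiff(names(features), c("epoch_valid", "epoch_index"))
  valid <- features$epoch_valid
  x <- as.matrix(features[valid, fcols])
  if (nrow(x) < 2L) stop("need at least two valid epochs")
  ## band powers and amplitudes are heavy-tailed; log-transform strictly
  ## positive features so the PCA is not dominated by a few extreme epochs
  for (j in seq_len(ncol(x))) {
    if (all(x[, j] > 0)) x[, j] <- log10(x[, j])
  }
  sds <- apply(x, 2L, stats::sd)
  if (all(sds == 0)) stop("features are constant; cannot classify")
  keep_cols <- sds > 0
  z <- scale(x[, keep_cols, drop = FALSE])
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- sum(pca$sdev[1:2]^2) / sum(pca$sdev^2)
  orient_cols <- grep("(_so$)|(_amplitude$)", colnames(z))
  if (sum(pca$rotation[orient_cols, 1]) < 0) {
    pca$rotation[, 1] <- -pca$rotation[, 1]
    pca$x[, 1] <- -pca$x[, 1]
  }
  pcs <- pca$x[, 1:2, drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(pcs, centers = 2L, nstart = 10L)
  spread <- sqrt(mean(km$withinss / km$size))
  sep <- sqrt(sum((km$centers[1, ] - km$centers[2, ])^2))
  if (min(km$size) < 2L || (spread > 0 && sep < 2 * spread)) {
    warning("degenerate clustering (poorly separated clusters); ",
            "a single state may be present")
  }
  nrem_cluster <- which.max(tapply(pcs[, 1], km$cluster, mean))
  lab_valid <- ifelse(km$cluster == nrem_cluster, "NREM_like", "REM_like")
  labels <- rep("excluded", nrow(features))
  labels[valid] <- lab_valid
  pc_full <- matrix(NA_real_, nrow = nrow(features), ncol = 2L)
  pc_full[valid, ] <- pcs
  hypnogram(labels, epoch_s = epoch_s, pc_coords = pc_full,
            explained_variance = ev)
}
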