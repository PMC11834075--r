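## Shared fixtures, memoized so several test files can reuse the same
## synthetic recordings without regenerating them.

.fx_cache <- new.env(parent = emptyenv())

fixture_sim <- function(duration_s = 600, seed = 7, ...) {
  key <- paste(duration_s, seed, paste(deparse(list(...)), collapse = ""),
               sep = "|")
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- generate_recording(
      sim_config(duration_s = duration_s, seed = seed, ...))
  }
  .fx_cache[[key]]
}

## ground-truth hypnogram (bypasses the scorer where scoring is not under test)
gt_hypnogram <- function(sim, duration_s) {
  swrlamina:::schedule_to_hypnogram(sim$ground_truth$state_schedule,
                                    duration_s)
}

## per-type recall/precision of classified NREM events against ground truth,
## peaks matched within tol_s
match_scores <- function(gt_events, det_events, type, tol_s = 0.05) {
  gtp <- gt_events$peak_s[gt_events$type == type]
  dtp <- det_events$peak_s[det_events$type == type]
  list(
    recall = if (length(gtp)) {
      mean(vapply(gtp, function(p) any(abs(dtp - p) <= tol_s), TRUE))
    } else NA_real_,
    precision = if (length(dtp)) {
      mean(vapply(dtp, function(p) any(abs(gtp - p) <= tol_s), TRUE))
    } else NA_real_)
}

## brute-force endpoint-containment oracle for ripple/sharp-wave overlap
oracle_overlap_count <- function(r_start, r_end, sw_starts, sw_ends) {
  n <- 0L
  for (k in seq_along(sw_starts)) {
    case1 <- sw_ends[k] >= r_start && sw_ends[k] <= r_end
    case2 <- sw_starts[k] >= r_start && sw_starts[k] <= r_end
    if (case1 || case2) n <- n + 1L
  }
  n
}

## amplitude of a sinusoid from its RMS over (approximately) whole cycles
tone_amplitude <- function(x) sqrt(2 * mean(x^2))
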