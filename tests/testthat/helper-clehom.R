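# Shared fixtures. Everything is generated in code; the expensive default
# study is computed once per session and reused across test files.

# small, fast configuration for unit-level checks
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(frame_px = 100L, n_benign = 2L, n_scc = 2L,
         frames_per_sequence = 3L, calibration_frames = 60L, seed = 11L),
    list(...))
  do.call(generator_config, args)
}

# brute-force pixel-loop oracle for the mean of a half-open rectangle
brute_roi_mean <- function(frame, rect) {
  acc <- 0
  n <- 0
  for (r in seq(rect[[1]] + 1, rect[[1]] + rect[[3]])) {
    for (c in seq(rect[[2]] + 1, rect[[2]] + rect[[4]])) {
      acc <- acc + frame[r, c]
      n <- n + 1
    }
  }
  acc / n
}

# sample SD with an explicit loop (denominator n - 1)
brute_sd <- function(v) {
  m <- sum(v) / length(v)
  acc <- 0
  for (x in v) acc <- acc + (x - m)^2
  sqrt(acc / (length(v) - 1))
}

# a frame whose four corner-ROI quadrants have exactly the given means
# (frame side 2 * side, ROIs tile the quadrants)
quadrant_frame <- function(means, side = 45L) {
  f <- matrix(0L, 2L * side, 2L * side)
  lo <- 1:side
  hi <- (side + 1L):(2L * side)
  f[lo, lo] <- as.integer(means[1])
  f[lo, hi] <- as.integer(means[2])
  f[hi, lo] <- as.integer(means[3])
  f[hi, hi] <- as.integer(means[4])
  f
}

# simple position-weighted checksum of a frame (collision-unlikely for the
# identity check; independent of the TIFF reader/writer)
digest_frame <- function(f) {
  v <- as.double(f)
  sprintf("%dx%d:%.0f:%.0f", nrow(f), ncol(f), sum(v),
          sum(v * seq_along(v)) %% 2^31)
}

# the default study, generated and analyzed once per test session
.study_cache <- new.env(parent = emptyenv())
default_study_report <- function() {
  if (is.null(.study_cache$report)) {
    cfg <- generator_config(seed = 20260926L)
    .study_cache$cfg <- cfg
    .study_cache$report <- run_study(cfg)
  }
  .study_cache$report
}
default_study_cfg <- function() {
  invisible(default_study_report())
  .study_cache$cfg
}
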