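#' Kinetic trace of a sequence
#'
#' The per-ROI mean-intensity time series (the "kinetic graph"): for each
#' frame, the mean gray value of each of the four corner ROIs, against
#' acquisition time `frame index / fps` (plus an optional offset for
#' sequences cut from a longer recording; time 0 is the first frame of the
#' recording).
#'
#' @param seq A [frame_sequence()].
#' @param rois A [corner_rois()] set (default: placed on `seq`'s geometry).
#' @param t0_s Time of the first frame, seconds.
#' @return An object of class `cle_kinetic_trace`: list with `times_s`
#'   (length T) and `intensity` (4 x T matrix, rows in ROI order).
#' @export
kinetic_trace <- function(seq, rois = NULL, t0_s = 0) {
  validate_frame_sequence(seq)
  if (is.null(rois)) rois <- corner_rois(frame_shape(seq), seq$pixel_size_um)
  intensity <- vapply(seq$frames, function(f) roi_means(f, rois), numeric(4))
  intensity <- matrix(intensity, nrow = 4L,
                      dimnames = list(names(rois), NULL))
  structure(list(times_s = t0_s + (seq_len(n_frames(seq)) - 1L) / seq$fps,
                 intensity = intensity,
                 sequence_id = seq$sequence_id),
            class = "cle_kinetic_trace")
}

#' @export
print.cle_kinetic_trace <- function(x, ...) {
  cat(sprintf("<cle_kinetic_trace %s> %d frames, t = [%.2f, %.2f] s\n",
              x$sequence_id, length(x$times_s), min(x$times_s),
              max(x$times_s)))
  invisible(x)
}

#' Plot a kinetic trace
#'
#' One curve per corner ROI; overlapping curves indicate homogeneous tissue,
#' diverging curves regional inhomogeneity.
#'
#' @param x A `cle_kinetic_trace`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cle_kinetic_trace <- function(x, ...) {
  graphics::matplot(x$times_s, t(x$intensity), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "ROI mean gray value",
                    main = x$sequence_id, ...)
  graphics::legend("bottomright", legend = rownames(x$intensity),
                   col = seq_len(4), lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Detect fluorescein flooding on a kinetic trace
#'
#' Finds when the dye wash-in starts and when image quality becomes adequate,
#' from the across-ROI average signal. The baseline level and noise are
#' estimated from the first `baseline_window_s` seconds. The onset is the
#' first time the signal exceeds `baseline mean + k_sigma * baseline SD` for
#' at least `sustain_frames` consecutive frames; the adequate-quality time is
#' the first time (at or after onset) the signal reaches
#' `baseline + plateau_frac * (plateau - baseline)`, with the plateau
#' estimated from the final decile of the trace. Fields are `NA` when the
#' criteria are never met.
#'
#' @param trace A [kinetic_trace()].
#' @param baseline_window_s Length of the baseline estimation window,
#'   seconds; the trace must span at least this long.
#' @param k_sigma Onset threshold in baseline SDs.
#' @param plateau_frac Fraction of the plateau rise defining adequate
#'   quality.
#' @param sustain_frames Consecutive frames required above the onset
#'   threshold.
#' @return An object of class `cle_flooding_result`: list with `onset_s`,
#'   `adequate_s` (either may be `NA`) and `baseline_level`.
#' @export
detect_flooding <- function(trace, baseline_window_s = 30, k_sigma = 3,
                            plateau_frac = 0.9, sustain_frames = 5) {
  stopifnot(inherits(trace, "cle_kinetic_trace"))
  t_s <- trace$times_s
  span <- max(t_s) - min(t_s)
  if (span < baseline_window_s)
    stop("trace spans ", round(span, 2), " s, shorter than the ",
         baseline_window_s, " s baseline window", call. = FALSE)
  avg <- colMeans(trace$intensity)
  base <- avg[t_s < min(t_s) + baseline_window_s]
  bm <- mean(base)
  bs <- sd(base)
  if (!is.finite(bs)) bs <- 0

  above <- avg > bm + k_sigma * bs
  onset_idx <- first_sustained(above, sustain_frames)
  onset_s <- if (is.na(onset_idx)) NA_real_ else t_s[onset_idx]

  nT <- length(avg)
  plateau <- mean(avg[ceiling(nT * 0.9):nT])
  adequate_s <- NA_real_
  if (plateau > bm) {
    thr <- bm + plateau_frac * (plateau - bm)
    from <- if (is.na(onset_idx)) 1L else onset_idx
    hit <- which(avg[from:nT] >= thr)
    if (length(hit)) adequate_s <- t_s[from + hit[1] - 1L]
  }
  structure(list(onset_s = onset_s, adequate_s = adequate_s,
                 baseline_level = bm),
            class = "cle_flooding_result")
}

# index of the first run of >= k consecutive TRUEs, NA if none
first_sustained <- function(flag, k) {
  if (!any(flag)) return(NA_integer_)
  r <- rle(flag)
  ok <- which(r$values & r$lengths >= k)
  if (!length(ok)) return(NA_integer_)
  sum(r$lengths[seq_len(ok[1] - 1L)]) + 1L
}

#' @export
print.cle_flooding_result <- function(x, ...) {
  cat(sprintf(
    "<cle_flooding_result> onset %s s, adequate %s s (baseline %.1f)\n",
    format(x$onset_s), format(x$adequate_s), x$baseline_level))
  invisible(x)
}
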