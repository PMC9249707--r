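#' Per-sequence homogeneity statistics
#'
#' The core summary of a 60-frame sequence: `mean_intensity` is the mean over
#' all frames and all four corner ROIs of the ROI mean gray value;
#' `mean_spread` is the mean over frames of the across-ROI sample SD
#' ([frame_spread()]), the homogeneity statistic. Also flags frames whose
#' ROI-average jumps suspiciously between frames (`qc_flags`), an advisory
#' artifact heuristic that never drops frames: a frame is flagged when the
#' absolute frame-to-frame change of the across-ROI average exceeds
#' `qc_k = 5` robust SDs (1.4826 x MAD) of all such changes in the sequence.
#'
#' @param seq A [frame_sequence()].
#' @param rois A [corner_rois()] set (default: placed on `seq`'s geometry).
#' @param qc_k Flagging threshold in robust SDs of the frame-to-frame change.
#' @return An object of class `cle_sequence_homogeneity`: list with
#'   `sequence_id`, `label`, `n_frames`, `mean_intensity`, `mean_spread`,
#'   `frame_spreads` (per-frame SDs), `call` (`"not_called"` until
#'   [classify()]), `qc_flags` (1-based frame indices).
#' @export
sequence_stats <- function(seq, rois = NULL, qc_k = 5) {
  validate_frame_sequence(seq)
  if (is.null(rois)) rois <- corner_rois(frame_shape(seq), seq$pixel_size_um)
  mu <- vapply(seq$frames, function(f) roi_means(f, rois), numeric(4))
  mu <- matrix(mu, nrow = 4L)
  spreads <- apply(mu, 2L, sd)
  avg <- colMeans(mu)

  qc_flags <- integer(0)
  if (length(avg) > 2L) {
    d <- diff(avg)
    s <- mad(d)
    if (s == 0) s <- sd(d)
    if (is.finite(s) && s > 0) qc_flags <- which(abs(d) > qc_k * s) + 1L
  }
  structure(list(sequence_id = seq$sequence_id,
                 label = seq$label,
                 n_frames = n_frames(seq),
                 mean_intensity = mean(mu),
                 mean_spread = mean(spreads),
                 frame_spreads = spreads,
                 call = "not_called",
                 qc_flags = qc_flags),
            class = "cle_sequence_homogeneity")
}

#' @export
print.cle_sequence_homogeneity <- function(x, ...) {
  cat(sprintf(
    "<cle_sequence_homogeneity %s> %d frames | mean intensity %.1f | mean spread %.2f | call: %s | %d QC flags\n",
    x$sequence_id, x$n_frames, x$mean_intensity, x$mean_spread, x$call,
    length(x$qc_flags)))
  invisible(x)
}

#' Dichotomous homogeneity call
#'
#' Calls a sequence `inhomogeneous` when its mean across-ROI spread strictly
#' exceeds the threshold, `homogeneous` otherwise (a spread exactly at the
#' threshold is homogeneous). The default threshold 70.3 is the midpoint of
#' the two published class means of the spread statistic (39.1 for benign,
#' 101.5 for SCC); [fit_threshold()] offers a Youden-optimal alternative on
#' labeled training data.
#'
#' @param stats A `cle_sequence_homogeneity` (from [sequence_stats()]) or a
#'   numeric vector of mean spreads.
#' @param threshold Gray-value cutoff on the mean spread (> 0).
#' @return The same object with `call` set, or a character vector of calls.
#' @export
#' @examples
#' classify(c(39.1, 101.5))         # homogeneous, inhomogeneous
#' classify(70.3)                   # exactly at threshold -> homogeneous
classify <- function(stats, threshold = 70.3) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (inherits(stats, "cle_sequence_homogeneity")) {
    stats$call <- classify(stats$mean_spread, threshold)
    return(stats)
  }
  ifelse(stats > threshold, "inhomogeneous", "homogeneous")
}

#' Youden-optimal spread threshold
#'
#' Scans midpoints between consecutive sorted spread values and returns the
#' threshold maximizing Youden's J = sensitivity + specificity - 1 for the
#' rule `inhomogeneous iff spread > threshold` (SCC is the positive class).
#' Ties are broken toward the smallest such threshold.
#'
#' @param spreads Numeric per-sequence mean spreads.
#' @param labels Matching `"benign"`/`"scc"` labels.
#' @return List with `threshold`, `youden_j`, `sensitivity`, `specificity`.
#' @export
fit_threshold <- function(spreads, labels) {
  stopifnot(length(spreads) == length(labels),
            all(labels %in% c("benign", "scc")),
            any(labels == "benign"), any(labels == "scc"))
  s <- sort(unique(spreads))
  cand <- if (length(s) > 1L) (head(s, -1L) + tail(s, -1L)) / 2 else s
  pos <- labels == "scc"
  j <- vapply(cand, function(th) {
    sens <- mean(spreads[pos] > th)
    spec <- mean(spreads[!pos] <= th)
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)
  th <- cand[best]
  list(threshold = th,
       youden_j = j[best],
       sensitivity = mean(spreads[pos] > th),
       specificity = mean(spreads[!pos] <= th))
}
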