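#' CLE frame sequence
#'
#' The unit of analysis: an ordered stack of 2-D gray-value frames with its
#' acquisition metadata. Frames are integer matrices sharing one shape, with
#' intensities on the 16-bit scale `[0, 65535]`.
#'
#' @param frames List of integer matrices (rows x columns), all the same
#'   shape.
#' @param pixel_size_um Pixel size, micrometres per pixel (> 0).
#' @param fps Frame rate, Hz (> 0).
#' @param label Histology label: `"benign"`, `"scc"` or `"unknown"`.
#' @param sequence_id Identifier string.
#' @param source_path Optional path the sequence was read from.
#' @param artifacts_applied Character vector of artifact kinds composited
#'   into the sequence (generator bookkeeping).
#' @return An object of class `cle_frame_sequence`.
#' @export
#' @examples
#' fs <- frame_sequence(list(matrix(7L, 2, 2)), sequence_id = "toy")
#' fs$label
frame_sequence <- function(frames, pixel_size_um = 1.0, fps = 12.0,
                           label = "unknown", sequence_id = "unnamed",
                           source_path = NULL, artifacts_applied = character(0)) {
  s <- structure(list(frames = frames,
                      pixel_size_um = pixel_size_um,
                      fps = fps,
                      label = label,
                      sequence_id = sequence_id,
                      source_path = source_path,
                      artifacts_applied = artifacts_applied),
                 class = "cle_frame_sequence")
  validate_frame_sequence(s)
  s
}

validate_frame_sequence <- function(s) {
  stopifnot(inherits(s, "cle_frame_sequence"))
  if (length(s$frames) < 1L)
    stop("a frame sequence needs at least one frame", call. = FALSE)
  shapes <- vapply(s$frames, function(f) {
    if (!is.matrix(f)) stop("frames must be 2-D matrices", call. = FALSE)
    paste(dim(f), collapse = "x")
  }, character(1))
  if (length(unique(shapes)) != 1L) {
    bad <- which(shapes != shapes[1])[1]
    stop("all frames must share one shape; frame ", bad, " is ", shapes[bad],
         " but frame 1 is ", shapes[1], call. = FALSE)
  }
  rng <- range(vapply(s$frames, function(f) range(f), numeric(2)))
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > .GRAY_MAX)
    stop("frame intensities must be finite and in [0, 65535]", call. = FALSE)
  if (s$pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  if (s$fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (!(s$label %in% c("benign", "scc", "unknown")))
    stop("label must be benign, scc or unknown", call. = FALSE)
  invisible(s)
}

#' @export
print.cle_frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<cle_frame_sequence %s> %d frames of %dx%d px, %.3g um/px, %.3g fps, label=%s\n",
    x$sequence_id, length(x$frames), d[1], d[2], x$pixel_size_um, x$fps,
    x$label))
  invisible(x)
}

#' Number of frames / frame dimension helpers
#' @param s A `cle_frame_sequence`.
#' @return `n_frames()`: integer frame count; `frame_shape()`: integer
#'   `c(rows, cols)`.
#' @export
n_frames <- function(s) length(s$frames)

#' @rdname n_frames
#' @export
frame_shape <- function(s) dim(s$frames[[1]])
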