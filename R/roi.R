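#' Corner ROI geometry
#'
#' Places four equal square regions of interest at the four corners of a
#' frame, the geometry used for the homogeneity statistic: 45x45 um squares
#' flush with the image edges (optionally inset). The ROI side in pixels is
#' the nearest integer (half away from zero) of `roi_side_um /
#' pixel_size_um`, minimum 1 px.
#'
#' Rectangles use 0-based, row-major, half-open coordinates
#' `(row0, col0, height, width)`, ordered top-left, top-right, bottom-left,
#' bottom-right.
#'
#' @param frame_shape_px Integer `c(rows, cols)` (a single number means a
#'   square frame).
#' @param pixel_size_um Micrometres per pixel.
#' @param roi_side_um ROI side length, micrometres.
#' @param inset_um Inset of each ROI from its two adjacent edges,
#'   micrometres.
#' @return An object of class `cle_roi_set`: a list of four rectangles with
#'   attributes `roi_side_um` and `inset_um`.
#' @export
#' @examples
#' corner_rois(c(240, 240), 1)   # 45 px squares at (0,0) ... (195,195)
corner_rois <- function(frame_shape_px, pixel_size_um = 1.0, roi_side_um = 45,
                        inset_um = 0) {
  if (length(frame_shape_px) == 1L) frame_shape_px <- rep(frame_shape_px, 2L)
  nr <- as.integer(frame_shape_px[1])
  nc <- as.integer(frame_shape_px[2])
  side <- roi_side_px(roi_side_um, pixel_size_um)
  inset <- as.integer(floor(inset_um / pixel_size_um + 0.5))
  if (inset < 0) stop("inset_um must be >= 0", call. = FALSE)
  if (2L * (side + inset) > nr || 2L * (side + inset) > nc)
    stop("corner ROIs of ", side, " px (+ inset ", inset,
         " px) do not fit without overlap in a ", nr, "x", nc, " frame",
         call. = FALSE)
  r0 <- inset
  r1 <- nr - side - inset
  c0 <- inset
  c1 <- nc - side - inset
  rects <- list(
    top_left = c(row0 = r0, col0 = c0, height = side, width = side),
    top_right = c(row0 = r0, col0 = c1, height = side, width = side),
    bottom_left = c(row0 = r1, col0 = c0, height = side, width = side),
    bottom_right = c(row0 = r1, col0 = c1, height = side, width = side)
  )
  structure(rects, class = "cle_roi_set", roi_side_um = roi_side_um,
            inset_um = inset_um, frame_shape_px = c(nr, nc))
}

#' Mean gray value of a rectangular ROI
#'
#' Arithmetic mean of the pixel values inside a half-open rectangle
#' `(row0, col0, height, width)` in 0-based coordinates.
#'
#' @param frame Gray-value matrix.
#' @param rect Rectangle `c(row0, col0, height, width)`.
#' @return The mean, as a double.
#' @export
#' @examples
#' roi_mean(matrix(1:4, 2, 2), c(0, 0, 2, 2))  # 2.5
roi_mean <- function(frame, rect) {
  r0 <- rect[[1]]; c0 <- rect[[2]]; h <- rect[[3]]; w <- rect[[4]]
  if (r0 < 0 || c0 < 0 || h < 1 || w < 1 ||
      r0 + h > nrow(frame) || c0 + w > ncol(frame))
    stop("rectangle (", r0, ",", c0, ",", h, ",", w,
         ") does not lie inside a ", nrow(frame), "x", ncol(frame), " frame",
         call. = FALSE)
  mean(frame[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)])
}

#' Four corner-ROI means of a frame
#'
#' @param frame Gray-value matrix.
#' @param rois A [corner_rois()] set.
#' @return Numeric vector of four means (top-left, top-right, bottom-left,
#'   bottom-right).
#' @export
roi_means <- function(frame, rois) {
  stopifnot(inherits(rois, "cle_roi_set"))
  vapply(rois, function(r) roi_mean(frame, r), numeric(1))
}

#' Across-ROI spread of a frame
#'
#' The homogeneity measure of a single frame: the sample standard deviation
#' (denominator n-1, n = 4) of the four corner-ROI mean gray values. Low for
#' regular honeycomb epithelium, high when signal varies regionally (SCC,
#' tangent probe position, motion).
#'
#' @inheritParams roi_means
#' @return The sample SD of the four ROI means.
#' @export
#' @examples
#' fr <- matrix(0L, 90, 90)
#' frame_spread(fr, corner_rois(90, 1))  # 0 for a constant frame
frame_spread <- function(frame, rois) {
  sd(roi_means(frame, rois))
}
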