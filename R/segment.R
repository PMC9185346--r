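#' Construct a gait segment
#'
#' A gait segment is an ordered sequence of skeleton frames for one
#' participant walking in one direction: per frame, 17 keypoint coordinates
#' (pixels, origin top-left, y increasing downward) and their prediction
#' confidences, plus participant/group/direction metadata.
#'
#' @param x,y numeric matrices, frames x 17, pixel coordinates.
#' @param confidence numeric matrix, frames x 17, values in \[0, 1\].
#' @param frame_index integer vector of frame numbers (0-based or as emitted
#'   by the estimator), strictly increasing.
#' @param participant_id participant identifier string.
#' @param group clinical group, one of `"EOA"`, `"DCD"`, `"CON"` or `NA`.
#' @param direction walking direction relative to the camera, `"towards"`,
#'   `"away"` or `NA`.
#' @param segment_label free-text label distinguishing segments of the same
#'   participant and direction.
#' @return An object of class `gait_segment`.
#' @export
gait_segment <- function(x, y, confidence, frame_index = seq_len(nrow(x)) - 1L,
                         participant_id = NA_character_, group = NA_character_,
                         direction = NA_character_,
                         segment_label = NA_character_) {
  x <- as.matrix(x); y <- as.matrix(y); confidence <- as.matrix(confidence)
  n <- nrow(x)
  if (ncol(x) != 17L || ncol(y) != 17L || ncol(confidence) != 17L)
    stop("x, y and confidence must have 17 columns (COCO-17 layout)",
         call. = FALSE)
  if (nrow(y) != n || nrow(confidence) != n || length(frame_index) != n)
    stop("x, y, confidence and frame_index disagree on the number of frames",
         call. = FALSE)
  if (n < 2L)
    stop("segment too short: a gait segment needs at least 2 frames",
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("keypoint coordinates must be finite", call. = FALSE)
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop("confidences must lie in [0, 1]", call. = FALSE)
  frame_index <- as.integer(frame_index)
  if (is.unsorted(frame_index, strictly = TRUE))
    stop("frame_index must be strictly increasing", call. = FALSE)
  if (!is.na(group) && !group %in% c("EOA", "DCD", "CON"))
    stop("group must be one of EOA, DCD, CON (or NA)", call. = FALSE)
  if (!is.na(direction) && !direction %in% c("towards", "away"))
    stop("direction must be 'towards' or 'away' (or NA)", call. = FALSE)
  kps <- coco_keypoints()
  colnames(x) <- colnames(y) <- colnames(confidence) <- kps
  structure(
    list(x = x, y = y, confidence = confidence, frame_index = frame_index,
         participant_id = as.character(participant_id),
         group = as.character(group), direction = as.character(direction),
         segment_label = as.character(segment_label)),
    class = "gait_segment")
}

#' @export
print.gait_segment <- function(x, ...) {
  cat("Gait segment:", n_frames(x), "frames x 17 keypoints\n")
  meta <- c(participant = x$participant_id, group = x$group,
            direction = x$direction, label = x$segment_label)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = " = ", collapse = ", "), "\n")
  cat("  frames", x$frame_index[1], "..", x$frame_index[n_frames(x)],
      "; mean confidence", round(mean(x$confidence), 3), "\n")
  invisible(x)
}

#' @export
summary.gait_segment <- function(object, ...) {
  disp <- keypoint_dispersion(object)
  cat("Gait segment summary\n")
  print(object)
  cat("\nPer-keypoint dispersion (px):\n")
  print(round(disp, 2))
  invisible(disp)
}

#' Plot keypoint trajectories of a segment
#'
#' Scatters every keypoint location across frames, one colour per keypoint,
#' in image convention (y axis pointing down). Useful for eyeballing the
#' contraction of keypoint clouds after normalization.
#'
#' @param x a `gait_segment`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gait_segment <- function(x, ...) {
  cols <- grDevices::hcl.colors(17, "Dark 3")
  graphics::plot(range(x$x), rev(range(x$y)), type = "n",
                 xlab = "x (px)", ylab = "y (px)", ylim = rev(range(x$y)), ...)
  for (k in 1:17)
    graphics::points(x$x[, k], x$y[, k], col = cols[k], pch = 16, cex = 0.4)
  invisible(x)
}

#' Number of frames in a segment
#' @param segment a `gait_segment`.
#' @return Integer frame count.
#' @export
n_frames <- function(segment) length(segment$frame_index)

#' Extract a subset of frames, keeping metadata
#' @param segment a `gait_segment`.
#' @param i logical or integer row selector.
#' @return A `gait_segment` with the selected frames.
#' @keywords internal
subset_frames <- function(segment, i) {
  gait_segment(segment$x[i, , drop = FALSE], segment$y[i, , drop = FALSE],
               segment$confidence[i, , drop = FALSE],
               segment$frame_index[i],
               segment$participant_id, segment$group, segment$direction,
               segment$segment_label)
}
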