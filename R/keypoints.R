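#' The COCO-17 keypoint layout
#'
#' Pose estimators trained on the MSCOCO body model emit 17 landmarks per
#' person in a fixed order. All containers in this package index keypoints by
#' these names (or equivalently by their 0-based COCO index).
#'
#' @return Character vector of the 17 keypoint names, in COCO output order.
#' @export
#' @examples
#' coco_keypoints()[1]   # "nose"
#' coco_keypoints()[17]  # "right_ankle"
coco_keypoints <- function() {
  c("nose",
    "left_eye", "right_eye",
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

#' Map keypoint names or 0-based COCO indices to column positions
#'
#' @param id character names (see [coco_keypoints()]) or integer 0-based
#'   indices.
#' @return Integer 1-based column positions into the 17-column layout.
#' @export
#' @examples
#' kp_index("left_shoulder")  # 6
#' kp_index(0L)               # 1 (nose)
kp_index <- function(id) {
  kps <- coco_keypoints()
  if (is.character(id)) {
    i <- match(id, kps)
    if (anyNA(i)) {
      stop("unknown keypoint name(s): ",
           paste(id[is.na(i)], collapse = ", "), call. = FALSE)
    }
    i
  } else if (is.numeric(id)) {
    i <- as.integer(id)
    if (any(i < 0L | i > 16L)) {
      stop("COCO keypoint index must be in 0..16", call. = FALSE)
    }
    i + 1L
  } else {
    stop("keypoint id must be a name or a 0-based index", call. = FALSE)
  }
}

# Column positions used throughout the geometry code.
.KP <- local({
  n <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
         "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
         "left_wrist", "right_wrist", "left_hip", "right_hip",
         "left_knee", "right_knee", "left_ankle", "right_ankle")
  stats::setNames(seq_along(n), n)
})
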