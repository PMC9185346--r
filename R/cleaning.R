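# Frame exclusion for occluded/lost body parts, and confidence summaries.

#' Frame-cleaning policy
#'
#' Frames in which body parts are occluded or lost carry unreliable
#' keypoints; they are detected through the estimator's confidence scores
#' and excluded. A frame is removed when any *required* keypoint falls below
#' `min_keypoint_confidence`, or when fewer than `min_fraction_valid` of all
#' 17 keypoints reach it.
#'
#' The defaults require the shoulders and hips — the anchors every scaling
#' method needs — at confidence 0.3, and at least half of all keypoints
#' valid.
#'
#' @param min_keypoint_confidence confidence threshold in \[0, 1\].
#' @param required_keypoints character names of keypoints that must each
#'   pass the threshold (subset of [coco_keypoints()]).
#' @param min_fraction_valid minimum fraction of the 17 keypoints at or
#'   above threshold, in \[0, 1\].
#' @return An object of class `cleaning_policy`.
#' @export
cleaning_policy <- function(min_keypoint_confidence = 0.3,
                            required_keypoints = c("left_shoulder",
                                                   "right_shoulder",
                                                   "left_hip", "right_hip"),
                            min_fraction_valid = 0.5) {
  stopifnot(min_keypoint_confidence >= 0, min_keypoint_confidence <= 1,
            min_fraction_valid >= 0, min_fraction_valid <= 1)
  req <- kp_index(required_keypoints)  # validates names
  structure(list(min_keypoint_confidence = min_keypoint_confidence,
                 required_keypoints = coco_keypoints()[req],
                 min_fraction_valid = min_fraction_valid),
            class = "cleaning_policy")
}

#' @export
print.cleaning_policy <- function(x, ...) {
  cat("Cleaning policy: confidence >=", x$min_keypoint_confidence,
      "on {", paste(x$required_keypoints, collapse = ", "), "};",
      "fraction valid >=", x$min_fraction_valid, "\n")
  invisible(x)
}

#' Exclude unusable frames from a segment
#'
#' @param segment a `gait_segment`.
#' @param policy a [cleaning_policy()].
#' @return A list with `segment` (the cleaned `gait_segment`, frame order
#'   preserved) and `removed` (the frame indices that were dropped).
#' @export
filter_frames <- function(segment, policy = cleaning_policy()) {
  stopifnot(inherits(segment, "gait_segment"),
            inherits(policy, "cleaning_policy"))
  ok <- segment$confidence >= policy$min_keypoint_confidence
  req <- kp_index(policy$required_keypoints)
  keep_req <- if (length(req)) {
    rowSums(!ok[, req, drop = FALSE]) == 0L
  } else rep(TRUE, n_frames(segment))
  keep_frac <- rowMeans(ok) >= policy$min_fraction_valid
  keep <- keep_req & keep_frac
  if (sum(keep) < 2L)
    stop("segment exhausted by cleaning: ", sum(keep),
         " frame(s) left of ", n_frames(segment), call. = FALSE)
  list(segment = subset_frames(segment, keep),
       removed = segment$frame_index[!keep])
}

#' Summarize keypoint prediction confidence
#'
#' Computes, per summary unit, the mean of all keypoint confidences (frames
#' x 17 keypoints), then the mean and SD (n-1 denominator) across units.
#' The default unit is one segment; `unit = "participant_direction"` pools
#' all segments sharing participant and walking direction, matching paired
#' before/after-cleaning comparisons at the recording level.
#'
#' @param segments a list of `gait_segment`s.
#' @param unit `"segment"` or `"participant_direction"`.
#' @return A list with `per_unit_means` (named numeric), `grand_mean` and
#'   `grand_sd`.
#' @export
likelihood_summary <- function(segments,
                               unit = c("segment", "participant_direction")) {
  unit <- match.arg(unit)
  if (inherits(segments, "gait_segment")) segments <- list(segments)
  if (length(segments) == 0L)
    stop("at least one segment is required", call. = FALSE)
  key <- vapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    if (unit == "segment") {
      paste(s$participant_id, s$direction, s$segment_label, i, sep = "/")
    } else {
      paste(s$participant_id, s$direction, sep = "/")
    }
  }, character(1))
  conf <- lapply(segments, function(s) as.vector(s$confidence))
  per_unit <- vapply(split(conf, key), function(cs) mean(unlist(cs)),
                     numeric(1))
  list(per_unit_means = per_unit,
       grand_mean = mean(per_unit),
       grand_sd = if (length(per_unit) > 1L) stats::sd(per_unit) else 0)
}
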