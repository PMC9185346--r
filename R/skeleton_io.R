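# IO for pose-estimator output (AlphaPose COCO-17 dialect), the package's
# internal segment format, and segment-annotation tables.

#' Read AlphaPose COCO-17 keypoint results
#'
#' Reads a pose-estimator result file in the AlphaPose dialect: per detection
#' an `image_id`, a flat `keypoints` array of 51 numbers (x, y, confidence
#' for each of the 17 COCO keypoints), a detection `score` and, when a
#' tracker was run, a track `idx`. Two dialects are auto-detected by the
#' top-level JSON structure: a flat detection array, or an object mapping
#' each image id to its detection array.
#'
#' `image_id` strings (image filenames) are mapped to integer frame indices
#' via the numeric stem of the filename when every id has one (so gaps in
#' the frame numbering survive), otherwise by natural-sort rank (0-based).
#' Coordinates are passed through untouched: no rounding, no axis flip.
#'
#' @param path path to the JSON file.
#' @return An object of class `alphapose_detections`: a list with vectors
#'   `frame_index`, `image_id`, `track_id`, `score` and matrices `x`, `y`,
#'   `confidence` (detections x 17).
#' @export
read_alphapose <- function(path) {
  if (!file.exists(path))
    stop("cannot read AlphaPose file: '", path, "' does not exist",
         call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(names(raw))) {
    dets <- raw
  } else {
    # grouped dialect: { "<image_id>": [det, det, ...], ... }
    dets <- list()
    for (img in names(raw)) {
      for (d in raw[[img]]) {
        if (is.null(d$image_id)) d$image_id <- img
        dets[[length(dets) + 1L]] <- d
      }
    }
  }
  n <- length(dets)
  if (n == 0L) {
    return(.alphapose_detections(integer(0), character(0), integer(0),
                                 numeric(0),
                                 matrix(numeric(0), 0, 17),
                                 matrix(numeric(0), 0, 17),
                                 matrix(numeric(0), 0, 17)))
  }
  x <- y <- conf <- matrix(NA_real_, n, 17)
  image_id <- character(n); track_id <- integer(n); score <- numeric(n)
  for (i in seq_len(n)) {
    d <- dets[[i]]
    kpts <- unlist(d$keypoints)
    if (length(kpts) != 51L)
      stop("malformed AlphaPose record ", i, " (image_id '",
           if (is.null(d$image_id)) "?" else d$image_id,
           "'): keypoints has length ", length(kpts), ", expected 51",
           call. = FALSE)
    x[i, ] <- kpts[seq(1, 51, by = 3)]
    y[i, ] <- kpts[seq(2, 51, by = 3)]
    conf[i, ] <- kpts[seq(3, 51, by = 3)]
    image_id[i] <- as.character(d$image_id)
    track_id[i] <- if (is.null(d$idx)) 1L else as.integer(d$idx)
    score[i] <- if (is.null(d$score)) NA_real_ else as.numeric(d$score)
  }
  .alphapose_detections(.image_id_to_frame(image_id), image_id,
                        track_id, score, x, y, conf)
}

.alphapose_detections <- function(frame_index, image_id, track_id, score,
                                  x, y, confidence) {
  colnames(x) <- colnames(y) <- colnames(confidence) <- coco_keypoints()
  structure(list(frame_index = frame_index, image_id = image_id,
                 track_id = track_id, score = score,
                 x = x, y = y, confidence = confidence),
            class = "alphapose_detections")
}

#' @export
print.alphapose_detections <- function(x, ...) {
  cat("AlphaPose detections:", length(x$frame_index), "records,",
      length(unique(x$frame_index)), "frames,",
      length(unique(x$track_id)), "track(s)\n")
  invisible(x)
}

# "000012.jpg" -> 12; non-numeric stems fall back to natural-sort rank.
.image_id_to_frame <- function(image_id) {
  stem <- sub("\\.[A-Za-z0-9]+$", "", image_id)
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", stem)))
  if (!anyNA(num) && all(nchar(gsub("[^0-9]", "", stem)) > 0L)) {
    as.integer(num)
  } else {
    uid <- unique(image_id)
    rank <- stats::setNames(order(order(uid)) - 1L, uid)
    as.integer(rank[image_id])
  }
}

#' Select one pose track from multi-person detections
#'
#' Keeps the detections of a single tracked person, one per frame. With
#' `track_id = "auto"` the track covering the most frames wins (ties broken
#' by higher mean detection score) — the usual case when the walking child
#' is the dominant person in frame. Duplicate detections of the chosen track
#' within one frame keep the higher-score record, with a warning.
#'
#' @param records an `alphapose_detections` object.
#' @param track_id integer track id, or `"auto"`.
#' @return An `alphapose_detections` object restricted to one track, ordered
#'   by frame.
#' @export
select_track <- function(records, track_id = "auto") {
  stopifnot(inherits(records, "alphapose_detections"))
  if (length(records$frame_index) == 0L)
    stop("no detections to select a track from", call. = FALSE)
  if (identical(track_id, "auto")) {
    per <- tapply(records$frame_index, records$track_id,
                  function(f) length(unique(f)))
    best <- names(per)[per == max(per)]
    if (length(best) > 1L) {
      ms <- vapply(best, function(tr)
        mean(records$score[records$track_id == as.integer(tr)], na.rm = TRUE),
        numeric(1))
      best <- best[which.max(ms)]
    }
    track_id <- as.integer(best[1])
  }
  keep <- which(records$track_id == track_id)
  if (length(keep) == 0L)
    stop("track ", track_id, " not present; available tracks: ",
         paste(sort(unique(records$track_id)), collapse = ", "),
         call. = FALSE)
  fi <- records$frame_index[keep]
  if (anyDuplicated(fi)) {
    warning("duplicate detections of track ", track_id,
            " in frame(s) ", paste(unique(fi[duplicated(fi)]), collapse = ", "),
            "; keeping the higher-score detection", call. = FALSE)
    ord <- order(fi, -records$score[keep])
    keep <- keep[ord][!duplicated(fi[ord])]
  } else {
    keep <- keep[order(fi)]
  }
  .alphapose_detections(records$frame_index[keep], records$image_id[keep],
                        records$track_id[keep], records$score[keep],
                        records$x[keep, , drop = FALSE],
                        records$y[keep, , drop = FALSE],
                        records$confidence[keep, , drop = FALSE])
}

#' Assemble a gait segment from single-track frames
#'
#' @param frames an `alphapose_detections` object holding one detection per
#'   frame (see [select_track()]).
#' @param participant_id,group,direction,segment_label segment metadata; see
#'   [gait_segment()].
#' @return A `gait_segment` sorted by frame index.
#' @export
assemble_segment <- function(frames, participant_id = NA_character_,
                             group = NA_character_, direction = NA_character_,
                             segment_label = NA_character_) {
  stopifnot(inherits(frames, "alphapose_detections"))
  if (length(frames$frame_index) < 2L)
    stop("segment too short: at least 2 frames are required", call. = FALSE)
  if (anyDuplicated(frames$frame_index))
    stop("duplicate frame indices; run select_track() first", call. = FALSE)
  ord <- order(frames$frame_index)
  gait_segment(frames$x[ord, , drop = FALSE], frames$y[ord, , drop = FALSE],
               frames$confidence[ord, , drop = FALSE],
               frames$frame_index[ord],
               participant_id, group, direction, segment_label)
}

#' Write a segment (or several) in the AlphaPose dialect
#'
#' Emits the flat detection-array dialect read by [read_alphapose()], with
#' `image_id` of the form `"<frame>.jpg"`, full-precision coordinates (the
#' write-then-read round trip is bit-exact) and per-detection `score` equal
#' to the mean keypoint confidence.
#'
#' @param segments one `gait_segment` or a list of them (multi-person file);
#'   track `idx` is the list position.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alphapose <- function(segments, path) {
  if (inherits(segments, "gait_segment")) segments <- list(segments)
  dets <- list()
  for (tr in seq_along(segments)) {
    seg <- segments[[tr]]
    for (i in seq_len(n_frames(seg))) {
      kpts <- as.vector(rbind(seg$x[i, ], seg$y[i, ], seg$confidence[i, ]))
      dets[[length(dets) + 1L]] <- list(
        image_id = sprintf("%d.jpg", seg$frame_index[i]),
        category_id = 1L,
        keypoints = kpts,
        score = mean(seg$confidence[i, ]),
        idx = tr)
    }
  }
  jsonlite::write_json(dets, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write / read the internal segment format
#'
#' A versioned JSON schema with explicit keypoint names, per-frame coordinate
#' arrays and a metadata header. Round trips are bit-exact on coordinates
#' and confidences.
#'
#' @param segment a `gait_segment`.
#' @param path file path.
#' @return `write_segment` returns `path` invisibly; `read_segment` returns
#'   the `gait_segment`.
#' @export
write_segment <- function(segment, path) {
  stopifnot(inherits(segment, "gait_segment"))
  obj <- list(
    format = "gaitnorm-segment",
    version = 1L,
    metadata = list(participant_id = segment$participant_id,
                    group = segment$group,
                    direction = segment$direction,
                    segment_label = segment$segment_label),
    keypoints = coco_keypoints(),
    frame_index = segment$frame_index,
    x = unname(apply(segment$x, 1, identity, simplify = FALSE)),
    y = unname(apply(segment$y, 1, identity, simplify = FALSE)),
    confidence = unname(apply(segment$confidence, 1, identity,
                              simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_segment
#' @export
read_segment <- function(path) {
  if (!file.exists(path))
    stop("cannot read segment file: '", path, "' does not exist",
         call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "gaitnorm-segment"))
    stop("'", path, "' is not a gaitnorm segment file", call. = FALSE)
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported segment format version ", obj$version, call. = FALSE)
  m <- obj$metadata
  as_chr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  gait_segment(obj$x, obj$y, obj$confidence, as.integer(obj$frame_index),
               as_chr(m$participant_id), as_chr(m$group), as_chr(m$direction),
               as_chr(m$segment_label))
}

#' Read a segment-annotation table
#'
#' The annotation CSV delimits the walking segments within each recording:
#' columns `participant_id`, `group` (EOA/DCD/CON), `direction`
#' (towards/away), `segment_label`, `start_frame`, `end_frame` (inclusive).
#'
#' @param path CSV file path.
#' @return A data frame with the six columns, types checked.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "direction", "segment_label",
            "start_frame", "end_frame")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- !ann$group %in% c("EOA", "DCD", "CON")
  if (any(bad))
    stop("annotation rows with invalid group: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  bad <- !ann$direction %in% c("towards", "away")
  if (any(bad))
    stop("annotation rows with invalid direction: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  if (any(ann$end_frame < ann$start_frame))
    stop("annotation rows with end_frame < start_frame", call. = FALSE)
  ann
}

#' Cut annotated segments out of a detection track
#'
#' @param frames single-track `alphapose_detections` (see [select_track()]).
#' @param annotations data frame from [read_annotations()] (rows for this
#'   recording).
#' @return A list of `gait_segment`s, one per annotation row.
#' @export
extract_segments <- function(frames, annotations) {
  lapply(seq_len(nrow(annotations)), function(r) {
    a <- annotations[r, ]
    keep <- frames$frame_index >= a$start_frame &
      frames$frame_index <= a$end_frame
    sub <- .alphapose_detections(frames$frame_index[keep],
                                 frames$image_id[keep],
                                 frames$track_id[keep], frames$score[keep],
                                 frames$x[keep, , drop = FALSE],
                                 frames$y[keep, , drop = FALSE],
                                 frames$confidence[keep, , drop = FALSE])
    assemble_segment(sub, a$participant_id, a$group, a$direction,
                     a$segment_label)
  })
}

#' Infer walking direction from the apparent-size trend
#'
#' A participant walking towards the camera grows in apparent size, one
#' walking away shrinks. This heuristic fits a linear trend to the
#' per-frame torso size (mean shoulder-to-opposite-hip diagonal) and reads
#' the sign of its slope. It is a convenience for unannotated data; the
#' annotation table remains the authoritative source.
#'
#' @param segment a `gait_segment`.
#' @return `"towards"` or `"away"`.
#' @export
infer_direction <- function(segment) {
  stopifnot(inherits(segment, "gait_segment"))
  size <- .frame_scales(segment, "ASH")$w
  slope <- stats::coef(stats::lm(size ~ seq_along(size)))[2]
  if (slope >= 0) "towards" else "away"
}
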