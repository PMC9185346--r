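# Two-step skeleton normalization: position shifting (mid-shoulder to the
# origin) followed by size scaling against a per-segment reference, with
# seven scaling-method variants, then recentering into image coordinates.

#' The seven scaling methods
#'
#' Four methods are anisotropic, using the width and height of a bounding
#' box: all 17 keypoints (`BoN`), the two shoulders (`S`), left shoulder and
#' right hip (`LS_RH`), or the two hips (`H`). Three are isotropic, using a
#' single Euclidean distance for both width and height: left shoulder to
#' right hip (`LS_RH_d`), shoulder midpoint to hip midpoint (`MS_MH_d`), or
#' the average of the two shoulder-to-opposite-hip diagonals (`ASH`). Only
#' the isotropic methods preserve joint angles.
#'
#' @return Character vector of the seven method names.
#' @export
norm_methods <- function() {
  c("BoN", "S", "H", "LS_RH", "LS_RH_d", "MS_MH_d", "ASH")
}

#' @keywords internal
.match_method <- function(method) {
  key <- toupper(gsub("-", "_", method))
  m <- norm_methods()[match(key, toupper(norm_methods()))]
  if (is.na(m))
    stop("unknown normalization method '", method, "'; choose one of ",
         paste(norm_methods(), collapse = ", "), call. = FALSE)
  m
}

#' Is a scaling method isotropic?
#' @param method a method name (see [norm_methods()]).
#' @return `TRUE` for the single-distance methods `LS_RH_d`, `MS_MH_d`,
#'   `ASH`; `FALSE` for the bounding-box methods.
#' @export
is_isotropic <- function(method) {
  .match_method(method) %in% c("LS_RH_d", "MS_MH_d", "ASH")
}

#' Shift each frame so the mid-shoulder point is the origin
#'
#' Subtracts the shoulder midpoint from every keypoint of every frame; the
#' shifted shoulder midpoint is exactly (0, 0). Confidences, frame indices
#' and metadata are untouched.
#'
#' @param segment a `gait_segment`.
#' @return The shifted `gait_segment`.
#' @export
position_shift <- function(segment) {
  stopifnot(inherits(segment, "gait_segment"))
  msx <- (segment$x[, .KP["left_shoulder"]] +
            segment$x[, .KP["right_shoulder"]]) / 2
  msy <- (segment$y[, .KP["left_shoulder"]] +
            segment$y[, .KP["right_shoulder"]]) / 2
  if (!all(is.finite(msx)) || !all(is.finite(msy)))
    stop("non-finite shoulder coordinates", call. = FALSE)
  out <- segment
  out$x <- segment$x - msx
  out$y <- segment$y - msy
  out
}

# Per-frame (w, h) for every frame, no degeneracy check.
.frame_scales <- function(segment, method) {
  x <- segment$x; y <- segment$y
  Ls <- .KP["left_shoulder"]; Rs <- .KP["right_shoulder"]
  Lh <- .KP["left_hip"]; Rh <- .KP["right_hip"]
  d2 <- function(xa, ya, xb, yb) sqrt((xa - xb)^2 + (ya - yb)^2)
  switch(.match_method(method),
    BoN = list(w = apply(x, 1, max) - apply(x, 1, min),
               h = apply(y, 1, max) - apply(y, 1, min)),
    S = list(w = abs(x[, Ls] - x[, Rs]), h = abs(y[, Ls] - y[, Rs])),
    LS_RH = list(w = abs(x[, Ls] - x[, Rh]), h = abs(y[, Ls] - y[, Rh])),
    H = list(w = abs(x[, Lh] - x[, Rh]), h = abs(y[, Lh] - y[, Rh])),
    LS_RH_d = {
      d <- d2(x[, Ls], y[, Ls], x[, Rh], y[, Rh])
      list(w = d, h = d)
    },
    MS_MH_d = {
      d <- d2((x[, Ls] + x[, Rs]) / 2, (y[, Ls] + y[, Rs]) / 2,
              (x[, Lh] + x[, Rh]) / 2, (y[, Lh] + y[, Rh]) / 2)
      list(w = d, h = d)
    },
    ASH = {
      d <- (d2(x[, Ls], y[, Ls], x[, Rh], y[, Rh]) +
              d2(x[, Rs], y[, Rs], x[, Lh], y[, Lh])) / 2
      list(w = d, h = d)
    })
}

#' Per-frame scale references for a segment
#'
#' Computes the scaling width and height of every frame under one method,
#' from the original (unshifted) coordinates. Degenerate frames — width or
#' height below `eps` pixels, e.g. collinear hips under the `H` method —
#' raise an error naming the method and frame.
#'
#' @param segment a `gait_segment`.
#' @param method one of [norm_methods()].
#' @param eps degeneracy guard in pixels.
#' @return A data frame with columns `frame_index`, `w`, `h` (pixels).
#' @export
frame_scale <- function(segment, method, eps = 1e-6) {
  stopifnot(inherits(segment, "gait_segment"))
  s <- .frame_scales(segment, method)
  bad <- which(s$w < eps | s$h < eps)
  if (length(bad))
    stop("degenerate frame(s) under method ", .match_method(method), ": ",
         paste(segment$frame_index[utils::head(bad, 5)], collapse = ", "),
         if (length(bad) > 5) " ..." else "",
         " (scale below ", eps, " px)", call. = FALSE)
  data.frame(frame_index = segment$frame_index, w = s$w, h = s$h)
}

#' Segment-level reference scale
#'
#' Averages the per-frame widths and heights of one segment into the
#' reference pair (`w0`, `h0`) used to rescale every frame. Frames are taken
#' from the original coordinates of this segment only (references are never
#' pooled across segments).
#'
#' @inheritParams frame_scale
#' @param on_degenerate `"error"` (default) to fail on any degenerate frame,
#'   or `"skip"` to drop such frames from both the reference and, later, the
#'   normalized output (with a warning).
#' @return An object of class `reference_scale`: `method`, `per_frame_w`,
#'   `per_frame_h`, `w0`, `h0`, and `retained` (logical per frame).
#' @export
segment_reference <- function(segment, method,
                              on_degenerate = c("error", "skip"),
                              eps = 1e-6) {
  stopifnot(inherits(segment, "gait_segment"))
  on_degenerate <- match.arg(on_degenerate)
  method <- .match_method(method)
  s <- .frame_scales(segment, method)
  retained <- s$w >= eps & s$h >= eps
  if (!all(retained)) {
    if (on_degenerate == "error") {
      frame_scale(segment, method, eps)  # raises the informative error
    }
    warning("skipping ", sum(!retained), " degenerate frame(s) under method ",
            method, call. = FALSE)
  }
  if (!any(retained))
    stop("all frames degenerate under method ", method, call. = FALSE)
  structure(list(method = method,
                 per_frame_w = s$w, per_frame_h = s$h,
                 w0 = mean(s$w[retained]), h0 = mean(s$h[retained]),
                 retained = retained),
            class = "reference_scale")
}

#' @export
print.reference_scale <- function(x, ...) {
  cat("Reference scale (", x$method, "): w0 = ", format(x$w0),
      " px, h0 = ", format(x$h0), " px over ", sum(x$retained),
      " frame(s)\n", sep = "")
  invisible(x)
}

#' Normalize a gait segment
#'
#' The full two-step normalization: each frame is shifted so its shoulder
#' midpoint sits at the origin, rescaled by the segment reference over the
#' frame scale (`w0 / w_i` horizontally, `h0 / h_i` vertically), and
#' recentred at (`x0`, `y0`). The shoulder midpoint of every output frame is
#' exactly (`x0`, `y0`); confidences, frame indices and metadata are carried
#' through unchanged. Output coordinates may fall outside the original image
#' — they are not clipped, since clipping would corrupt distances.
#'
#' @inheritParams segment_reference
#' @param x0,y0 recentering offset in pixels. The defaults (640, 200) centre
#'   the skeleton horizontally in a 1280 x 720 image with the shoulders in
#'   the upper part of the frame.
#' @return The normalized `gait_segment` (class `normalized_gait_segment`),
#'   with the `reference_scale` attached as attribute `"reference"` and the
#'   method as attribute `"method"`. Frames skipped as degenerate (under
#'   `on_degenerate = "skip"`) are absent from the output.
#' @export
#' @examples
#' seg <- simulate_gait(synthetic_gait_config(n_frames = 50, seed = 1))$segment
#' nrm <- normalize_segment(seg, "ASH")
#' attr(nrm, "reference")
normalize_segment <- function(segment, method, x0 = 640, y0 = 200,
                              on_degenerate = c("error", "skip"),
                              eps = 1e-6) {
  stopifnot(inherits(segment, "gait_segment"))
  ref <- segment_reference(segment, method, on_degenerate, eps)
  keep <- ref$retained
  seg <- if (all(keep)) segment else subset_frames(segment, keep)
  msx <- (seg$x[, .KP["left_shoulder"]] + seg$x[, .KP["right_shoulder"]]) / 2
  msy <- (seg$y[, .KP["left_shoulder"]] + seg$y[, .KP["right_shoulder"]]) / 2
  fw <- ref$w0 / ref$per_frame_w[keep]
  fh <- ref$h0 / ref$per_frame_h[keep]
  out <- gait_segment((seg$x - msx) * fw + x0, (seg$y - msy) * fh + y0,
                      seg$confidence, seg$frame_index,
                      seg$participant_id, seg$group, seg$direction,
                      seg$segment_label)
  class(out) <- c("normalized_gait_segment", class(out))
  attr(out, "method") <- ref$method
  attr(out, "reference") <- ref
  attr(out, "offset") <- c(x0 = x0, y0 = y0)
  out
}

#' @export
print.normalized_gait_segment <- function(x, ...) {
  off <- attr(x, "offset")
  cat("Normalized (", attr(x, "method"), ", recentred at ",
      off["x0"], ", ", off["y0"], ")\n", sep = "")
  NextMethod()
}
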