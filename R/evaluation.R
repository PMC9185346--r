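# Evaluation metrics for normalization quality: joint-angle preservation,
# inter-keypoint distance variance, keypoint dispersion, and group tests.

#' Undirected angle between a 2D vector and the horizontal line
#'
#' @param v numeric length-2 vector (or 2-column matrix of vectors).
#' @return Angle(s) in degrees, in \[0, 180).
#' @export
#' @examples
#' absolute_angle(c(1, 0))  # 0
#' absolute_angle(c(0, 5))  # 90
#' absolute_angle(c(1, 1))  # 45
absolute_angle <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 2)
  if (any(rowSums(abs(v)) == 0))
    stop("zero vector has no direction", call. = FALSE)
  a <- atan2(v[, 2], v[, 1]) * 180 / pi
  a <- a %% 180
  a[a >= 180] <- 0   # guard against 180 from rounding of tiny negatives
  if (length(a) == 1L) as.numeric(a) else a
}

#' Angle between two 2D vectors
#'
#' @param u,v numeric length-2 vectors (or 2-column matrices).
#' @return Angle(s) in degrees, in \[0, 180\].
#' @export
#' @examples
#' relative_angle(c(1, 0), c(0, 1))   # 90
#' relative_angle(c(1, 0), c(-1, 0))  # 180
relative_angle <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 2)
  if (is.null(dim(v))) v <- matrix(v, ncol = 2)
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  if (any(nu == 0) || any(nv == 0))
    stop("zero vector has no direction", call. = FALSE)
  cosang <- rowSums(u * v) / (nu * nv)
  a <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (length(a) == 1L) as.numeric(a) else a
}

# The evaluated angle set: 4 relative joint angles (elbows, knees) and 8
# absolute limb-vector angles against the horizontal.
.angle_names <- function() {
  c("rel_left_elbow", "rel_right_elbow", "rel_left_knee", "rel_right_knee",
    "abs_left_wrist_elbow", "abs_right_wrist_elbow",
    "abs_left_elbow_shoulder", "abs_right_elbow_shoulder",
    "abs_left_hip_knee", "abs_right_hip_knee",
    "abs_left_knee_ankle", "abs_right_knee_ankle")
}

#' Per-frame joint angles of a segment
#'
#' Computes the 12 evaluated angles for every frame: four relative angles
#' (left/right elbow, between the wrist-to-elbow and elbow-to-shoulder
#' vectors; left/right knee, between the hip-to-knee and knee-to-ankle
#' vectors) and eight absolute angles (the wrist-elbow, elbow-shoulder,
#' hip-knee and knee-ankle vectors of each side against the horizontal).
#'
#' @param segment a `gait_segment`.
#' @return Numeric matrix, frames x 12, columns named.
#' @export
segment_angles <- function(segment) {
  stopifnot(inherits(segment, "gait_segment"))
  x <- segment$x; y <- segment$y
  vec <- function(from, to) {
    cbind(x[, .KP[to]] - x[, .KP[from]], y[, .KP[to]] - y[, .KP[from]])
  }
  we_l <- vec("left_wrist", "left_elbow")
  we_r <- vec("right_wrist", "right_elbow")
  es_l <- vec("left_elbow", "left_shoulder")
  es_r <- vec("right_elbow", "right_shoulder")
  hk_l <- vec("left_hip", "left_knee")
  hk_r <- vec("right_hip", "right_knee")
  ka_l <- vec("left_knee", "left_ankle")
  ka_r <- vec("right_knee", "right_ankle")
  out <- cbind(
    relative_angle(we_l, es_l), relative_angle(we_r, es_r),
    relative_angle(hk_l, ka_l), relative_angle(hk_r, ka_r),
    absolute_angle(we_l), absolute_angle(we_r),
    absolute_angle(es_l), absolute_angle(es_r),
    absolute_angle(hk_l), absolute_angle(hk_r),
    absolute_angle(ka_l), absolute_angle(ka_r))
  colnames(out) <- .angle_names()
  out
}

#' Mean absolute angle error between two aligned segments
#'
#' For each frame and each of the 12 evaluated angles, the minimal circular
#' difference between the two segments' angles — wrapped into \[0, 90\] for
#' the undirected absolute angles and \[0, 180\] for the relative angles —
#' averaged over frames. The overall error is the mean over the 12 angles.
#' Isotropic normalization preserves all angles, so its error is zero up to
#' floating point; anisotropic scaling distorts them.
#'
#' @param before,after two `gait_segment`s with identical retained frame
#'   indices (e.g. a segment and its normalization).
#' @return A list with `per_angle` (named numeric, 12 mean absolute errors
#'   in degrees) and `overall` (their mean).
#' @export
angle_error <- function(before, after) {
  stopifnot(inherits(before, "gait_segment"), inherits(after, "gait_segment"))
  if (!identical(before$frame_index, after$frame_index))
    stop("segments are not frame-aligned; subset to common frames first",
         call. = FALSE)
  a <- segment_angles(before)
  b <- segment_angles(after)
  d <- abs(a - b)
  is_abs <- grepl("^abs_", colnames(d))
  d[, is_abs] <- pmin(d[, is_abs] %% 180, 180 - d[, is_abs] %% 180)
  per_angle <- colMeans(d)
  list(per_angle = per_angle, overall = mean(per_angle))
}

#' The four evaluated bilateral keypoint pairs
#'
#' @return Data frame with columns `name` (shoulders, wrists, hips, ankles),
#'   `left`, `right` (keypoint names).
#' @export
distance_pairs <- function() {
  data.frame(name = c("shoulders", "wrists", "hips", "ankles"),
             left = c("left_shoulder", "left_wrist", "left_hip",
                      "left_ankle"),
             right = c("right_shoulder", "right_wrist", "right_hip",
                       "right_ankle"),
             stringsAsFactors = FALSE)
}

#' Per-frame distance between a bilateral keypoint pair
#'
#' @param segment a `gait_segment`.
#' @param pair one of `"shoulders"`, `"wrists"`, `"hips"`, `"ankles"`.
#' @return Numeric vector of per-frame Euclidean distances in pixels.
#' @export
#' @examples
#' seg <- simulate_gait(synthetic_gait_config(n_frames = 30, seed = 1))$segment
#' head(pair_distance_series(seg, "shoulders"))
pair_distance_series <- function(segment, pair) {
  stopifnot(inherits(segment, "gait_segment"))
  pairs <- distance_pairs()
  p <- pairs[match(match.arg(pair, pairs$name), pairs$name), ]
  l <- .KP[p$left]; r <- .KP[p$right]
  sqrt((segment$x[, l] - segment$x[, r])^2 +
         (segment$y[, l] - segment$y[, r])^2)
}

#' Mean variance of a pair distance across segments
#'
#' Per segment, the variance of its per-frame pair distance; the returned
#' value is the mean of these variances across segments (optionally
#' restricted to one clinical group). High values on raw coordinates
#' reflect camera-distance scale change, not physiology; after good
#' normalization the shoulder and hip values collapse while wrist and ankle
#' values retain genuine movement variability.
#'
#' @param segments a `gait_segment` or list of them.
#' @param pair one of `"shoulders"`, `"wrists"`, `"hips"`, `"ankles"`.
#' @param group optional group filter (`"EOA"`, `"DCD"`, `"CON"`).
#' @param denominator `"n-1"` (sample variance, default) or `"n"`.
#' @return Mean variance in squared pixels.
#' @export
mean_distance_variance <- function(segments, pair, group = NULL,
                                   denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (inherits(segments, "gait_segment")) segments <- list(segments)
  if (!is.null(group))
    segments <- Filter(function(s) identical(s$group, group), segments)
  if (length(segments) == 0L)
    stop("no segments to summarize", call. = FALSE)
  v <- vapply(segments, function(s) {
    d <- pair_distance_series(s, pair)
    if (length(d) < 2L) return(NA_real_)
    vv <- stats::var(d)
    if (denominator == "n") vv * (length(d) - 1) / length(d) else vv
  }, numeric(1))
  if (anyNA(v)) {
    warning(sum(is.na(v)), " segment(s) with < 2 frames excluded",
            call. = FALSE)
    v <- v[!is.na(v)]
  }
  mean(v)
}

#' Mann-Whitney U test (rank-sum), exact or approximate
#'
#' U is the rank-sum statistic of `x` (midranks for ties):
#' `U = R_x - n_x (n_x + 1) / 2`. The two-sided p-value is exact — computed
#' by enumeration of the rank-sum distribution — when `n_x + n_y <= 12` and
#' there are no ties, and otherwise uses the normal approximation with tie
#' and continuity corrections.
#'
#' @param x,y numeric samples.
#' @return A list with `U`, `p`, and `exact` (logical: enumeration used).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1 (exact)
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && N <= 12L) {
    counts <- .usum_counts(nx, ny)          # frequencies of U = 0..nx*ny
    total <- sum(counts)
    u <- seq_along(counts) - 1
    lower <- sum(counts[u <= U]) / total
    upper <- sum(counts[u >= U]) / total
    p <- min(1, 2 * min(lower, upper))
    list(U = U, p = p, exact = TRUE)
  } else {
    mu <- nx * ny / 2
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma <- sqrt(nx * ny / 12 * ((N + 1) - tie_term))
    if (sigma == 0)
      stop("degenerate test: all pooled values tied", call. = FALSE)
    z <- (U - mu - 0.5 * sign(U - mu)) / sigma
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
  }
}

# Frequency table of U = sum(ranks of x) - nx(nx+1)/2 over all C(N, nx)
# tie-free rank assignments, by dynamic programming over the ranks.
.usum_counts <- function(nx, ny) {
  maxu <- nx * ny
  # f[k + 1, u + 1] = number of ways to pick k ranks so far with statistic u
  f <- matrix(0, nx + 1, maxu + 1)
  f[1, 1] <- 1
  for (v in seq_len(nx + ny)) {
    # taking rank v as an x raises U by (number of smaller ranks not in x)
    for (k in rev(seq_len(min(v, nx)))) {
      add <- v - k  # ranks below v assigned to y when this is the k-th x
      if (add <= maxu) {
        src <- f[k, seq_len(maxu + 1 - add)]
        f[k + 1, seq(add + 1, maxu + 1)] <-
          f[k + 1, seq(add + 1, maxu + 1)] + src
      }
    }
  }
  f[nx + 1, ]
}

#' Paired-samples t-test
#'
#' Thin wrapper with an explicit degenerate-input error: all-equal
#' differences have zero variance and no defined t statistic.
#'
#' @param x,y paired numeric samples of equal length (n >= 2).
#' @return A list with `t`, `df` and `p` (two-sided).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("at least 2 pairs are required", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("degenerate paired t-test: differences have zero variance",
         call. = FALSE)
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Per-keypoint location dispersion
#'
#' How widely each keypoint's location spreads across the frames of a
#' segment: SD of x, SD of y (n-1 denominator) and the RMS radius about the
#' keypoint's centroid. On raw approach-walk data the clouds are wide
#' (the skeleton shrinks/grows with camera distance); after normalization
#' each keypoint concentrates in a small region.
#'
#' @param segment a `gait_segment`.
#' @return Numeric matrix, 17 x 3 (`sd_x`, `sd_y`, `rms_radius`), rows named
#'   by keypoint, units pixels.
#' @export
keypoint_dispersion <- function(segment) {
  stopifnot(inherits(segment, "gait_segment"))
  cx <- colMeans(segment$x); cy <- colMeans(segment$y)
  dx <- sweep(segment$x, 2, cx); dy <- sweep(segment$y, 2, cy)
  out <- cbind(sd_x = apply(segment$x, 2, stats::sd),
               sd_y = apply(segment$y, 2, stats::sd),
               rms_radius = sqrt(colMeans(dx^2 + dy^2)))
  rownames(out) <- coco_keypoints()
  out
}
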