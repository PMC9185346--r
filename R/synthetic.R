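# Seeded synthetic gait generator: a canonical 17-keypoint walker in the
# body frame, pushed through a weak-perspective camera model (per-frame
# uniform scaling for camera distance, handheld translation jitter,
# additive keypoint noise, confidence scores, occlusion bursts and
# dropout). Ground truth of every applied transform is returned, so the
# normalization and evaluation stages can be tested against known answers.

#' Configuration of the synthetic walker and camera
#'
#' Canonical body proportions are in abstract units converted by
#' `px_per_unit` (the defaults give a torso-plus-legs height of about
#' 180 px at scale 1, a child-sized figure in a 1280 x 720 frame at 25 fps).
#' The camera model is weak-perspective: each frame is uniformly scaled by
#' `scale_trajectory` (default: a linear ramp `scale_start` to `scale_end`,
#' the monotone size change of walking towards or away from the camera),
#' translated by the image anchor plus handheld jitter, and perturbed with
#' Gaussian keypoint noise. Keypoint confidences emulate a pose estimator:
#' clean keypoints score high, occlusion bursts depress a subset of
#' keypoints for a stretch of frames, and dropout zeroes a confidence
#' entirely.
#'
#' The three clinical profiles differ in movement irregularity, the feature
#' the evaluation metrics are designed to retain: `EOA` has markedly larger
#' cycle-to-cycle swing-amplitude variability, per-frame limb-angle noise
#' (dysmetric limb trajectories) and lateral foot-placement irregularity
#' (wide, irregular base) than `CON`; `DCD` sits between.
#'
#' @param n_frames number of frames (>= 2).
#' @param profile `"CON"`, `"DCD"` or `"EOA"`.
#' @param seed integer seed; all randomness in the generator derives from
#'   it deterministically (per-frame and per-cycle substreams, so early
#'   frames do not change when `n_frames` grows).
#' @param frame_rate frames per second.
#' @param image_width,image_height image resolution in pixels.
#' @param shoulder_width,hip_width,trunk_length,upper_arm,lower_arm,thigh,shank
#'   canonical body proportions, units.
#' @param px_per_unit pixel size of one canonical unit at scale 1.
#' @param arm_swing_deg,leg_swing_deg base lateral swing amplitudes.
#' @param swing_frequency_hz gait cycle frequency.
#' @param torso_roll_deg amplitude of the sinusoidal torso roll.
#' @param amplitude_variability SD of the per-cycle swing-amplitude
#'   multiplier (default by profile: CON 0.05, DCD 0.15, EOA 0.35).
#' @param angle_noise_deg per-frame SD of limb-angle noise (default by
#'   profile: CON 1, DCD 2.5, EOA 6).
#' @param step_irregularity SD of the per-cycle lateral foot-placement
#'   offset, units (default by profile: CON 0.03, DCD 0.08, EOA 0.18).
#' @param swing_scale multiplier on both swing amplitudes — dysmetric,
#'   enlarged limb excursions (default by profile: CON 1.0, DCD 1.1,
#'   EOA 1.3).
#' @param scale_start,scale_end endpoints of the default linear scale ramp.
#' @param scale_trajectory optional explicit per-frame positive scale
#'   factors (overrides the ramp).
#' @param jitter_sd handheld camera translation jitter SD, pixels.
#' @param noise_sd additive keypoint noise SD, pixels.
#' @param dropout_rate per-keypoint-per-frame probability of dropout
#'   (confidence 0).
#' @param occlusion_rate per-frame probability of an occlusion burst
#'   (several keypoints at very low confidence).
#' @param confidence_mean,confidence_sd clean-keypoint confidence model
#'   (clamped to \[0, 1\]).
#' @return An object of class `synthetic_gait_config`.
#' @export
synthetic_gait_config <- function(n_frames = 100,
                                  profile = c("CON", "DCD", "EOA"),
                                  seed = 1L,
                                  frame_rate = 25,
                                  image_width = 1280, image_height = 720,
                                  shoulder_width = 2.0, hip_width = 1.4,
                                  trunk_length = 3.0,
                                  upper_arm = 1.4, lower_arm = 1.3,
                                  thigh = 1.8, shank = 1.7,
                                  px_per_unit = 28,
                                  arm_swing_deg = 20, leg_swing_deg = 25,
                                  swing_frequency_hz = 1.0,
                                  torso_roll_deg = 4,
                                  amplitude_variability = NULL,
                                  angle_noise_deg = NULL,
                                  step_irregularity = NULL,
                                  swing_scale = NULL,
                                  scale_start = 1, scale_end = 2,
                                  scale_trajectory = NULL,
                                  jitter_sd = 2, noise_sd = 1,
                                  dropout_rate = 0.02,
                                  occlusion_rate = 0.12,
                                  confidence_mean = 0.90,
                                  confidence_sd = 0.05) {
  profile <- match.arg(profile)
  defaults <- list(CON = c(amp = 0.05, ang = 1.0, step = 0.03, swing = 1.0),
                   DCD = c(amp = 0.15, ang = 2.5, step = 0.08, swing = 1.1),
                   EOA = c(amp = 0.35, ang = 6.0, step = 0.18,
                           swing = 1.3))[[profile]]
  if (is.null(amplitude_variability)) amplitude_variability <- defaults["amp"]
  if (is.null(angle_noise_deg)) angle_noise_deg <- defaults["ang"]
  if (is.null(step_irregularity)) step_irregularity <- defaults["step"]
  if (is.null(swing_scale)) swing_scale <- defaults["swing"]
  cfg <- list(n_frames = as.integer(n_frames), profile = profile,
              seed = as.integer(seed), frame_rate = frame_rate,
              image_width = image_width, image_height = image_height,
              shoulder_width = shoulder_width, hip_width = hip_width,
              trunk_length = trunk_length, upper_arm = upper_arm,
              lower_arm = lower_arm, thigh = thigh, shank = shank,
              px_per_unit = px_per_unit,
              arm_swing_deg = arm_swing_deg, leg_swing_deg = leg_swing_deg,
              swing_frequency_hz = swing_frequency_hz,
              torso_roll_deg = torso_roll_deg,
              amplitude_variability = unname(amplitude_variability),
              angle_noise_deg = unname(angle_noise_deg),
              step_irregularity = unname(step_irregularity),
              swing_scale = unname(swing_scale),
              scale_start = scale_start, scale_end = scale_end,
              scale_trajectory = scale_trajectory,
              jitter_sd = jitter_sd, noise_sd = noise_sd,
              dropout_rate = dropout_rate, occlusion_rate = occlusion_rate,
              confidence_mean = confidence_mean,
              confidence_sd = confidence_sd)
  .validate_config(cfg)
  structure(cfg, class = "synthetic_gait_config")
}

.validate_config <- function(cfg) {
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  lens <- c(cfg$shoulder_width, cfg$hip_width, cfg$trunk_length,
            cfg$upper_arm, cfg$lower_arm, cfg$thigh, cfg$shank,
            cfg$px_per_unit, cfg$frame_rate, cfg$swing_frequency_hz)
  if (any(lens <= 0)) stop("body proportions and rates must be positive",
                           call. = FALSE)
  sds <- c(cfg$jitter_sd, cfg$noise_sd, cfg$amplitude_variability,
           cfg$angle_noise_deg, cfg$step_irregularity)
  if (any(sds < 0)) stop("noise SDs must be non-negative", call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1 ||
      cfg$occlusion_rate < 0 || cfg$occlusion_rate > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  traj <- .scale_trajectory(cfg)
  if (length(traj) != cfg$n_frames || any(traj <= 0))
    stop("scale_trajectory must be n_frames strictly positive factors",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.synthetic_gait_config <- function(x, ...) {
  cat("Synthetic gait config:", x$n_frames, "frames,", x$profile,
      "profile, seed", x$seed, "\n")
  cat("  scale", x$scale_start, "->", x$scale_end,
      "| jitter", x$jitter_sd, "px | noise", x$noise_sd,
      "px | dropout", x$dropout_rate, "\n")
  invisible(x)
}

.scale_trajectory <- function(cfg) {
  if (!is.null(cfg$scale_trajectory)) return(cfg$scale_trajectory)
  seq(cfg$scale_start, cfg$scale_end, length.out = cfg$n_frames)
}

# Deterministic substream: draws tied to (seed, stream id), independent of
# how many draws other streams made. Keeps early frames stable when
# n_frames grows and makes runs bit-reproducible.
.sub_rnorm <- function(seed, id, n, mean = 0, sd = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed((abs(seed) * 48271 + id) %% 2147483647L)
  stats::rnorm(n, mean, sd)
}

.sub_runif <- function(seed, id, n, min = 0, max = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed((abs(seed) * 48271 + id) %% 2147483647L)
  stats::runif(n, min, max)
}

#' Generate the canonical (body-frame) walking pose sequence
#'
#' Builds the walker before any camera effect: a rigid torso (constant
#' shoulder and hip widths) rolling gently side to side, arms and legs
#' swinging laterally as damped sinusoids with per-cycle amplitude
#' variability, per-frame limb-angle noise and per-cycle foot-placement
#' offsets according to the clinical profile. Coordinates are in pixels at
#' scale 1, image convention (y down), mid-shoulder near the origin.
#'
#' @param config a [synthetic_gait_config()].
#' @return A list with matrices `x`, `y` (frames x 17, columns named).
#' @export
make_walker <- function(config) {
  stopifnot(inherits(config, "synthetic_gait_config"))
  cfg <- config
  n <- cfg$n_frames
  t <- (seq_len(n) - 1L) / cfg$frame_rate
  phase <- 2 * pi * cfg$swing_frequency_hz * t
  cycle <- floor(cfg$swing_frequency_hz * t)  # 0-based gait cycle index
  ppu <- cfg$px_per_unit
  deg <- pi / 180

  # per-cycle amplitude multipliers and foot offsets, one substream per
  # (cycle, limb) so they are stable under n_frames changes
  amp_mult <- function(limb_id) {
    vapply(cycle, function(c)
      max(0.1, 1 + .sub_rnorm(cfg$seed, 101L + 8L * c + limb_id, 1) *
            cfg$amplitude_variability), numeric(1))
  }
  foot_off <- function(limb_id) {
    vapply(cycle, function(c)
      .sub_rnorm(cfg$seed, 601L + 8L * c + limb_id, 1) *
        cfg$step_irregularity, numeric(1))
  }
  ang_noise <- function(limb_id) {
    .sub_rnorm(cfg$seed, 901L + limb_id, n) * cfg$angle_noise_deg * deg
  }

  x <- matrix(0, n, 17); y <- matrix(0, n, 17)
  colnames(x) <- colnames(y) <- coco_keypoints()
  K <- .KP

  # rigid torso in the body frame, then rolled about the torso centroid
  roll <- cfg$torso_roll_deg * deg * sin(phase)
  torso <- list(
    left_shoulder = c(cfg$shoulder_width / 2, 0),
    right_shoulder = c(-cfg$shoulder_width / 2, 0),
    left_hip = c(cfg$hip_width / 2, cfg$trunk_length),
    right_hip = c(-cfg$hip_width / 2, cfg$trunk_length))
  ctr <- c(0, cfg$trunk_length / 2)
  for (kp in names(torso)) {
    p <- torso[[kp]] - ctr
    x[, K[kp]] <- (cos(roll) * p[1] - sin(roll) * p[2] + ctr[1]) * ppu
    y[, K[kp]] <- (sin(roll) * p[1] + cos(roll) * p[2] + ctr[2]) * ppu
  }

  # head, rigid with the shoulder line
  head <- list(nose = c(0, -0.8), left_eye = c(0.15, -0.95),
               right_eye = c(-0.15, -0.95), left_ear = c(0.35, -0.85),
               right_ear = c(-0.35, -0.85))
  for (kp in names(head)) {
    p <- head[[kp]] - ctr
    x[, K[kp]] <- (cos(roll) * p[1] - sin(roll) * p[2] + ctr[1]) * ppu
    y[, K[kp]] <- (sin(roll) * p[1] + cos(roll) * p[2] + ctr[2]) * ppu
  }

  # limbs: pendulum chains hanging from their anchor, swinging laterally
  chain <- function(anchor_x, anchor_y, len1, len2, a1, a2,
                    mid_kp, end_kp) {
    x[, K[mid_kp]] <<- anchor_x + len1 * ppu * sin(a1)
    y[, K[mid_kp]] <<- anchor_y + len1 * ppu * cos(a1)
    x[, K[end_kp]] <<- x[, K[mid_kp]] + len2 * ppu * sin(a2)
    y[, K[end_kp]] <<- y[, K[mid_kp]] + len2 * ppu * cos(a2)
  }
  arm_amp <- cfg$arm_swing_deg * deg * cfg$swing_scale
  leg_amp <- cfg$leg_swing_deg * deg * cfg$swing_scale

  aL <- arm_amp * amp_mult(0L) * sin(phase) + ang_noise(0L)
  chain(x[, K["left_shoulder"]], y[, K["left_shoulder"]],
        cfg$upper_arm, cfg$lower_arm, aL, 1.3 * aL + ang_noise(1L),
        "left_elbow", "left_wrist")
  aR <- arm_amp * amp_mult(2L) * sin(phase + pi) + ang_noise(2L)
  chain(x[, K["right_shoulder"]], y[, K["right_shoulder"]],
        cfg$upper_arm, cfg$lower_arm, aR, 1.3 * aR + ang_noise(3L),
        "right_elbow", "right_wrist")

  lL <- leg_amp * amp_mult(4L) * sin(phase + pi) + ang_noise(4L) +
    foot_off(4L)
  chain(x[, K["left_hip"]], y[, K["left_hip"]],
        cfg$thigh, cfg$shank, lL, 0.8 * lL + ang_noise(5L) + foot_off(5L),
        "left_knee", "left_ankle")
  lR <- leg_amp * amp_mult(6L) * sin(phase) + ang_noise(6L) + foot_off(6L)
  chain(x[, K["right_hip"]], y[, K["right_hip"]],
        cfg$thigh, cfg$shank, lR, 0.8 * lR + ang_noise(7L) + foot_off(7L),
        "right_knee", "right_ankle")

  list(x = x, y = y)
}

#' Project a canonical pose sequence through the camera model
#'
#' Applies, per frame: uniform scaling by the scale trajectory (camera
#' distance), translation to the image anchor plus handheld jitter, and
#' additive Gaussian keypoint noise. Draws confidence scores (occlusion
#' bursts depress a random subset of keypoints; dropout sets confidence to
#' exactly 0) and records every applied transform as ground truth.
#'
#' @param canonical list with `x`, `y` matrices from [make_walker()].
#' @param config the same [synthetic_gait_config()].
#' @return A list with `segment` (a `gait_segment`, group = profile) and
#'   `truth` (class `synthetic_gait_truth`: `canonical`, `applied_scales`,
#'   `applied_jitter` (frames x 2), `dropout_mask`, `occluded_frames`).
#' @export
project_to_camera <- function(canonical, config) {
  stopifnot(inherits(config, "synthetic_gait_config"))
  cfg <- config
  n <- nrow(canonical$x)
  scl <- .scale_trajectory(cfg)
  anchor <- c(cfg$image_width / 2, cfg$image_height * 0.35)
  jit <- cbind(.sub_rnorm(cfg$seed, 2001L, n, sd = cfg$jitter_sd),
               .sub_rnorm(cfg$seed, 2002L, n, sd = cfg$jitter_sd))
  x <- canonical$x * scl + anchor[1] + jit[, 1]
  y <- canonical$y * scl + anchor[2] + jit[, 2]
  x <- x + matrix(.sub_rnorm(cfg$seed, 3001L, n * 17, sd = cfg$noise_sd),
                  n, 17, byrow = TRUE)
  y <- y + matrix(.sub_rnorm(cfg$seed, 3002L, n * 17, sd = cfg$noise_sd),
                  n, 17, byrow = TRUE)

  conf <- matrix(pmin(1, pmax(0, .sub_rnorm(cfg$seed, 4001L, n * 17,
                                            mean = cfg$confidence_mean,
                                            sd = cfg$confidence_sd))),
                 n, 17, byrow = TRUE)
  occluded <- .sub_runif(cfg$seed, 5001L, n) < cfg$occlusion_rate
  for (i in which(occluded)) {
    hit <- order(.sub_runif(cfg$seed, 5100L + i, 17))[1:8]
    conf[i, hit] <- .sub_runif(cfg$seed, 5600L + i, 8, 0, 0.25)
  }
  dropout <- matrix(.sub_runif(cfg$seed, 6001L, n * 17) < cfg$dropout_rate,
                    n, 17, byrow = TRUE)
  conf[dropout] <- 0

  seg <- gait_segment(x, y, conf, seq_len(n) - 1L,
                      participant_id = sprintf("sim-%s-%d", cfg$profile,
                                               cfg$seed),
                      group = cfg$profile,
                      direction = if (utils::tail(scl, 1) >= scl[1])
                        "towards" else "away",
                      segment_label = "synthetic")
  truth <- structure(list(canonical = canonical, applied_scales = scl,
                          applied_jitter = jit, dropout_mask = dropout,
                          occluded_frames = which(occluded) - 1L),
                     class = "synthetic_gait_truth")
  list(segment = seg, truth = truth)
}

#' Simulate a full synthetic gait segment
#'
#' Convenience wrapper: [make_walker()] then [project_to_camera()].
#'
#' @param config a [synthetic_gait_config()].
#' @return A list with `segment` and `truth`; see [project_to_camera()].
#' @export
#' @examples
#' sim <- simulate_gait(synthetic_gait_config(n_frames = 60, seed = 42))
#' sim$segment
simulate_gait <- function(config) {
  project_to_camera(make_walker(config), config)
}
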