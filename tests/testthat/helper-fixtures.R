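# Small in-code fixtures shared across test files.

# A segment from per-frame keypoint coordinate lists. Unspecified keypoints
# sit on a generic non-degenerate default pose.
fixture_segment <- function(frames, conf = 0.9, ...) {
  base <- default_pose()
  n <- length(frames)
  x <- matrix(rep(base$x, each = n), n, 17)
  y <- matrix(rep(base$y, each = n), n, 17)
  colnames(x) <- colnames(y) <- coco_keypoints()
  for (i in seq_len(n)) {
    for (kp in names(frames[[i]])) {
      x[i, kp] <- frames[[i]][[kp]][1]
      y[i, kp] <- frames[[i]][[kp]][2]
    }
  }
  gait_segment(x, y, matrix(conf, n, 17), ...)
}

# Generic asymmetric pose: bilateral keypoints are clearly offset in both
# axes (as in a tilted skeleton), so no scaling method is near-degenerate
# even after perturbation.
default_pose <- function() {
  list(x = c(50, 47, 53, 44, 56, 38, 64, 33, 69, 30, 74, 42, 60, 40, 63,
             39, 65),
       y = c(10, 7, 8, 9, 11, 22, 32, 45, 47, 62, 64, 68, 80, 95, 97,
             118, 127))
}

# Random non-degenerate segments for property-style tests.
random_segment <- function(n = 8, seed = 1) {
  set.seed(seed)
  base <- default_pose()
  x <- matrix(rep(base$x, each = n), n, 17) + matrix(rnorm(n * 17, sd = 2.5),
                                                     n, 17)
  y <- matrix(rep(base$y, each = n), n, 17) + matrix(rnorm(n * 17, sd = 2.5),
                                                     n, 17)
  gait_segment(x, y, matrix(runif(n * 17, 0.5, 1), n, 17))
}

# Clean simulator settings: camera effects off unless asked for.
quiet_config <- function(...) {
  synthetic_gait_config(noise_sd = 0, jitter_sd = 0, dropout_rate = 0,
                        occlusion_rate = 0, ...)
}
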