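# The two-step normalization and its seven scaling methods.

# reference pose for the scale examples: shoulders at y = 0, hips 4 below
scale_pose <- function() {
  fixture_segment(list(
    list(left_shoulder = c(0, 0), right_shoulder = c(2, 0),
         left_hip = c(0, -4), right_hip = c(2, -4)),
    list(left_shoulder = c(0, 0), right_shoulder = c(2, 0),
         left_hip = c(0, -4), right_hip = c(2, -4))))
}

test_that("position shifting puts the mid-shoulder point at the origin", {
  seg <- fixture_segment(list(
    list(left_shoulder = c(4, 2), right_shoulder = c(6, 2),
         nose = c(5, 6)),
    list(left_shoulder = c(4, 2), right_shoulder = c(6, 2),
         nose = c(5, 6))))
  sh <- position_shift(seg)
  expect_equal(unname(sh$x[1, "nose"]), 0)
  expect_equal(unname(sh$y[1, "nose"]), 4)
  ms <- c((sh$x[1, "left_shoulder"] + sh$x[1, "right_shoulder"]) / 2,
          (sh$y[1, "left_shoulder"] + sh$y[1, "right_shoulder"]) / 2)
  expect_equal(unname(ms), c(0, 0))

  # already-centred poses are a fixed point; random poses centre to ~0
  expect_equal(position_shift(sh)$x, sh$x)
  for (sd in 1:5) {
    r <- position_shift(random_segment(6, seed = sd))
    msn <- sqrt(((r$x[, "left_shoulder"] + r$x[, "right_shoulder"]) / 2)^2 +
                  ((r$y[, "left_shoulder"] + r$y[, "right_shoulder"]) / 2)^2)
    expect_lt(max(msn), 1e-12)
  }
  # confidences untouched
  expect_identical(sh$confidence, seg$confidence)
})

test_that("frame scales match hand geometry for each method", {
  seg <- scale_pose()
  expect_equal(frame_scale(seg, "LS_RH_d")$w[1], sqrt(20))
  expect_equal(frame_scale(seg, "LS_RH_d")$h[1], sqrt(20))
  expect_equal(frame_scale(seg, "MS_MH_d")$w[1], 4)
  expect_equal(frame_scale(seg, "ASH")$w[1], sqrt(20))
  expect_equal(frame_scale(seg, "LS_RH")$w[1], 2)
  expect_equal(frame_scale(seg, "LS_RH")$h[1], 4)
  # collinear hips: the H method height degenerates
  expect_error(frame_scale(seg, "H"), "degenerate frame.*H")
  # level shoulders: so does the S height
  expect_error(frame_scale(seg, "S"), "degenerate frame.*S")
  # with a tilted shoulder line S recovers both extents
  tilted <- fixture_segment(list(
    list(left_shoulder = c(0, 0), right_shoulder = c(2, 1)),
    list(left_shoulder = c(0, 0), right_shoulder = c(2, 1))))
  expect_equal(frame_scale(tilted, "S")$w[1], 2)
  expect_equal(frame_scale(tilted, "S")$h[1], 1)
})

test_that("bounding-box scale spans all 17 keypoints", {
  seg <- random_segment(5, seed = 9)
  fs <- frame_scale(seg, "BoN")
  expect_equal(fs$w, apply(seg$x, 1, function(r) diff(range(r))))
  expect_equal(fs$h, apply(seg$y, 1, function(r) diff(range(r))))
})

test_that("ASH equals the mean of the two diagonals (independent oracle)", {
  for (sd in 1:50) {
    seg <- random_segment(2, seed = 100 + sd)
    got <- frame_scale(seg, "ASH")$w
    d1 <- sqrt((seg$x[, "left_shoulder"] - seg$x[, "right_hip"])^2 +
                 (seg$y[, "left_shoulder"] - seg$y[, "right_hip"])^2)
    d2 <- sqrt((seg$x[, "right_shoulder"] - seg$x[, "left_hip"])^2 +
                 (seg$y[, "right_shoulder"] - seg$y[, "left_hip"])^2)
    expect_equal(got, (d1 + d2) / 2)
  }
})

test_that("the segment reference is the frame mean, on original coordinates", {
  # two frames whose ASH sizes differ by a factor: w0 is their mean
  seg <- random_segment(2, seed = 42)
  seg$x[2, ] <- seg$x[1, ] * 2; seg$y[2, ] <- seg$y[1, ] * 2
  fs <- frame_scale(seg, "ASH")
  ref <- segment_reference(seg, "ASH")
  expect_equal(ref$w0, mean(fs$w))
  expect_equal(ref$w0, fs$w[1] * 1.5)

  # constant segment: w0 equals every frame scale
  cseg <- scale_pose()
  refc <- segment_reference(cseg, "ASH")
  expect_equal(refc$per_frame_w, rep(refc$w0, 2))

  # rigid torso under a known scale ramp: w0 = d * mean(ramp), closed form
  cfg <- quiet_config(n_frames = 40, seed = 13, arm_swing_deg = 0,
                      leg_swing_deg = 0, torso_roll_deg = 0,
                      angle_noise_deg = 0, amplitude_variability = 0,
                      step_irregularity = 0, scale_start = 1, scale_end = 2)
  sim <- simulate_gait(cfg)
  ramp <- seq(1, 2, length.out = 40)
  d <- frame_scale(sim$segment, "ASH")$w[1]  # scale_1 = 1 exactly
  expect_equal(segment_reference(sim$segment, "ASH")$w0, d * mean(ramp))
})

test_that("normalization recentres the shoulder midpoint exactly", {
  seg <- scale_pose()
  nrm <- normalize_segment(seg, "ASH")
  expect_equal(unname(nrm$x[1, ]), unname(nrm$x[2, ]))
  msx <- (nrm$x[, "left_shoulder"] + nrm$x[, "right_shoulder"]) / 2
  msy <- (nrm$y[, "left_shoulder"] + nrm$y[, "right_shoulder"]) / 2
  expect_equal(unname(msx), c(640, 640))
  expect_equal(unname(msy), c(200, 200))
})

test_that("frames differing by a similarity transform normalize identically", {
  base <- random_segment(2, seed = 77)
  base$x[2, ] <- base$x[1, ] * 2 + 30
  base$y[2, ] <- base$y[1, ] * 2 - 10
  for (m in c("LS_RH_d", "MS_MH_d", "ASH")) {
    nrm <- normalize_segment(base, m)
    expect_lt(max(abs(nrm$x[1, ] - nrm$x[2, ])), 1e-9)
    expect_lt(max(abs(nrm$y[1, ] - nrm$y[2, ])), 1e-9)
  }
})

test_that("each method anchors its own reference distance at (w0, h0)", {
  seg <- random_segment(6, seed = 5)
  for (m in norm_methods()) {
    ref <- segment_reference(seg, m)
    nrm <- normalize_segment(seg, m)
    after <- frame_scale(nrm, m)
    expect_lt(max(abs(after$w - ref$w0)), 1e-9)
    expect_lt(max(abs(after$h - ref$h0)), 1e-9)
  }
})

test_that("normalization is idempotent for every method", {
  for (sd in 1:5) {
    seg <- random_segment(6, seed = 200 + sd)
    for (m in norm_methods()) {
      once <- normalize_segment(seg, m)
      twice <- normalize_segment(once, m)
      expect_lt(max(abs(once$x - twice$x)), 1e-9)
      expect_lt(max(abs(once$y - twice$y)), 1e-9)
    }
  }
})

test_that("per-frame scale and position variability is removed exactly", {
  # per-frame similarity transforms can only change the segment's global
  # size unit (w0, h0 rescale with the applied factors); after matching
  # that unit the outputs coincide
  match_unit <- function(a, b, x0 = 640, y0 = 200) {
    ra <- attr(a, "reference"); rb <- attr(b, "reference")
    list(x = (b$x - x0) * ra$w0 / rb$w0 + x0,
         y = (b$y - y0) * ra$h0 / rb$h0 + y0)
  }
  set.seed(303)
  seg <- random_segment(6, seed = 303)
  pert <- seg
  s <- runif(6, 0.5, 3)
  tx <- runif(6, -50, 50); ty <- runif(6, -50, 50)
  pert$x <- seg$x * s + tx
  pert$y <- seg$y * s + ty
  for (m in norm_methods()) {
    a <- normalize_segment(seg, m)
    b <- match_unit(a, normalize_segment(pert, m))
    expect_lt(max(abs(a$x - b$x)), 1e-9)
    expect_lt(max(abs(a$y - b$y)), 1e-9)
  }
  # box methods additionally shrug off independent x/y scalings
  sx <- runif(6, 0.5, 2); sy <- runif(6, 0.5, 2)
  aniso <- seg
  aniso$x <- seg$x * sx; aniso$y <- seg$y * sy
  for (m in c("BoN", "S", "H", "LS_RH")) {
    a <- normalize_segment(seg, m)
    b <- match_unit(a, normalize_segment(aniso, m))
    expect_lt(max(abs(a$x - b$x)), 1e-9)
    expect_lt(max(abs(a$y - b$y)), 1e-9)
  }
})

test_that("confidences, frame indices and metadata pass through unchanged", {
  sim <- simulate_gait(synthetic_gait_config(n_frames = 20, seed = 31,
                                             profile = "DCD"))
  nrm <- normalize_segment(sim$segment, "MS_MH_d")
  expect_identical(nrm$confidence, sim$segment$confidence)
  expect_identical(nrm$frame_index, sim$segment$frame_index)
  expect_identical(nrm$group, "DCD")
  expect_identical(nrm$segment_label, sim$segment$segment_label)
})

test_that("degenerate frames follow the configured policy", {
  seg <- random_segment(5, seed = 61)
  # force one frame's hips level: H height collapses there
  seg$y[3, "left_hip"] <- seg$y[3, "right_hip"]
  expect_error(normalize_segment(seg, "H"), "degenerate frame")
  expect_warning(nrm <- normalize_segment(seg, "H", on_degenerate = "skip"),
                 "skipping 1")
  expect_equal(n_frames(nrm), 4)
  expect_false(seg$frame_index[3] %in% nrm$frame_index)
  # reference excludes the skipped frame
  ref <- suppressWarnings(segment_reference(seg, "H", "skip"))
  expect_equal(ref$w0, mean(ref$per_frame_w[-3]))

  flat <- scale_pose()
  expect_error(suppressWarnings(segment_reference(flat, "H", "skip")),
               "all frames degenerate")
})
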