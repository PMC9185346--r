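# Angle metrics, distance variance, dispersion and the statistical tests.

test_that("absolute and relative angles follow plane geometry", {
  expect_equal(absolute_angle(c(1, 0)), 0)
  expect_equal(absolute_angle(c(0, 5)), 90)
  expect_equal(absolute_angle(c(1, 1)), 45)
  expect_equal(absolute_angle(c(-1, -1)), 45)   # undirected
  expect_error(absolute_angle(c(0, 0)), "zero vector")

  expect_equal(relative_angle(c(2, 3), c(2, 3)), 0)
  expect_equal(relative_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(relative_angle(c(1, 0), c(-1, 0)), 180)
  expect_error(relative_angle(c(1, 0), c(0, 0)), "zero vector")
})

test_that("angle error is zero on identity and symmetric in its arguments", {
  seg <- random_segment(6, seed = 14)
  expect_equal(angle_error(seg, seg)$overall, 0)

  other <- random_segment(6, seed = 15)
  ab <- angle_error(seg, other)
  ba <- angle_error(other, seg)
  expect_equal(ab$per_angle, ba$per_angle)

  misaligned <- random_segment(5, seed = 16)
  expect_error(angle_error(seg, misaligned), "not frame-aligned")
})

test_that("isotropic normalization preserves every angle; anisotropic does not", {
  sim <- simulate_gait(synthetic_gait_config(n_frames = 40, seed = 17))
  for (m in c("LS_RH_d", "MS_MH_d", "ASH")) {
    nrm <- normalize_segment(sim$segment, m)
    expect_lt(angle_error(sim$segment, nrm)$overall, 1e-9)
  }

  # doubling y turns a 45-degree limb vector into arctan(2) = 63.4349...
  seg <- fixture_segment(list(
    list(left_wrist = c(0, 0), left_elbow = c(1, 1)),
    list(left_wrist = c(0, 0), left_elbow = c(1, 1))))
  squashed <- seg
  squashed$y <- seg$y * 2
  err <- angle_error(seg, squashed)
  expect_equal(unname(err$per_angle["abs_left_wrist_elbow"]),
               atan(2) * 180 / pi - 45, tolerance = 1e-6)
})

test_that("absolute-angle errors wrap so near-horizontal vectors stay close", {
  # 179 deg vs 1 deg is a 2-degree difference, not 178
  a <- fixture_segment(list(list(left_wrist = c(0, 0),
                                 left_elbow = c(100, 1.7455)),
                            list(left_wrist = c(0, 0),
                                 left_elbow = c(100, 1.7455))))
  b <- fixture_segment(list(list(left_wrist = c(0, 0),
                                 left_elbow = c(-100, 1.7455)),
                            list(left_wrist = c(0, 0),
                                 left_elbow = c(-100, 1.7455))))
  err <- angle_error(a, b)
  expect_lt(unname(err$per_angle["abs_left_wrist_elbow"]), 2.1)
})

test_that("pair distances and their mean variance match hand values", {
  seg <- fixture_segment(list(
    list(left_shoulder = c(0, 0), right_shoulder = c(3, 4)),
    list(left_shoulder = c(1, 1), right_shoulder = c(1, 1))))
  d <- pair_distance_series(seg, "shoulders")
  expect_equal(d, c(5, 0))

  runs <- fixture_segment(list(
    list(left_shoulder = c(0, 0), right_shoulder = c(2, 0)),
    list(left_shoulder = c(0, 0), right_shoulder = c(4, 0)),
    list(left_shoulder = c(0, 0), right_shoulder = c(6, 0))))
  expect_equal(mean_distance_variance(list(runs), "shoulders"), 4)
  expect_equal(mean_distance_variance(list(runs), "shoulders",
                                      denominator = "n"), 8 / 3)

  const <- fixture_segment(list(
    list(left_shoulder = c(0, 0), right_shoulder = c(2, 0)),
    list(left_shoulder = c(5, 5), right_shoulder = c(7, 5))))
  expect_equal(mean_distance_variance(list(const, const), "shoulders"), 0)

  # translating every pose cannot change distance variance
  shifted <- runs
  shifted$x <- runs$x + 123.4
  shifted$y <- runs$y - 77.7
  expect_equal(mean_distance_variance(list(shifted), "shoulders"), 4)

  # group filter
  runs$group <- "EOA"; const$group <- "CON"
  expect_equal(mean_distance_variance(list(runs, const), "shoulders",
                                      group = "EOA"), 4)
})

test_that("Mann-Whitney U matches enumeration on the textbook cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_true(r$exact)

  # fully interleaved, symmetric: U at the centre, p = 1
  r2 <- mann_whitney_u(c(1, 4, 5, 8), c(2, 3, 6, 7))
  expect_equal(r2$U, 8)
  expect_equal(r2$p, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("random tie-free cases agree with brute force and wilcox.test", {
  set.seed(18)
  for (rep in 1:200) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1000, nx + ny)  # distinct -> tie-free
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    got <- mann_whitney_u(x, y)
    # brute force over all C(nx+ny, nx) labelings of the pooled values
    pooled <- c(x, y)
    idx <- utils::combn(nx + ny, nx)
    us <- apply(idx, 2, function(ii)
      sum(rank(pooled)[ii]) - nx * (nx + 1) / 2)
    p_bf <- min(1, 2 * min(mean(us <= got$U), mean(us >= got$U)))
    expect_equal(got$p, p_bf)
    expect_equal(got$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("the normal approximation tracks the exact p for moderate samples", {
  # exhaustive over every tie-free configuration with both sample sizes
  # >= 5 in the exact regime
  worst <- 0
  for (nx in 5:7) {
    for (ny in 5:7) {
      if (nx + ny > 12) next
      N <- nx + ny
      cnt <- gaitnorm:::.usum_counts(nx, ny)
      u <- 0:(nx * ny)
      for (U in 0:(nx * ny)) {
        p_exact <- min(1, 2 * min(sum(cnt[u <= U]),
                                  sum(cnt[u >= U])) / sum(cnt))
        mu <- nx * ny / 2
        sigma <- sqrt(nx * ny * (N + 1) / 12)
        z <- (U - mu - 0.5 * sign(U - mu)) / sigma
        p_approx <- min(1, 2 * stats::pnorm(-abs(z)))
        worst <- max(worst, abs(p_exact - p_approx))
      }
    }
  }
  expect_lt(worst, 0.02)
})

test_that("ties push the test onto the corrected normal approximation", {
  x <- c(1, 2, 2, 3, 5, 7, 9)
  y <- c(2, 4, 4, 6, 6, 8, 10)
  got <- mann_whitney_u(x, y)
  expect_false(got$exact)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("paired t matches the closed form and flags degenerate input", {
  y <- c(10, 20, 30)
  x <- y + c(1, 2, 3)
  r <- paired_t(x, y)
  expect_equal(r$t, 2 * sqrt(3))
  expect_equal(r$df, 2)

  expect_error(paired_t(y, y), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")

  sym <- paired_t(c(0, 1, 2), c(1, 1, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
})

test_that("keypoint dispersion measures spread about the centroid", {
  const <- fixture_segment(list(list(), list(), list()))
  expect_true(all(keypoint_dispersion(const) == 0))

  seg <- fixture_segment(list(list(nose = c(0, 0)), list(nose = c(2, 0))))
  disp <- keypoint_dispersion(seg)
  expect_equal(unname(disp["nose", "sd_x"]), sqrt(2))
  expect_equal(unname(disp["nose", "sd_y"]), 0)
  expect_equal(unname(disp["nose", "rms_radius"]), 1)

  # normalization concentrates torso keypoints on an approach walk
  sim <- simulate_gait(synthetic_gait_config(n_frames = 80, seed = 23,
                                             scale_start = 1,
                                             scale_end = 2.5))
  before <- keypoint_dispersion(sim$segment)
  after <- keypoint_dispersion(normalize_segment(sim$segment, "ASH"))
  torso <- c("left_shoulder", "right_shoulder", "left_hip", "right_hip")
  expect_true(all(after[torso, "rms_radius"] < before[torso, "rms_radius"]))
})
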