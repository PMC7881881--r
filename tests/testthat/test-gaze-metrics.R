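test_that("heatmap peaks at a lone sample and conserves mass", {
  tr <- gaze_trajectory(1 / 60, 480, 360)
  hm <- compute_heatmap(tr, sigma = 10)
  peak <- which(hm$grid == max(hm$grid), arr.ind = TRUE)
  expect_equal(unname(peak[1L, ]), c(361L, 481L))  # row = y + 1, col = x + 1
  expect_equal(sum(hm$grid), 1, tolerance = 1e-9)
})

test_that("two distant samples split the mass evenly", {
  tr <- gaze_trajectory(c(1, 2) / 60, c(430, 530), c(360, 360))
  hm <- compute_heatmap(tr, sigma = 10)
  expect_equal(sum(hm$grid), 1, tolerance = 1e-9)
  # oracle: direct summation of the two truncated discretized kernels
  xs <- 0:959; ys <- 0:719
  kern_at <- function(cx, cy) {
    kx <- exp(-(xs - cx)^2 / 200); kx[abs(xs - cx) > 40] <- 0
    ky <- exp(-(ys - cy)^2 / 200); ky[abs(ys - cy) > 40] <- 0
    outer(ky, kx)
  }
  oracle <- kern_at(430, 360) + kern_at(530, 360)
  oracle <- oracle / sum(oracle)
  expect_lt(max(abs(hm$grid - oracle)), 1e-12)
  # mass within 30 px of each sample is equal (one kernel each)
  dist_to <- function(cx, cy) outer((ys - cy)^2, (xs - cx)^2, "+")
  m1 <- sum(hm$grid[dist_to(430, 360) <= 900])
  m2 <- sum(hm$grid[dist_to(530, 360) <= 900])
  expect_equal(m1, m2, tolerance = 1e-3)
  expect_gt(m1, 0.49)
  # two local maxima at the two sample positions
  expect_equal(hm$grid[361, 431], max(hm$grid[, 1:480]))
  expect_equal(hm$grid[361, 531], max(hm$grid[, 481:960]))
})

test_that("invalid samples are excluded and zero valid samples error", {
  tr <- gaze_trajectory(c(1, 2) / 60, c(100, 800), c(100, 600),
                        valid = c(TRUE, FALSE))
  hm <- compute_heatmap(tr, 10)
  expect_gt(sum(hm$grid[1:200, 1:200]), 0.99)
  tr2 <- gaze_trajectory(c(1, 2) / 60, c(100, 800), c(100, 600),
                         valid = c(FALSE, FALSE))
  expect_error(compute_heatmap(tr2, 10), "no valid samples")
})

test_that("spatial entropy matches closed forms and bounds", {
  g <- matrix(0, 2, 2); g[1:4] <- 0.25
  expect_identical(spatial_entropy(g), 2)
  point <- matrix(c(1, 0, 0, 0), 2)
  expect_identical(spatial_entropy(point), 0)
  # permutation invariance
  set.seed(1)
  p <- runif(64); p <- p / sum(p)
  expect_equal(spatial_entropy(matrix(p, 8)),
               spatial_entropy(matrix(sample(p), 8)), tolerance = 1e-12)
  # bounds on a random map
  expect_lte(spatial_entropy(matrix(p, 8)), log2(64))
  expect_error(spatial_entropy(matrix(0.3, 2, 2)), "not normalized")
})

test_that("single-kernel entropy equals high-precision direct summation", {
  tr <- gaze_trajectory(1 / 60, 480, 360)
  hm <- compute_heatmap(tr, sigma = 10)
  p <- hm$grid[hm$grid > 0]
  oracle <- -sum(p * log(p)) / log(2)
  expect_equal(spatial_entropy(hm), oracle, tolerance = 1e-9)
  expect_equal(oracle, 10.74, tolerance = 0.05)  # ~ log2(2*pi*e*sigma^2)
})

test_that("a stationary trajectory yields one long fixation", {
  tr <- stationary_traj(n = 600L)  # 10 s at 60 Hz
  fs <- segment_fixations(tr)
  expect_equal(nrow(fs$fixations), 1L)
  expect_equal(fs$fixations$duration_ms, 10000, tolerance = 0.01)
  expect_equal(nrow(fs$saccades), 0L)
})

test_that("a single jump between two clusters yields two fixations and one saccade", {
  set.seed(2)
  n <- 120L
  x <- c(rnorm(n, 300, 1), rnorm(n, 500, 1))
  y <- c(rnorm(n, 360, 1), rnorm(n, 360, 1))
  tr <- gaze_trajectory((seq_len(2L * n) - 1L) / 60, x, y)
  fs <- segment_fixations(tr)
  expect_equal(nrow(fs$fixations), 2L)
  expect_equal(nrow(fs$saccades), 1L)
  expect_equal(fs$saccades$amplitude_px, 200, tolerance = 5)
})

test_that("segmentation is invariant to uniform spatial translation", {
  set.seed(3)
  hmm <- two_state_hmm()
  ses <- simulate_gaze(hmm, session_config(dropout_fraction = 0),
                       seed = 3, duration = 60)
  tr <- ses$traj
  tr2 <- gaze_trajectory(tr$t_s, tr$x_px + 40, tr$y_px - 30,
                         image_dims = c(1200L, 900L))
  fs1 <- segment_fixations(tr)
  fs2 <- segment_fixations(tr2)
  expect_equal(fs1$fixations$start_s, fs2$fixations$start_s)
  expect_equal(fs1$fixations$x_px + 40, fs2$fixations$x_px, tolerance = 1e-9)
  expect_equal(fs1$saccades$amplitude_px, fs2$saccades$amplitude_px,
               tolerance = 1e-9)
})

test_that("fixations never span an invalid run longer than 75 ms", {
  n <- 600L
  valid <- rep(TRUE, n)
  valid[290:310] <- FALSE   # 350 ms gap
  tr <- gaze_trajectory((seq_len(n) - 1L) / 60, rep(480, n), rep(360, n),
                        valid = valid)
  fs <- segment_fixations(tr)
  expect_equal(nrow(fs$fixations), 2L)
  expect_true(all(fs$fixations$end_s <= (289 - 1) / 60 + 1e-9 |
                    fs$fixations$start_s >= (311 - 1) / 60 - 1e-9))
  expect_error(segment_fixations(
    gaze_trajectory(1:3 / 60, rep(1, 3), rep(1, 3), valid = rep(FALSE, 3))),
    "valid samples")
})

test_that("known fixation onsets are recovered from a synthetic session", {
  hmm <- default_gaze_hmm()
  cfg <- session_config(dropout_fraction = 0)
  ses <- simulate_gaze(hmm, cfg, seed = 42, duration = 600)
  fs <- segment_fixations(ses$traj)
  hit <- vapply(ses$fixations$start_s, function(o)
    any(abs(fs$fixations$start_s - o) <= 1.0001 / 60), logical(1L))
  expect_gte(mean(hit), 0.9)
})

test_that("gaze summary averages durations and amplitudes", {
  fs <- structure(list(
    fixations = data.frame(start_s = c(0, 1), end_s = c(0.3, 1.5),
                           x_px = c(0, 0), y_px = c(0, 0),
                           duration_ms = c(300, 500)),
    saccades = data.frame(onset_s = 0.3, amplitude_px = 120)),
    class = "fixation_sequence")
  gs <- gaze_summary(fs)
  expect_equal(gs$mean_fixation_duration_ms, 400)
  expect_equal(gs$mean_saccade_amplitude_px, 120)
  empty <- structure(list(fixations = data.frame(), saccades = data.frame()),
                     class = "fixation_sequence")
  expect_error(gaze_summary(empty), "no fixations")
})

test_that("mean fixation duration recovers the generator parameter", {
  hmm <- default_gaze_hmm()
  cfg <- session_config(dropout_fraction = 0)
  ses <- simulate_gaze(hmm, cfg, fixation_duration_mean = 350,
                       seed = 11, duration = 900)
  gs <- gaze_summary(segment_fixations(ses$traj))
  expect_lt(abs(gs$mean_fixation_duration_ms - 350), 20)
})
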