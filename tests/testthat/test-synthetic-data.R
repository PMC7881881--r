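test_that("absorbing chain keeps every fixation in the start state", {
  hmm <- two_state_hmm(A = diag(2), p = c(1, 0))
  ses <- simulate_gaze(hmm, session_config(), seed = 1, duration = 120)
  expect_true(all(ses$states == 1L))
  # all centroids near the state-1 emission (within 6 SD)
  d <- sqrt((ses$fixations$x_px - 250)^2 + (ses$fixations$y_px - 360)^2)
  expect_true(all(d < 6 * 30))
})

test_that("empirical state-transition frequencies converge to the chain", {
  A <- matrix(0.5, 2L, 2L)
  hmm <- two_state_hmm(A = A)
  out <- generate_from_hmm(hmm, n = 10000L, seed = 3)
  s <- out$states
  emp <- prop.table(table(factor(s[-length(s)], 1:2),
                          factor(s[-1L], 1:2)), margin = 1L)
  expect_true(max(abs(emp - 0.5)) < 0.02)
})

test_that("dropout is placed in contiguous runs at the requested fraction", {
  hmm <- two_state_hmm()
  cfg <- session_config(dropout_fraction = 0.2)
  ses <- simulate_gaze(hmm, cfg, seed = 5, duration = 900)
  expect_equal(nrow(ses$traj), 54000L)
  expect_lt(abs(mean(!ses$traj$valid) - 0.20), 0.01)
  # contiguous blink-like runs: mean invalid run length near 200 ms
  r <- rle(ses$traj$valid)
  runs <- r$lengths[!r$values]
  expect_gt(mean(runs), 6)    # > 100 ms at 60 Hz
  expect_lt(mean(runs), 24)   # < 400 ms
})

test_that("generated samples lie inside the frame or are flagged invalid", {
  hmm <- two_state_hmm()
  for (s in 1:3) {
    ses <- simulate_gaze(hmm, session_config(), seed = s, duration = 60)
    v <- ses$traj[ses$traj$valid, ]
    expect_true(all(v$x_px >= 0 & v$x_px < 960 & v$y_px >= 0 & v$y_px < 720))
  }
})

test_that("emission components outside the frame reject the configuration", {
  bad <- gaussian_mixture(1, matrix(c(2000, 360), 1L),
                          array(diag(2) * 100, c(2L, 2L, 1L)))
  hmm <- gaze_hmm(matrix(0.5, 2L, 2L), c(0.5, 0.5),
                  list(bad, two_state_hmm()$emissions[[2L]]))
  expect_error(simulate_gaze(hmm, session_config(), seed = 1, duration = 10),
               "outside the image frame")
})

test_that("identical seeds give byte-identical simulated outputs", {
  hmm <- two_state_hmm()
  a <- simulate_gaze(hmm, session_config(), seed = 9, duration = 30)
  b <- simulate_gaze(hmm, session_config(), seed = 9, duration = 30)
  expect_identical(a, b)
  ea <- simulate_ecg(1000, 30, 30, 2048, seed = 9)
  eb <- simulate_ecg(1000, 30, 30, 2048, seed = 9)
  expect_identical(ea, eb)
  ga <- simulate_gsr(5, 0.1, 30, 256, seed = 9)
  gb <- simulate_gsr(5, 0.1, 30, 256, seed = 9)
  expect_identical(ga, gb)
  ca <- simulate_cohort(6, 2, seed = 9)
  cb <- simulate_cohort(6, 2, seed = 9)
  expect_identical(ca, cb)
})

test_that("ECG generator hits the requested beat timing and RMSSD", {
  # zero variability: perfectly regular beats
  e0 <- simulate_ecg(mean_rr = 1000, rmssd_target = 0, duration = 30,
                     rate = 512, seed = 1)
  expect_true(all(abs(diff(e0$beat_times) - 1) < 1e-9))
  # 60 bpm for 60 s: 60 +/- 1 beats
  e1 <- simulate_ecg(mean_rr = 1000, rmssd_target = 0, duration = 60,
                     rate = 512, seed = 1)
  expect_lt(abs(length(e1$beat_times) - 60), 1.5)
  # realized RMSSD from returned beat times within +/- 3 ms of target
  e2 <- simulate_ecg(mean_rr = 1000, rmssd_target = 30, duration = 300,
                     rate = 512, seed = 2)
  rr <- diff(e2$beat_times) * 1000
  expect_lt(abs(sqrt(mean(diff(rr)^2)) - 30), 3)
})

test_that("ECG generator rejects unresolvable or inconsistent settings", {
  expect_error(simulate_ecg(rate = 50), "100 Hz")
  expect_error(simulate_ecg(mean_rr = 50, rmssd_target = 30), "mean_rr")
})

test_that("GSR generator matches its closed-form window mean", {
  g0 <- simulate_gsr(5, 0, 60, 256, seed = 1, noise_sd = 0)
  expect_true(all(g0$values == 5))
  # level 5, drift 0.1 uS/min over 180 s: mean = 5 + 0.1 * 3 / 2 = 5.15
  g1 <- simulate_gsr(5, 0.1, 180, 256, seed = 2, noise_sd = 0)
  expect_equal(mean(g1$values), 5.15, tolerance = 1e-3)
  g2 <- simulate_gsr(5, 0.1, 180, 256, seed = 3, noise_sd = 0.05)
  expect_equal(mean(g2$values), 5.15, tolerance = 0.02)
  expect_error(simulate_gsr(-1, 0, 10, 256), "nonnegative")
})

test_that("uncoupled cohorts have near-zero pooled correlation at large n", {
  co <- simulate_cohort(200, 60, coupling_slope = 0, seed = 4)
  pc <- pooled_correlation(co$metrics$transition_entropy, co$metrics$d_hr)
  expect_lt(abs(pc$r), 0.05)
})

test_that("the coupling slope induces the designed population correlation", {
  sl <- coupling_slope_for_r(0.25)
  co <- simulate_cohort(400, 120, coupling_slope = sl, seed = 6)
  pc <- pooled_correlation(co$metrics$transition_entropy, co$metrics$d_hr)
  expect_lt(abs(pc$r - 0.25), 0.05)
  expect_equal(co$truth$expected_r, 0.25, tolerance = 1e-12)
})

test_that("cohort effect sizes shift the targeted factor level only", {
  co <- simulate_cohort(200, 100, effect_sizes = list(d_hr = c(gender = 5)),
                        seed = 7)
  m <- co$metrics
  expect_equal(mean(m$d_hr[m$gender == "F"]) - mean(m$d_hr[m$gender == "M"]),
               5, tolerance = 0.5)
  expect_lt(abs(mean(m$transition_entropy[m$gender == "F"]) -
                  mean(m$transition_entropy[m$gender == "M"])), 0.05)
})

test_that("session-level cohorts carry raw signals and ground truth", {
  cfg <- session_config(viewing_duration = 360, baseline_duration = 60)
  co <- simulate_cohort(2, 1, seed = 8, level = "sessions", config = cfg)
  expect_length(co$sessions, 2L)
  s <- co$sessions[[1L]]
  expect_s3_class(s$ecg, "physio_record")
  expect_equal(length(s$ecg$values) / s$ecg$rate, 420)
  expect_true(all(diff(s$beat_times) > 0))
  expect_length(s$truth$transition_entropy, nrow(s$windows))
})
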