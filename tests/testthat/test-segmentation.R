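test_that("resting pose estimation recovers the baseline", {
  # constant trace: pose exact, dispersion zero
  n <- 1200
  t <- round((seq_len(n) - 1) * 1000 / 30)
  flat <- accel_trace(tibble::tibble(t_ms = t, x = 9, y = -1, z = 5))
  pose <- estimate_resting_pose(flat)
  expect_equal(c(pose$x, pose$y, pose$z), c(9, -1, 5))
  expect_equal(c(pose$disp_x, pose$disp_y, pose$disp_z), c(0, 0, 0))

  # too-short trace errors
  short <- accel_trace(tibble::tibble(t_ms = t[1:60], x = 9, y = -1, z = 5))
  expect_error(estimate_resting_pose(short), "shorter than the baseline")

  # an all-plateau trace locks onto the plateau (documented hazard)
  plat <- accel_trace(tibble::tibble(t_ms = t, x = 9, y = -5, z = -3))
  pose_p <- estimate_resting_pose(plat)
  expect_equal(c(pose_p$x, pose_p$y, pose_p$z), c(9, -5, -3))

  # noisy simulated session: within 0.1 m/s^2 of the configured rest pose
  cfg <- quick_config(seed = 14, noise_sd = 0.2)
  s <- simulate_session(cfg)
  pose_s <- estimate_resting_pose(s$trace)
  expect_lt(max(abs(c(pose_s$x, pose_s$y, pose_s$z) - cfg$rest_pose)), 0.1)
})

test_that("a flat trace yields no detections", {
  n <- 2000
  t <- round((seq_len(n) - 1) * 1000 / 30)
  flat <- accel_trace(tibble::tibble(t_ms = t, x = 9, y = -1, z = 5))
  expect_equal(nrow(detect_puffs(flat)), 0)
})

test_that("a single trapezoidal puff is recovered with its plateau duration", {
  fx <- single_puff_trace(plateau_samples = 60)
  ev <- detect_puffs(fx$trace)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end_ms - ev$start_ms, 2000, tolerance = 34 / 2000)
  expect_equal(ev$start_ms, fx$start_ms, tolerance = 34 / fx$start_ms)
})

test_that("detection matches truth one-to-one on a noisy session", {
  s <- simulate_session(quick_config(seed = 6, noise_sd = 0.2))
  det <- detect_puffs(s$trace)
  left <- s$truth[s$truth$hand == "left", ]
  m <- match_events(det, left, max_offset_ms = 1000)
  expect_equal(m$true_positives, nrow(left))
  expect_equal(m$false_positives, 0)
  expect_equal(m$misses, 0)
  # boundary error within 2 sample periods
  expect_lte(max(abs(c(m$pairs$start_offset_ms, m$pairs$end_offset_ms))), 67)
})

test_that("detected events satisfy the output invariants", {
  params <- segmentation_params()
  s <- simulate_session(quick_config(seed = 23, noise_sd = 0.5))
  ev <- detect_puffs(s$trace, params = params)
  expect_true(all(diff(ev$start_ms) > 0))
  expect_true(all(ev$end_ms[-nrow(ev)] <= ev$start_ms[-1]))
  expect_true(all(ev$end_ms - ev$start_ms >= params$min_plateau_ms))
})

test_that("raising the minimum plateau hold never adds detections", {
  s <- simulate_session(quick_config(seed = 9, noise_sd = 0.3))
  holds <- c(500, 800, 1100, 1400, 2000)
  counts <- vapply(holds, function(h) {
    nrow(detect_puffs(s$trace, params = segmentation_params(min_plateau_ms = h)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("greedy matching partitions both lists and equals brute force", {
  ev <- puff_events(seq(0, 4) * 20000, seq(0, 4) * 20000 + 1500)
  m <- match_events(ev, ev, 1000)
  expect_equal(m$true_positives, 5)
  expect_equal(m$false_positives, 0)
  expect_equal(m$misses, 0)

  m0 <- match_events(puff_events(), ev, 1000)
  expect_equal(c(m0$true_positives, m0$false_positives, m0$misses), c(0, 0, 5))

  for (seed in 1:5) {
    s <- simulate_session(quick_config(seed = seed, noise_sd = 0.5))
    det <- detect_puffs(s$trace)
    left <- s$truth[s$truth$hand == "left", ]
    m <- match_events(det, left, 1000)
    expect_equal(m$true_positives, brute_force_match_count(det, left, 1000))
    expect_equal(m$true_positives + m$false_positives, nrow(det))
    expect_equal(m$true_positives + m$misses, nrow(left))
  }
})

test_that("window restriction keeps only fully contained events", {
  ev <- puff_events(c(1000, 5000, 9000), c(2000, 6000, 10000))
  expect_equal(as.data.frame(restrict_to_window(ev, 0, 20000)),
               as.data.frame(ev))
  # event straddling the window end is dropped, not truncated
  kept <- restrict_to_window(ev, 0, 9500)
  expect_equal(kept$start_ms, c(1000, 5000))
  expect_error(restrict_to_window(ev, 5000, 5000), "must be <")

  s <- simulate_session(quick_config(seed = 17))
  seg <- s$schedule[s$schedule$activity == "smoking_left", ]
  left <- restrict_to_window(s$truth, seg$start_ms, seg$end_ms)
  expect_equal(as.data.frame(left)[c("start_ms", "end_ms")],
               as.data.frame(s$truth[s$truth$hand == "left", ])[
                 c("start_ms", "end_ms")])
})
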