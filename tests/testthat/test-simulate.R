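test_that("the default session spans the full 20-minute protocol at 30 Hz", {
  s <- simulate_session(quick_config(seed = 1))
  expect_equal(nrow(s$trace), 36000) # 20 min x 60 s x 30 Hz
  expect_equal(sampling_rate(s$trace), 30)
  # schedule conservation: segment durations tile the trace span
  expect_equal(max(s$schedule$end_ms), 1200 * 1000)
  expect_equal(sum(s$schedule$duration_s), 1200)
  smoking_s <- sum(s$schedule$duration_s[
    startsWith(s$schedule$activity, "smoking")])
  expect_equal(smoking_s, 360) # 6 minutes split across hands
})

test_that("every truth event lies inside its hand's smoking segment", {
  s <- simulate_session(quick_config(seed = 12))
  for (hand in c("left", "right")) {
    seg <- s$schedule[s$schedule$activity == paste0("smoking_", hand), ]
    ev <- s$truth[s$truth$hand == hand, ]
    expect_gt(nrow(ev), 0)
    expect_true(all(ev$start_ms >= seg$start_ms & ev$end_ms <= seg$end_ms))
  }
})

test_that("a zero-puff session never leaves the rest pose while smoking", {
  cfg <- quick_config(seed = 2, n_puffs_per_hand = 0)
  s <- simulate_session(cfg)
  expect_equal(nrow(s$truth), 0)
  seg <- s$schedule[s$schedule$activity == "smoking_left", ]
  idx <- s$trace$t_ms >= seg$start_ms & s$trace$t_ms < seg$end_ms
  expect_equal(max(abs(s$trace$y[idx] - cfg$rest_pose[2])), 0)
  expect_equal(max(abs(s$trace$z[idx] - cfg$rest_pose[3])), 0)
})

test_that("identical config and seed reproduce the session bit-exactly", {
  a <- simulate_session(quick_config(seed = 77, noise_sd = 0.4))
  b <- simulate_session(quick_config(seed = 77, noise_sd = 0.4))
  expect_identical(a$trace$x, b$trace$x)
  expect_identical(a$trace$z, b$trace$z)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
})

test_that("plateau noise variance scales with noise_sd squared", {
  plateau_var <- function(sd) {
    s <- simulate_session(quick_config(seed = 31, noise_sd = sd))
    ev <- s$truth[s$truth$hand == "left", ][1, ]
    idx <- s$trace$t_ms >= ev$start_ms & s$trace$t_ms < ev$end_ms
    stats::var(s$trace$z[idx])
  }
  v1 <- plateau_var(0.2)
  v2 <- plateau_var(0.4)
  expect_equal(v2 / v1, 4, tolerance = 0.5)
  s0 <- simulate_session(quick_config(seed = 31, noise_sd = 0))
  ev <- s0$truth[1, ]
  idx <- s0$trace$t_ms >= ev$start_ms & s0$trace$t_ms < ev$end_ms
  expect_equal(stats::var(s0$trace$z[idx]), 0)
})

test_that("an artifact-free device log reproduces the truth topography", {
  s <- simulate_session(quick_config(seed = 3))
  art <- cress_artifact_config(seed = 5, leading_ipi_ms = 75000)
  log <- simulate_cress_log(s$truth, art)
  expect_equal(nrow(log), nrow(s$truth))
  tt <- events_to_topography(s$truth, "truth")
  expect_equal(log$pd_ms, tt$pd_ms)
  expect_equal(log$ipi_ms[1], 75000)
  expect_equal(log$ipi_ms[-1], tt$ipi_ms)
})

test_that("each split artifact adds exactly one sub-second fragment record", {
  truth <- puff_events(seq(0, 9) * 25000, seq(0, 9) * 25000 + 1500)
  # find a seed drawing exactly one split at p = 0.1 (deterministic draw log)
  seed <- NULL
  for (cand in 1:50) {
    draw <- withr::with_seed(cand, stats::runif(10) < 0.1)
    if (sum(draw) == 1) { seed <- cand; break }
  }
  art <- cress_artifact_config(seed = seed, split_probability = 0.1,
                               split_fragment_pd_ms = 5, split_gap_ms = 330)
  log <- simulate_cress_log(truth, art)
  expect_equal(nrow(log), 11)
  expect_equal(sum(log$pd_ms == 5), 1)
  expect_equal(sum(log$ipi_ms == 330), 1)
  # splitting conserves the puff's total span
  expect_equal(sum(log$pd_ms) + sum(log$ipi_ms),
               10 * 1500 + art$leading_ipi_ms + 9 * 23500)
  expect_equal(nrow(simulate_cress_log(puff_events(), art)), 0)
})

test_that("cohort metadata tracks truth counts and completeness flags", {
  co1 <- simulate_cohort(1, quick_config(seed = 8))
  expect_equal(cohort_meta(co1)$visual_puff_count_left +
                 cohort_meta(co1)$visual_puff_count_right,
               nrow(co1[[1]]$truth))

  co <- simulate_cohort(35, quick_config(seed = 8),
                        n_incomplete_cress = 5, n_incomplete_aspire = 3)
  meta <- cohort_meta(co)
  expect_equal(nrow(meta), 35)
  expect_equal(sum(!meta$complete_cress), 5)
  expect_equal(sum(!meta$complete_aspire), 3)
  expect_equal(sum(meta$complete_cress & meta$complete_aspire), 27)
})

test_that("cohort draws vary topography parameters yet stay reproducible", {
  co <- simulate_cohort(5, quick_config(seed = 21))
  medians <- vapply(co, function(s) {
    stats::median(s$truth$end_ms - s$truth$start_ms)
  }, numeric(1))
  expect_gt(stats::sd(medians), 0)
  co2 <- simulate_cohort(5, quick_config(seed = 21))
  expect_identical(cohort_meta(co), cohort_meta(co2))
  expect_identical(co[[3]]$cress$pd_ms, co2[[3]]$cress$pd_ms)
})
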