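make_meta <- function(n, bad_cress = integer(), bad_aspire = integer()) {
  tibble::tibble(participant_id = sprintf("P%02d", seq_len(n)),
                 complete_cress = !(seq_len(n) %in% bad_cress),
                 complete_aspire = !(seq_len(n) %in% bad_aspire))
}

test_that("the analytic roster drops any incomplete recording", {
  roster <- suppressMessages(
    filter_complete(make_meta(35, bad_cress = 1:5, bad_aspire = 6:8)))
  expect_equal(nrow(roster), 27)

  all_ok <- make_meta(10)
  expect_equal(suppressMessages(filter_complete(all_ok)), all_ok)

  # overlapping causes: retained = total - |union|, against set arithmetic
  bad_c <- c(2, 3, 7)
  bad_a <- c(3, 7, 9)
  roster2 <- suppressMessages(
    filter_complete(make_meta(12, bad_cress = bad_c, bad_aspire = bad_a)))
  expect_equal(nrow(roster2), 12 - length(union(bad_c, bad_a)))

  expect_error(suppressMessages(filter_complete(make_meta(2, 1:2, 1:2))),
               "no participant")
})

test_that("pearson_r2 agrees with the direct formula and rejects degeneracy", {
  xs <- c(3, 1, 4, 1, 5)
  expect_equal(pearson_r2(xs, 2 * xs + 1), 1.0)
  expect_equal(pearson_r2(c(1, 2, 3), c(1, 3, 2)),
               r2_formula(c(1, 2, 3), c(1, 3, 2)))
  expect_error(pearson_r2(xs, rep(2, 5)), "constant")
  expect_error(pearson_r2(xs, xs[-1]), "equal length")
  expect_error(pearson_r2(1, 2), "at least 2")

  # affine invariance in either argument
  withr::with_seed(99, {
    for (i in 1:20) {
      x <- stats::rnorm(10)
      y <- stats::rnorm(10)
      a <- stats::runif(1, 0.1, 5) * sample(c(-1, 1), 1)
      b <- stats::rnorm(1, 0, 10)
      expect_equal(pearson_r2(a * x + b, y), pearson_r2(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("count concordance is a symmetric within-tolerance proportion", {
  expect_equal(puff_count_concordance(c(10, 12, 8), c(10, 12, 8), 2), 1.0)
  expect_equal(puff_count_concordance(c(10, 12, 8), c(12, 10, 15), 2), 2 / 3)
  expect_equal(puff_count_concordance(c(12, 10, 15), c(10, 12, 8), 2), 2 / 3)
  expect_error(puff_count_concordance(integer(), integer()), "non-empty")

  withr::with_seed(7, {
    a <- stats::rpois(40, 10)
    b <- stats::rpois(40, 10)
    for (tol in 0:5) {
      expect_equal(puff_count_concordance(a, b, tol),
                   sum(abs(a - b) <= tol) / 40)
    }
    cs <- vapply(0:6, function(tol) puff_count_concordance(a, b, tol),
                 numeric(1))
    expect_true(all(diff(cs) >= 0)) # monotone in tol
  })
})

test_that("paired series agreement truncates by index and uses the formula", {
  tp <- topography(c(1400, 900, 2100, 1700), c(18000, 26000, 21000))
  same <- paired_series_r2(tp, tp)
  expect_equal(same$r2_pd, 1.0)
  expect_equal(same$r2_ipi, 1.0)

  s <- simulate_session(quick_config(seed = 10))
  tt <- events_to_topography(s$truth, "truth")
  log <- simulate_cress_log(s$truth, cress_artifact_config(
    seed = 3, split_probability = 0.4, jitter_sd_ms = 60))
  raw <- cress_to_topography(log)
  got <- paired_series_r2(raw, tt)
  n_pd <- min(length(raw$pd_ms), length(tt$pd_ms))
  n_ipi <- min(length(raw$ipi_ms), length(tt$ipi_ms))
  expect_equal(got$r2_pd, r2_formula(raw$pd_ms[1:n_pd], tt$pd_ms[1:n_pd]))
  expect_equal(got$r2_ipi, r2_formula(raw$ipi_ms[1:n_ipi], tt$ipi_ms[1:n_ipi]))

  tiny <- topography(1400, numeric())
  expect_error(paired_series_r2(tiny, tp), "at least 2 pairs")
})

test_that("a clean cohort yields perfect per-participant agreement", {
  co <- simulate_cohort(4, quick_config(seed = 30, noise_sd = 0),
                        cress_artifact_config(seed = 1))
  summ <- suppressMessages(run_comparison(co))
  per <- tidy(summ)
  # boundaries are rounded to integer ms, so agreement is exact up to that
  expect_equal(per$r2_pd, rep(1, 4), tolerance = 1e-4)
  expect_equal(per$r2_ipi, rep(1, 4), tolerance = 1e-4)
  # zero-noise detection reproduces the visual (truth) count per hand
  expect_equal(per$puff_count_watch, per$puff_count_visual_watch_hand)
  pooled <- glance(summ)
  expect_equal(pooled$r2_counts_watch_visual, 1.0)
  # no splits: device count equals the visual total, so full concordance
  expect_equal(pooled$concordance_within_tol, 1.0)
})

test_that("comparison summaries are deterministic and degrade gracefully", {
  co <- simulate_cohort(4, quick_config(seed = 13, noise_sd = 0.3),
                        cress_artifact_config(seed = 2,
                                              split_probability = 0.2,
                                              jitter_sd_ms = 60))
  s1 <- suppressMessages(run_comparison(co))
  s2 <- suppressMessages(run_comparison(co))
  expect_identical(glance(s1), glance(s2))
  expect_identical(tidy(s1), tidy(s2))

  one <- simulate_cohort(1, quick_config(seed = 13))
  expect_warning(suppressMessages(summ1 <- run_comparison(one)),
                 "fewer than 3")
  expect_true(is.na(glance(summ1)$r2_median_pd))
  expect_equal(nrow(tidy(summ1)), 1)
})
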