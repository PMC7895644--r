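test_that("a milliseconds fragment is merged into the preceding puff", {
  log <- cress_log(tibble::tibble(pd_ms = c(1500, 5, 1200),
                                  ipi_ms = c(50000, 300, 3000)))
  res <- clean_cress(log, cleaning_params(min_plausible_pd_ms = 300))
  # hand-traced merge: 1500 + 300 (gap) + 5 (fragment) = 1805
  expect_equal(res$log$pd_ms, c(1805, 1200))
  expect_equal(res$log$ipi_ms, c(50000, 3000))
  expect_equal(res$report$action, "merge_into_preceding")
  expect_equal(res$report$record_index, 2L)
})

test_that("a fragment in first position merges into the following puff", {
  log <- cress_log(tibble::tibble(pd_ms = c(5, 1500),
                                  ipi_ms = c(50000, 400)))
  res <- clean_cress(log, cleaning_params())
  expect_equal(res$log$pd_ms, 5 + 400 + 1500)
  expect_equal(res$log$ipi_ms, 50000) # keeps the original lead interval
  expect_equal(res$report$action, "merge_into_following")
})

test_that("the leading device-on interval is dropped only above threshold", {
  log <- cress_log(tibble::tibble(pd_ms = c(1500, 1200),
                                  ipi_ms = c(65000, 3000)))
  res <- clean_cress(log, cleaning_params(
    leading_ipi_rule = "drop_if_over_ms", leading_ipi_threshold_ms = 60000))
  expect_equal(res$log$ipi_ms[1], 0)
  expect_true("drop_leading_ipi" %in% res$report$action)

  below <- cress_log(tibble::tibble(pd_ms = c(1500, 1200),
                                    ipi_ms = c(55000, 3000)))
  res2 <- clean_cress(below, cleaning_params())
  expect_equal(res2$log$ipi_ms[1], 55000)

  res3 <- clean_cress(below, cleaning_params(leading_ipi_rule = "always_drop"))
  expect_equal(res3$log$ipi_ms[1], 0)
})

test_that("an artifact-free log passes through cleaning untouched", {
  log <- cress_log(tibble::tibble(pd_ms = c(1500, 1200, 900),
                                  ipi_ms = c(30000, 21000, 19000)))
  res <- clean_cress(log, cleaning_params())
  expect_equal(as.data.frame(res$log), as.data.frame(log))
  expect_equal(nrow(res$report), 0)
})

test_that("merging conserves total recorded time; deletion does not", {
  for (seed in c(4, 15, 33)) {
    s <- simulate_session(quick_config(seed = seed))
    log <- simulate_cress_log(s$truth, cress_artifact_config(
      seed = seed + 100, split_probability = 0.4, leading_ipi_ms = 50000))
    before <- sum(log$pd_ms) + sum(log$ipi_ms)
    res <- clean_cress(log, cleaning_params(merge_fragments = TRUE))
    expect_equal(sum(res$log$pd_ms) + sum(res$log$ipi_ms), before,
                 tolerance = 1 / before)
    res_d <- clean_cress(log, cleaning_params(merge_fragments = FALSE))
    expect_equal(nrow(res_d$log), nrow(log) - sum(log$pd_ms < 300))
  }
})

test_that("outlier IPIs are replaced by the mean of the remaining ones", {
  tp <- topography(rep(1500, 6), c(5, 20000, 21000, 22000, 90000))
  res <- correct_ipis(tp, outlier_rule(method = "range",
                                       min_ipi_ms = 1000, max_ipi_ms = 60000))
  expect_equal(res$series$ipi_ms, c(21000, 20000, 21000, 22000, 21000))
  expect_equal(res$flags, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$series$pd_ms, tp$pd_ms) # PDs untouched
  expect_length(res$series$ipi_ms, length(tp$ipi_ms))

  # idempotent: a second pass flags nothing new
  res2 <- correct_ipis(res$series, outlier_rule(method = "range",
                                                min_ipi_ms = 1000,
                                                max_ipi_ms = 60000))
  expect_false(any(res2$flags))
  expect_equal(res2$series$ipi_ms, res$series$ipi_ms)
})

test_that("degenerate outlier configurations behave as specified", {
  tp <- topography(rep(1500, 4), c(20000, 21000, 22000))
  # nothing flagged: identity
  res <- correct_ipis(tp, outlier_rule())
  expect_equal(res$series$ipi_ms, tp$ipi_ms)
  # all-equal IPIs under the MAD rule: zero dispersion flags nothing
  eq <- topography(rep(1500, 4), rep(20000, 3))
  res_eq <- correct_ipis(eq, outlier_rule(method = "mad"))
  expect_equal(res_eq$series$ipi_ms, eq$ipi_ms)
  # every IPI flagged: no reference set remains
  allbad <- topography(rep(1500, 3), c(5, 500000))
  expect_error(correct_ipis(allbad, outlier_rule()), "no reference set")
  # MAD rule needs at least 3 IPIs
  two <- topography(rep(1500, 3), c(20000, 21000))
  expect_warning(res_two <- correct_ipis(two, outlier_rule(method = "mad")),
                 "fewer than 3")
  expect_equal(res_two$series$ipi_ms, two$ipi_ms)
})

test_that("the corrected pipeline recovers the truth topography", {
  s <- simulate_session(quick_config(seed = 41))
  tt <- events_to_topography(s$truth, "truth")

  clean_log <- simulate_cress_log(s$truth, cress_artifact_config(seed = 1))
  res0 <- ccress_pipeline(clean_log)
  expect_equal(res0$series$pd_ms, tt$pd_ms)
  expect_equal(res0$series$ipi_ms, tt$ipi_ms)
  expect_equal(res0$series$source, "cress_corrected")

  jitter <- 80
  log <- simulate_cress_log(s$truth, cress_artifact_config(
    seed = 2, split_probability = 0.3, jitter_sd_ms = jitter))
  res <- ccress_pipeline(log)
  expect_length(res$series$pd_ms, length(tt$pd_ms))
  expect_lt(max(abs(res$series$pd_ms - tt$pd_ms)), 6 * jitter)

  # heavily corrupted: every surviving IPI implausible
  bad <- cress_log(tibble::tibble(pd_ms = c(1500, 1500),
                                  ipi_ms = c(70000, 500)))
  expect_error(ccress_pipeline(bad), "no reference set")
})

test_that("correction improves agreement with truth on corrupted logs", {
  wins <- 0L
  n_rep <- 20L
  for (seed in seq_len(n_rep)) {
    s <- simulate_session(quick_config(seed = seed))
    tt <- events_to_topography(s$truth, "truth")
    log <- simulate_cress_log(s$truth, cress_artifact_config(
      seed = seed + 500, split_probability = 0.25, jitter_sd_ms = 80))
    raw <- cress_to_topography(log)
    corr <- ccress_pipeline(log)$series
    r_raw <- paired_series_r2(raw, tt)
    r_cor <- paired_series_r2(corr, tt)
    if (r_cor$r2_pd >= r_raw$r2_pd) wins <- wins + 1L
  }
  expect_gte(wins, round(0.95 * n_rep))
})
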