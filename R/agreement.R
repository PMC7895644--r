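#' Retain participants with complete data from both methods
#'
#' The analytic roster keeps only participants whose watch-side and
#' device-side recordings are both complete; exclusion counts by cause are
#' reported as a message.
#'
#' @param meta A tibble of per-participant metadata with logical columns
#'   `complete_aspire` and `complete_cress` (e.g. [cohort_meta()]).
#' @return The retained rows.
#' @export
filter_complete <- function(meta) {
  meta <- as_tibble(meta)
  if (!all(c("complete_aspire", "complete_cress") %in% names(meta))) {
    abort("`meta` needs logical columns `complete_aspire` and `complete_cress`.")
  }
  n_cress <- sum(!meta$complete_cress)
  n_aspire <- sum(!meta$complete_aspire)
  keep <- meta$complete_aspire & meta$complete_cress
  inform(sprintf(
    "analytic roster: %d of %d retained (%d device-incomplete, %d watch-incomplete, %d excluded).",
    sum(keep), nrow(meta), n_cress, n_aspire, sum(!keep)))
  if (!any(keep)) abort("no participant has complete data from both methods.")
  meta[keep, , drop = FALSE]
}

#' Squared Pearson correlation
#'
#' @param xs,ys Equal-length numeric vectors (n >= 2), both with nonzero
#'   variance.
#' @return The squared Pearson product-moment correlation, in `[0, 1]`.
#' @export
pearson_r2 <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) != length(ys)) abort("`xs` and `ys` must have equal length.")
  if (length(xs) < 2) abort("need at least 2 paired observations.")
  if (any(!is.finite(xs)) || any(!is.finite(ys))) {
    abort("inputs must be finite.")
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    abort("correlation is undefined for a constant input.")
  }
  stats::cor(xs, ys)^2
}

#' Proportion of paired counts agreeing within a tolerance
#'
#' @param counts_a,counts_b Equal-length integer vectors of per-session puff
#'   counts.
#' @param tol Maximum absolute difference counted as agreement (default 2).
#' @return Fraction of pairs with `|a - b| <= tol`, in `[0, 1]`.
#' @export
puff_count_concordance <- function(counts_a, counts_b, tol = 2) {
  if (length(counts_a) != length(counts_b)) {
    abort("count vectors must have equal length.")
  }
  if (length(counts_a) == 0) abort("count vectors must be non-empty.")
  assert_scalar_number(tol, "tol", min = 0)
  mean(abs(counts_a - counts_b) <= tol)
}

#' Per-puff agreement between two topography series
#'
#' Pairs PDs by puff index and IPIs by gap index, truncating to the shorter
#' list (the methods observe different portions of a session, so list
#' lengths can differ; truncation keeps the leading, co-observed stretch).
#'
#' @param series_a,series_b [topography()] objects.
#' @param pairing Pairing strategy; only `"by_index_truncate"` is provided.
#' @return A list with `r2_pd`, `r2_ipi`, `n_pairs_pd`, `n_pairs_ipi`.
#' @export
paired_series_r2 <- function(series_a, series_b,
                             pairing = "by_index_truncate") {
  stopifnot(inherits(series_a, "topography"), inherits(series_b, "topography"))
  pairing <- match.arg(pairing, "by_index_truncate")
  n_pd <- min(length(series_a$pd_ms), length(series_b$pd_ms))
  n_ipi <- min(length(series_a$ipi_ms), length(series_b$ipi_ms))
  if (n_pd < 2 || n_ipi < 2) {
    abort(sprintf("need at least 2 pairs per measure (got %d PD, %d IPI pairs).",
                  n_pd, n_ipi))
  }
  list(r2_pd = pearson_r2(series_a$pd_ms[seq_len(n_pd)],
                          series_b$pd_ms[seq_len(n_pd)]),
       r2_ipi = pearson_r2(series_a$ipi_ms[seq_len(n_ipi)],
                           series_b$ipi_ms[seq_len(n_ipi)]),
       n_pairs_pd = n_pd, n_pairs_ipi = n_ipi)
}

#' Run the full method-agreement comparison over a cohort
#'
#' For every participant with complete data: detect puffs on the watch
#' trace, restrict to the watch-hand smoking window, derive the watch-side
#' topography, derive the raw and corrected device-side topographies, and
#' compute per-puff agreement (index-paired R-squared, truncated to the
#' shorter list). Pooled statistics compare per-participant medians (the
#' device comparison's headline view), puff-count agreement against the
#' visual counts, and count concordance within `tol`.
#'
#' Watch counts are compared against the visual count of the watch hand;
#' device counts, which cover both hands, are compared against the total
#' visual count.
#'
#' @param cohort A `smoketop_cohort` from [simulate_cohort()].
#' @param segmentation A [segmentation_params()].
#' @param cleaning A [cleaning_params()].
#' @param rule An [outlier_rule()].
#' @param tol Count-concordance tolerance (default 2).
#' @param use_corrected Compare the corrected device series (default `TRUE`)
#'   or the raw one.
#' @return A list of class `agreement_summary` with `per_participant` (a
#'   tibble) and `pooled` (a one-row tibble).
#' @export
run_comparison <- function(cohort,
                           segmentation = segmentation_params(),
                           cleaning = cleaning_params(),
                           rule = outlier_rule(),
                           tol = 2,
                           use_corrected = TRUE) {
  stopifnot(inherits(cohort, "smoketop_cohort"))
  meta <- cohort_meta(cohort)
  roster <- filter_complete(meta)
  sessions <- cohort[meta$participant_id %in% roster$participant_id]

  per <- purrr::map(sessions, function(s) {
    watch_hand <- s$config$watch_hand %||% "left"
    seg <- s$schedule[s$schedule$activity == paste0("smoking_", watch_hand), ]
    detected <- detect_puffs(s$trace, params = segmentation)
    watch_events <- restrict_to_window(detected, seg$start_ms[1], seg$end_ms[1])
    watch <- events_to_topography(watch_events, source = "aspire")
    raw <- cress_to_topography(s$cress, drop_leading_ipi = TRUE)
    corrected <- ccress_pipeline(s$cress, cleaning, rule)$series
    device <- if (use_corrected) corrected else raw
    r2 <- tryCatch(paired_series_r2(watch, device),
                   error = function(e) list(r2_pd = NA_real_, r2_ipi = NA_real_,
                                            n_pairs_pd = 0L, n_pairs_ipi = 0L))
    visual_watch <- if (watch_hand == "left") {
      s$meta$visual_puff_count_left
    } else s$meta$visual_puff_count_right
    summ_w <- summarize_topography(watch)
    summ_d <- summarize_topography(device)
    tibble(
      participant_id = s$meta$participant_id,
      n_pairs = r2$n_pairs_pd,
      r2_pd = r2$r2_pd,
      r2_ipi = r2$r2_ipi,
      puff_count_watch = length(watch$pd_ms),
      puff_count_cress = nrow(s$cress),
      puff_count_visual_watch_hand = visual_watch,
      puff_count_visual_total = s$meta$visual_puff_count_left +
        s$meta$visual_puff_count_right,
      median_pd_watch = summ_w$median_pd_ms,
      median_ipi_watch = summ_w$median_ipi_ms,
      median_pd_device = summ_d$median_pd_ms,
      median_ipi_device = summ_d$median_ipi_ms)
  }) |> bind_rows()

  r2_or_na <- function(a, b) {
    tryCatch(pearson_r2(a, b), error = function(e) {
      warn(sprintf("pooled correlation omitted: %s", conditionMessage(e)))
      NA_real_
    })
  }
  pooled <- if (nrow(per) >= 3) {
    tibble(
      r2_median_pd = r2_or_na(per$median_pd_watch, per$median_pd_device),
      r2_median_ipi = r2_or_na(per$median_ipi_watch, per$median_ipi_device),
      r2_counts_watch_visual = r2_or_na(per$puff_count_watch,
                                        per$puff_count_visual_watch_hand),
      r2_counts_cress_visual = r2_or_na(per$puff_count_cress,
                                        per$puff_count_visual_total),
      concordance_within_tol = puff_count_concordance(
        per$puff_count_cress, per$puff_count_visual_total, tol),
      tol = tol,
      n_participants = nrow(per))
  } else {
    warn("fewer than 3 analytic participants: pooled scatter statistics omitted.")
    tibble(r2_median_pd = NA_real_, r2_median_ipi = NA_real_,
           r2_counts_watch_visual = NA_real_,
           r2_counts_cress_visual = NA_real_,
           concordance_within_tol = puff_count_concordance(
             per$puff_count_cress, per$puff_count_visual_total, tol),
           tol = tol, n_participants = nrow(per))
  }
  structure(list(per_participant = per, pooled = pooled),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("<agreement_summary: %d participants>\n", p$n_participants))
  cat(sprintf("  pooled R2 (median PD):  %.3f\n", p$r2_median_pd))
  cat(sprintf("  pooled R2 (median IPI): %.3f\n", p$r2_median_ipi))
  cat(sprintf("  count concordance within +/-%g: %.2f\n",
              p$tol, p$concordance_within_tol))
  invisible(x)
}

#' Tidy / glance methods for agreement summaries
#'
#' `tidy()` returns the per-participant table; `glance()` the pooled one-row
#' summary.
#'
#' @param x An `agreement_summary` from [run_comparison()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.agreement_summary <- function(x, ...) x$per_participant

#' @rdname tidy.agreement_summary
#' @export
glance.agreement_summary <- function(x, ...) x$pooled

#' Plot an agreement summary
#'
#' Scatter of per-participant median PD and median IPI, watch versus device,
#' with the identity line.
#'
#' @param object An `agreement_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_summary <- function(object, ...) {
  per <- object$per_participant
  long <- bind_rows(
    tibble(measure = "median PD (s)",
           watch = per$median_pd_watch / 1000,
           device = per$median_pd_device / 1000),
    tibble(measure = "median IPI (s)",
           watch = per$median_ipi_watch / 1000,
           device = per$median_ipi_device / 1000))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$device, y = .data$watch)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "device log", y = "wrist accelerometer")
}
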