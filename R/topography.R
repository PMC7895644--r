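#' Topography series: per-session PD and IPI lists
#'
#' The condensed topography of a session: the ordered list of puff durations
#' (PD) and the ordered list of interpuff intervals (IPI), both in
#' milliseconds, tagged with the measurement source. When derived from one
#' continuous event list there is exactly one fewer IPI than PD.
#'
#' @param pd_ms Numeric vector of puff durations (> 0), ms.
#' @param ipi_ms Numeric vector of interpuff intervals (>= 0), ms.
#' @param source One of `"aspire"`, `"cress"`, `"cress_corrected"`, `"truth"`.
#' @param strict If `TRUE`, require `length(ipi_ms) == max(0, length(pd_ms) - 1)`
#'   (the invariant of a single continuous event list).
#' @return A list of class `topography`.
#' @export
topography <- function(pd_ms = numeric(), ipi_ms = numeric(),
                       source = c("aspire", "cress", "cress_corrected", "truth"),
                       strict = FALSE) {
  source <- match.arg(source)
  pd_ms <- as.numeric(pd_ms)
  ipi_ms <- as.numeric(ipi_ms)
  if (any(!is.finite(pd_ms)) || any(pd_ms <= 0)) {
    abort("all `pd_ms` must be positive and finite.")
  }
  if (any(!is.finite(ipi_ms)) || any(ipi_ms < 0)) {
    abort("all `ipi_ms` must be non-negative and finite.")
  }
  if (strict && length(ipi_ms) != max(0L, length(pd_ms) - 1L)) {
    abort(sprintf("expected %d IPIs for %d puffs, got %d.",
                  max(0L, length(pd_ms) - 1L), length(pd_ms), length(ipi_ms)))
  }
  structure(list(pd_ms = pd_ms, ipi_ms = ipi_ms, source = source),
            class = "topography")
}

#' @export
print.topography <- function(x, ...) {
  cat(sprintf("<topography [%s]: %d puffs, %d IPIs", x$source,
              length(x$pd_ms), length(x$ipi_ms)))
  if (length(x$pd_ms)) {
    cat(sprintf("; median PD %.0f ms", stats::median(x$pd_ms)))
  }
  if (length(x$ipi_ms)) {
    cat(sprintf(", median IPI %.0f ms", stats::median(x$ipi_ms)))
  }
  cat(">\n")
  invisible(x)
}

#' Derive a topography series from puff events
#'
#' PD is the time a person inhales in one intake: `end_ms - start_ms`. IPI is
#' the time between the end of one puff and the beginning of the next:
#' `start_ms[i + 1] - end_ms[i]`. A list of n events yields n PDs and n - 1
#' IPIs.
#'
#' @param events A [puff_events()] tibble.
#' @param source Provenance tag for the series (default `"aspire"`).
#' @return A [topography()].
#' @export
events_to_topography <- function(events, source = "aspire") {
  events <- puff_events(events)
  n <- nrow(events)
  pd <- events$end_ms - events$start_ms
  ipi <- if (n > 1) events$start_ms[-1] - events$end_ms[-n] else numeric()
  topography(pd, ipi, source = source, strict = TRUE)
}

#' Derive a topography series from a device log
#'
#' Takes PDs from the records in order. The stored IPIs precede each puff,
#' so record 1's interval spans device-on to the first puff; it is an
#' artifact of session start, not an interpuff interval, and is dropped by
#' default.
#'
#' @param log A [cress_log()].
#' @param drop_leading_ipi Drop record 1's interval (default `TRUE`).
#' @param source Provenance tag (default `"cress"`).
#' @return A [topography()].
#' @export
cress_to_topography <- function(log, drop_leading_ipi = TRUE,
                                source = "cress") {
  log <- cress_log(log)
  if (nrow(log) == 0) return(topography(source = source))
  ipi <- if (drop_leading_ipi) log$ipi_ms[-1] else log$ipi_ms
  topography(log$pd_ms, ipi, source = source)
}

#' Summary statistics of a topography series
#'
#' Medians are the field's headline statistic for these series (small counts
#' and device outliers make means fragile); means and standard deviations are
#' reported alongside. `total_smoking_ms` (first puff start to last puff end)
#' and `total_puffing_ms` (sum of PDs) are derivable only when the series
#' came from one continuous event list, i.e. `length(ipi) == length(pd) - 1`;
#' otherwise they are `NA`.
#'
#' @param series A [topography()].
#' @return A one-row tibble: `n_puffs`, `median_pd_ms`, `mean_pd_ms`,
#'   `sd_pd_ms`, `median_ipi_ms`, `mean_ipi_ms`, `sd_ipi_ms`,
#'   `total_smoking_ms`, `total_puffing_ms`, `source`. Statistics of empty
#'   lists are `NA`.
#' @export
summarize_topography <- function(series) {
  stopifnot(inherits(series, "topography"))
  pd <- series$pd_ms; ipi <- series$ipi_ms
  stat <- function(v, f) if (length(v)) f(v) else NA_real_
  continuous <- length(pd) > 0 && length(ipi) == length(pd) - 1
  tibble(
    n_puffs = length(pd),
    median_pd_ms = stat(pd, stats::median),
    mean_pd_ms = stat(pd, mean),
    sd_pd_ms = if (length(pd) > 1) stats::sd(pd) else NA_real_,
    median_ipi_ms = stat(ipi, stats::median),
    mean_ipi_ms = stat(ipi, mean),
    sd_ipi_ms = if (length(ipi) > 1) stats::sd(ipi) else NA_real_,
    total_smoking_ms = if (continuous) sum(pd) + sum(ipi) else NA_real_,
    total_puffing_ms = if (continuous) sum(pd) else NA_real_,
    source = series$source)
}

#' @rdname summarize_topography
#' @param x A [topography()].
#' @param ... Unused.
#' @export
glance.topography <- function(x, ...) summarize_topography(x)

#' Tidy a topography series into long format
#'
#' @param x A [topography()].
#' @param ... Unused.
#' @return A tibble with columns `source`, `measure` (`"pd"`/`"ipi"`),
#'   `index`, `value_ms`.
#' @export
tidy.topography <- function(x, ...) {
  bind_rows(
    tibble(source = x$source, measure = "pd",
           index = seq_along(x$pd_ms), value_ms = x$pd_ms),
    tibble(source = x$source, measure = "ipi",
           index = seq_along(x$ipi_ms), value_ms = x$ipi_ms))
}

#' Histogram counts over fixed-width bins
#'
#' Left-closed, right-open bins of width `bin_width_ms` covering `range_ms`;
#' values outside the range are dropped (and counted in the output
#' attributes), so within-range counts always conserve the number of
#' retained values.
#'
#' @param values_ms Numeric vector (e.g. a PD or IPI list).
#' @param bin_width_ms Bin width (> 0); defaults: 250 ms suits PDs, 2000 ms
#'   suits IPIs.
#' @param range_ms Two-element numeric range; defaults to `c(0, ...)`
#'   covering the data.
#' @return A tibble with `bin_start_ms`, `bin_end_ms`, `count`.
#' @export
topography_histogram <- function(values_ms, bin_width_ms = 250,
                                 range_ms = NULL) {
  assert_scalar_number(bin_width_ms, "bin_width_ms", min = 0, strict_min = TRUE)
  values_ms <- as.numeric(values_ms)
  if (is.null(range_ms)) {
    hi <- if (length(values_ms)) max(values_ms) + bin_width_ms else bin_width_ms
    range_ms <- c(0, hi)
  }
  if (range_ms[1] >= range_ms[2]) abort("`range_ms` must be increasing.")
  breaks <- seq(range_ms[1], range_ms[2] + bin_width_ms, by = bin_width_ms)
  inside <- values_ms >= range_ms[1] & values_ms < breaks[length(breaks) - 1] +
    bin_width_ms
  binned <- floor((values_ms[inside] - range_ms[1]) / bin_width_ms)
  counts <- tabulate(binned + 1L, nbins = length(breaks) - 1L)
  out <- tibble(bin_start_ms = breaks[-length(breaks)],
                bin_end_ms = breaks[-1],
                count = counts)
  out <- out[out$bin_start_ms < range_ms[2], , drop = FALSE]
  attr(out, "n_dropped") <- sum(!inside)
  out
}

#' Plot PD and IPI distributions of one or more topography series
#'
#' @param object A [topography()] or list of them.
#' @param pd_bin_ms,ipi_bin_ms Bin widths (defaults 250 and 2000 ms).
#' @param ... Unused.
#' @return A ggplot object: PD and IPI histograms, colored by source.
#' @export
autoplot.topography <- function(object, pd_bin_ms = 250, ipi_bin_ms = 2000,
                                ...) {
  series <- if (inherits(object, "topography")) list(object) else object
  long <- bind_rows(purrr::map(series, tidy))
  long$measure <- factor(long$measure, c("pd", "ipi"),
                         c("puff duration", "interpuff interval"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value_ms / 1000,
                                     fill = .data$source)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.6, bins = 30) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "duration (s)", y = "count", fill = "source")
}
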