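#' Plausibility-cleaning parameters for device logs
#'
#' Mouthpiece topography devices occasionally report physically implausible
#' records — puffs of a few milliseconds arising from one physical puff being
#' split across records, and a long spurious first interval spanning device
#' power-on to the first puff. These parameters control how both are handled.
#'
#' @param min_plausible_pd_ms Records with PD below this are implausible
#'   (default 300 — well below any credible inhalation, far above the
#'   milliseconds-scale fragments the devices emit).
#' @param leading_ipi_rule `"drop_if_over_ms"` (default) zeroes record 1's
#'   preceding interval only when it exceeds `leading_ipi_threshold_ms`;
#'   `"always_drop"` zeroes it unconditionally.
#' @param leading_ipi_threshold_ms Threshold for `drop_if_over_ms`
#'   (default 60000, i.e. one minute).
#' @param merge_fragments If `TRUE` (default) an implausible record is
#'   absorbed into its neighbour — its PD and the interval separating them
#'   are added to the neighbouring record's PD — reconstituting the split
#'   physical puff and conserving total recorded time. If `FALSE` the record
#'   is simply deleted (useful for sensitivity analysis).
#' @return A list of class `cleaning_params`.
#' @export
cleaning_params <- function(min_plausible_pd_ms = 300,
                            leading_ipi_rule = c("drop_if_over_ms", "always_drop"),
                            leading_ipi_threshold_ms = 60000,
                            merge_fragments = TRUE) {
  leading_ipi_rule <- match.arg(leading_ipi_rule)
  assert_scalar_number(min_plausible_pd_ms, "min_plausible_pd_ms",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(leading_ipi_threshold_ms, "leading_ipi_threshold_ms",
                       min = 0, strict_min = TRUE)
  structure(list(min_plausible_pd_ms = min_plausible_pd_ms,
                 leading_ipi_rule = leading_ipi_rule,
                 leading_ipi_threshold_ms = leading_ipi_threshold_ms,
                 merge_fragments = isTRUE(merge_fragments)),
            class = "cleaning_params")
}

#' Outlier rule for interpuff intervals
#'
#' Two ways of flagging abnormally short or long IPIs: a fixed plausibility
#' range (default), or a robust median-absolute-deviation band.
#'
#' @param method `"range"` (default) or `"mad"`.
#' @param mad_k MAD multiplier for `"mad"` (default 3).
#' @param min_ipi_ms,max_ipi_ms Plausibility range for `"range"`
#'   (defaults 1000 and 120000).
#' @return A list of class `outlier_rule`.
#' @export
outlier_rule <- function(method = c("range", "mad"), mad_k = 3,
                         min_ipi_ms = 1000, max_ipi_ms = 120000) {
  method <- match.arg(method)
  assert_scalar_number(mad_k, "mad_k", min = 0, strict_min = TRUE)
  assert_scalar_number(min_ipi_ms, "min_ipi_ms", min = 0)
  if (min_ipi_ms >= max_ipi_ms) {
    abort("`min_ipi_ms` must be < `max_ipi_ms`.")
  }
  structure(list(method = method, mad_k = mad_k,
                 min_ipi_ms = min_ipi_ms, max_ipi_ms = max_ipi_ms),
            class = "outlier_rule")
}

#' Remove implausible records from a device log
#'
#' Handles the leading device-on interval per the configured rule and removes
#' every record whose PD falls below the plausibility threshold. With
#' `merge_fragments` the removed record's PD and the interval separating it
#' from its neighbour are absorbed into the preceding record's PD (or the
#' following record's, for a fragment in first position), so total recorded
#' time is conserved; without it, implausible records are deleted outright.
#'
#' @param log A [cress_log()].
#' @param params A [cleaning_params()].
#' @return A list with `log` (the cleaned [cress_log()]) and `report` (a
#'   tibble of actions with record indices); an artifact-free log passes
#'   through unchanged with an empty report.
#' @export
clean_cress <- function(log, params = cleaning_params()) {
  log <- cress_log(log)
  report <- tibble(action = character(), record_index = integer(),
                   detail = character())
  if (nrow(log) == 0) return(list(log = log, report = report))

  df <- as_tibble(log)
  df$orig_index <- seq_len(nrow(df))

  lead_ipi <- df$ipi_ms[1]
  drop_lead <- params$leading_ipi_rule == "always_drop" ||
    lead_ipi > params$leading_ipi_threshold_ms
  if (drop_lead && lead_ipi > 0) {
    df$ipi_ms[1] <- 0
    report <- bind_rows(report, tibble(
      action = "drop_leading_ipi", record_index = 1L,
      detail = sprintf("removed %0.f ms device-on interval", lead_ipi)))
  }

  repeat {
    bad <- which(df$pd_ms < params$min_plausible_pd_ms)
    if (!length(bad)) break
    i <- bad[1]
    orig <- df$orig_index[i]
    if (!params$merge_fragments) {
      report <- bind_rows(report, tibble(
        action = "delete_fragment", record_index = as.integer(orig),
        detail = sprintf("deleted %0.f ms record", df$pd_ms[i])))
      df <- df[-i, , drop = FALSE]
    } else if (i > 1) {
      # absorb fragment and the gap before it into the preceding puff
      df$pd_ms[i - 1] <- df$pd_ms[i - 1] + df$ipi_ms[i] + df$pd_ms[i]
      report <- bind_rows(report, tibble(
        action = "merge_into_preceding", record_index = as.integer(orig),
        detail = sprintf("merged %0.f ms record (+%0.f ms gap) into record %d",
                         df$pd_ms[i], df$ipi_ms[i], df$orig_index[i - 1])))
      df <- df[-i, , drop = FALSE]
    } else if (nrow(df) > 1) {
      # first record: absorb into the following puff, keeping its lead IPI
      df$pd_ms[2] <- df$pd_ms[1] + df$ipi_ms[2] + df$pd_ms[2]
      df$ipi_ms[2] <- df$ipi_ms[1]
      report <- bind_rows(report, tibble(
        action = "merge_into_following", record_index = as.integer(orig),
        detail = sprintf("merged %0.f ms first record into record %d",
                         df$pd_ms[1], df$orig_index[2])))
      df <- df[-1, , drop = FALSE]
    } else {
      report <- bind_rows(report, tibble(
        action = "delete_fragment", record_index = as.integer(orig),
        detail = "deleted sole implausible record"))
      df <- df[-1, , drop = FALSE]
    }
  }
  df$orig_index <- NULL
  list(log = cress_log(df), report = report)
}

#' Substitute outlier IPIs by the mean of the remaining IPIs
#'
#' The corrected-series rule: IPIs flagged as abnormally short or long are
#' replaced by the arithmetic mean of the non-flagged IPIs. The PD list and
#' the number of IPIs are untouched. The operation is idempotent: replacing
#' flags with the in-range mean leaves nothing new to flag on a second pass
#' under the same rule.
#'
#' @param series A [topography()].
#' @param rule An [outlier_rule()].
#' @return A list with `series` (corrected [topography()], source
#'   `"cress_corrected"`) and `flags` (logical, one per IPI).
#' @export
correct_ipis <- function(series, rule = outlier_rule()) {
  stopifnot(inherits(series, "topography"))
  ipi <- series$ipi_ms
  if (length(ipi) == 0) {
    return(list(series = topography(series$pd_ms, ipi, "cress_corrected"),
                flags = logical()))
  }
  method <- rule$method
  if (method == "mad" && length(ipi) < 3) {
    warn("fewer than 3 IPIs: MAD rule is undefined, series returned unchanged.")
    return(list(series = topography(series$pd_ms, ipi, "cress_corrected"),
                flags = rep(FALSE, length(ipi))))
  }
  flags <- if (method == "range") {
    ipi < rule$min_ipi_ms | ipi > rule$max_ipi_ms
  } else {
    abs(ipi - stats::median(ipi)) > rule$mad_k * stats::mad(ipi)
  }
  if (all(flags)) {
    abort("every IPI is flagged as an outlier: no reference set remains to substitute from.")
  }
  ipi[flags] <- mean(ipi[!flags])
  list(series = topography(series$pd_ms, ipi, "cress_corrected"),
       flags = flags)
}

#' Corrected device-log topography (clean, drop lead, substitute outliers)
#'
#' The full correction pipeline for a device log: plausibility cleaning
#' ([clean_cress()]), conversion to a topography series with the leading
#' device-on interval dropped ([cress_to_topography()]), then outlier-IPI
#' substitution ([correct_ipis()]).
#'
#' @param log A [cress_log()].
#' @param cleaning A [cleaning_params()].
#' @param rule An [outlier_rule()].
#' @return A list with `series` (a [topography()] tagged `cress_corrected`),
#'   `flags` (per-IPI outlier flags), and `report` (cleaning actions).
#' @export
ccress_pipeline <- function(log, cleaning = cleaning_params(),
                            rule = outlier_rule()) {
  cleaned <- clean_cress(log, cleaning)
  series <- cress_to_topography(cleaned$log, drop_leading_ipi = TRUE)
  corrected <- correct_ipis(series, rule)
  list(series = corrected$series, flags = corrected$flags,
       report = cleaned$report)
}
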