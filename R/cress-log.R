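#' Construct and validate a per-puff topography device log
#'
#' Mirrors the detailed per-puff view exported by mouthpiece topography
#' devices: puff volume, average flow, peak flow, time of peak flow, puff
#' duration (PD) and interpuff interval (IPI). `ipi_ms` is the interval
#' *preceding* each puff, so the first record carries the device-on to
#' first-puff interval. Flow fields are carried opaquely (units as exported)
#' and may be missing.
#'
#' @param data A data frame with at least `pd_ms` and `ipi_ms`; optional
#'   `puff_index`, `puff_volume_ml`, `avg_flow`, `peak_flow`,
#'   `time_of_peak_flow_ms`.
#' @return A tibble of class `cress_log` with the full column set (missing
#'   optional fields filled with `NA`).
#' @export
cress_log <- function(data = NULL) {
  cols <- c("puff_index", "puff_volume_ml", "avg_flow", "peak_flow",
            "time_of_peak_flow_ms", "pd_ms", "ipi_ms")
  if (is.null(data) || nrow(as_tibble(data)) == 0) {
    out <- tibble(puff_index = integer(), puff_volume_ml = numeric(),
                  avg_flow = numeric(), peak_flow = numeric(),
                  time_of_peak_flow_ms = numeric(), pd_ms = numeric(),
                  ipi_ms = numeric())
    return(structure(out, class = c("cress_log", class(tibble()))))
  }
  data <- as_tibble(data)
  if (!all(c("pd_ms", "ipi_ms") %in% names(data))) {
    abort("device log must contain `pd_ms` and `ipi_ms` columns.")
  }
  for (cc in setdiff(cols, names(data))) data[[cc]] <- NA_real_
  data <- data[cols]
  data$puff_index <- seq_len(nrow(data))
  data$pd_ms <- as.numeric(data$pd_ms)
  data$ipi_ms <- as.numeric(data$ipi_ms)
  if (any(!is.finite(data$pd_ms)) || any(data$pd_ms <= 0)) {
    i <- which(!is.finite(data$pd_ms) | data$pd_ms <= 0)[1]
    abort(sprintf("record %d has non-positive pd_ms (%s).", i, data$pd_ms[i]))
  }
  if (any(!is.finite(data$ipi_ms)) || any(data$ipi_ms < 0)) {
    i <- which(!is.finite(data$ipi_ms) | data$ipi_ms < 0)[1]
    abort(sprintf("record %d has negative ipi_ms (%s).", i, data$ipi_ms[i]))
  }
  structure(data, class = c("cress_log", class(tibble())))
}

#' Read / write a device log CSV
#'
#' Columns `puff_index,puff_volume_ml,avg_flow,peak_flow,time_of_peak_flow_ms,
#' pd_ms,ipi_ms`. Missing optional flow fields are tolerated and flagged with
#' a warning; an empty data section yields an empty log with a warning.
#'
#' @param path File path.
#' @return `read_cress_log()` returns a [cress_log()] tibble;
#'   `write_cress_log()` returns `path` invisibly.
#' @export
read_cress_log <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double())))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed device log `%s`: parse problem at line %d",
                  path, probs$row[1]))
  }
  if (nrow(df) == 0) {
    warn(sprintf("device log `%s` has an empty data section.", path))
    return(cress_log())
  }
  optional <- c("puff_volume_ml", "avg_flow", "peak_flow", "time_of_peak_flow_ms")
  absent <- setdiff(optional, names(df))
  if (length(absent)) {
    warn(sprintf("device log `%s` is missing optional field(s): %s",
                 path, paste(absent, collapse = ", ")))
  }
  cress_log(df)
}

#' @rdname read_cress_log
#' @param log A [cress_log()] tibble.
#' @export
write_cress_log <- function(log, path) {
  log <- cress_log(log)
  readr::write_csv(as_tibble(log), path)
  invisible(path)
}
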