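#' Construct and validate an accelerometer trace
#'
#' An accelerometer trace is a tibble with one row per sample and columns
#' `t_ms` (integer milliseconds since session start, strictly increasing on a
#' uniform grid), and `x`, `y`, `z` (acceleration in m/s^2). The sampling rate
#' in Hz is carried as the `sampling_rate` attribute (default 30, the rate of
#' the wrist device the pipeline targets).
#'
#' @param data A data frame with columns `t_ms`, `x`, `y`, `z`.
#' @param sampling_rate Samples per second. If `NULL`, inferred from the
#'   median inter-sample gap.
#' @return A tibble of class `accel_trace`.
#' @export
accel_trace <- function(data, sampling_rate = NULL) {
  data <- as_tibble(data)
  required <- c("t_ms", "x", "y", "z")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(sprintf("accel trace is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  data <- data[required]
  data$t_ms <- as.numeric(data$t_ms)
  if (nrow(data) >= 2) {
    data <- arrange(data, .data$t_ms)
    gaps <- diff(data$t_ms)
    if (any(gaps <= 0)) {
      abort("accel trace timestamps must be strictly increasing (duplicate or out-of-order t_ms).")
    }
    med_gap <- stats::median(gaps)
    if (is.null(sampling_rate)) {
      sampling_rate <- round(1000 / med_gap)
    }
    expected_gap <- 1000 / sampling_rate
    # Tolerate ms rounding (33/34 ms alternation at 30 Hz): gaps must stay
    # within 5% of the nominal spacing, after allowing 1 ms of rounding.
    if (any(abs(gaps - expected_gap) > pmax(1, 0.05 * expected_gap))) {
      bad <- which(abs(gaps - expected_gap) > pmax(1, 0.05 * expected_gap))[1]
      abort(sprintf(
        "non-uniform sampling: gap of %s ms between rows %d and %d (expected ~%.1f ms at %g Hz)",
        gaps[bad], bad, bad + 1, expected_gap, sampling_rate))
    }
  } else if (is.null(sampling_rate)) {
    sampling_rate <- 30
  }
  for (ax in c("x", "y", "z")) {
    v <- data[[ax]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      abort(sprintf("accel trace axis `%s` must be finite numeric.", ax))
    }
  }
  assert_scalar_number(sampling_rate, "sampling_rate", min = 0, strict_min = TRUE)
  structure(data,
            sampling_rate = sampling_rate,
            class = c("accel_trace", class(tibble())))
}

#' Sampling rate of an accelerometer trace
#' @param trace An [accel_trace()].
#' @return Samples per second.
#' @export
sampling_rate <- function(trace) {
  attr(trace, "sampling_rate") %||% 30
}

#' Convert a sample count to milliseconds
#'
#' With a known sampling rate the duration covered by `n_samples` timesteps is
#' `n_samples * 1000 / sampling_rate`, rounded to the nearest integer
#' millisecond.
#'
#' @param n_samples Non-negative number of samples.
#' @param sampling_rate Samples per second (> 0), default 30.
#' @return Integer milliseconds.
#' @examples
#' samples_to_ms(30, 30) # one second
#' @export
samples_to_ms <- function(n_samples, sampling_rate = 30) {
  if (any(!is.finite(n_samples)) || any(n_samples < 0)) {
    abort("`n_samples` must be non-negative and finite.")
  }
  assert_scalar_number(sampling_rate, "sampling_rate", min = 0, strict_min = TRUE)
  as.integer(round(n_samples * 1000 / sampling_rate))
}

#' Read / write an accelerometer trace CSV
#'
#' The on-disk format is CSV with a header row `t_ms,x,y,z`, UTF-8, `.` as
#' decimal separator. Rows are re-sorted by time on read.
#'
#' @param path File path.
#' @param sampling_rate Optional declared rate; inferred when `NULL`.
#' @return `read_accel_trace()` returns an [accel_trace()];
#'   `write_accel_trace()` returns `path` invisibly.
#' @export
read_accel_trace <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double())))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed accelerometer table `%s`: parse problem at line %d (%s)",
                  path, probs$row[1], probs$expected[1]))
  }
  accel_trace(df, sampling_rate = sampling_rate)
}

#' @rdname read_accel_trace
#' @param trace An [accel_trace()].
#' @export
write_accel_trace <- function(trace, path) {
  trace <- accel_trace(trace, sampling_rate = sampling_rate(trace))
  readr::write_csv(as_tibble(trace), path)
  invisible(path)
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace: %d samples at %g Hz, %.1f s>\n",
              nrow(x), sampling_rate(x),
              if (nrow(x)) (max(x$t_ms) - min(x$t_ms)) / 1000 else 0))
  NextMethod()
}

#' Plot an accelerometer trace
#'
#' One panel per axis against time; puff events, when supplied, are shaded.
#'
#' @param object An [accel_trace()].
#' @param events Optional [puff_events()] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accel_trace <- function(object, events = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("x", "y", "z"),
                              names_to = "axis", values_to = "accel")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t_ms / 1000, y = .data$accel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = expression("acceleration (m/"*s^2*")"))
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(events),
      ggplot2::aes(xmin = .data$start_ms / 1000, xmax = .data$end_ms / 1000),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "tomato",
      inherit.aes = FALSE)
  }
  p
}
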