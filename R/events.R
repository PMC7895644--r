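#' Construct and validate a puff-event list
#'
#' A puff event is the half-open interval `[start_ms, end_ms)` during which the
#' hand holds the cigarette at the mouth; puff duration is `end_ms - start_ms`.
#' Events in a session are sorted by start and must not overlap
#' (`end_ms[i] <= start_ms[i + 1]`).
#'
#' @param start_ms,end_ms Integer milliseconds since session start.
#' @param hand `"left"`, `"right"` or `"unknown"` per event (recycled).
#' @return A tibble of class `puff_events` with columns `start_ms`, `end_ms`,
#'   `hand`.
#' @export
puff_events <- function(start_ms = integer(), end_ms = integer(),
                        hand = "unknown") {
  if (is.data.frame(start_ms)) {
    df <- start_ms
    start_ms <- df$start_ms
    end_ms <- df$end_ms
    hand <- df$hand %||% "unknown"
  }
  if (length(start_ms) != length(end_ms)) {
    abort("`start_ms` and `end_ms` must have the same length.")
  }
  hand <- rep_len(as.character(hand), length(start_ms))
  bad_hand <- setdiff(unique(hand), c("left", "right", "unknown"))
  if (length(bad_hand)) {
    abort(sprintf("`hand` must be left/right/unknown (got %s).",
                  paste(bad_hand, collapse = ", ")))
  }
  ev <- tibble(start_ms = as.numeric(start_ms),
               end_ms = as.numeric(end_ms),
               hand = hand)
  if (nrow(ev)) {
    if (any(!is.finite(ev$start_ms)) || any(!is.finite(ev$end_ms))) {
      abort("event timestamps must be finite.")
    }
    if (any(ev$end_ms <= ev$start_ms)) {
      i <- which(ev$end_ms <= ev$start_ms)[1]
      abort(sprintf("event %d has end_ms <= start_ms (%s <= %s).",
                    i, ev$end_ms[i], ev$start_ms[i]))
    }
    ev <- arrange(ev, .data$start_ms)
    if (nrow(ev) > 1 && any(ev$end_ms[-nrow(ev)] > ev$start_ms[-1])) {
      i <- which(ev$end_ms[-nrow(ev)] > ev$start_ms[-1])[1]
      abort(sprintf("events %d and %d overlap.", i, i + 1L))
    }
  }
  structure(ev, class = c("puff_events", class(tibble())))
}

#' Read / write puff events as CSV
#'
#' Columns `start_ms,end_ms,hand`; a header-only file encodes an empty list.
#' The pair is a lossless round trip on valid inputs.
#'
#' @param events A [puff_events()] tibble.
#' @param path File path.
#' @return `read_events()` returns a [puff_events()] tibble;
#'   `write_events()` returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  events <- puff_events(events)
  readr::write_csv(as_tibble(events), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          start_ms = readr::col_double(),
                          end_ms = readr::col_double(),
                          hand = readr::col_character()))
  puff_events(df)
}

#' Keep only events fully inside a time window
#'
#' Events straddling a window boundary are dropped, not truncated: a puff that
#' is only partially observable by a method should not contribute a biased
#' partial duration to the comparison.
#'
#' @param events A [puff_events()] tibble.
#' @param window_start_ms,window_end_ms Window bounds in ms, start < end.
#' @return The retained [puff_events()].
#' @export
restrict_to_window <- function(events, window_start_ms, window_end_ms) {
  if (window_start_ms >= window_end_ms) {
    abort("`window_start_ms` must be < `window_end_ms`.")
  }
  events <- puff_events(events)
  keep <- events$start_ms >= window_start_ms & events$end_ms <= window_end_ms
  puff_events(events[keep, , drop = FALSE])
}
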