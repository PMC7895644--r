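#' Laboratory protocol schedule
#'
#' A schedule is an ordered tibble of activity segments, one row per segment,
#' with columns `activity` (one of `rest`, `smoking_left`, `smoking_right`,
#' `packing`, `other_movement`) and `duration_s` (> 0 seconds).
#'
#' @param data A data frame with columns `activity` and `duration_s`.
#' @param session_length_s Optional total length the segments must sum to.
#' @return A tibble of class `protocol_schedule`.
#' @export
protocol_schedule <- function(data, session_length_s = NULL) {
  data <- as_tibble(data)
  if (!all(c("activity", "duration_s") %in% names(data))) {
    abort("schedule needs columns `activity` and `duration_s`.")
  }
  allowed <- c("rest", "smoking_left", "smoking_right", "packing",
               "other_movement")
  bad <- setdiff(unique(data$activity), allowed)
  if (length(bad)) {
    abort(sprintf("unknown activity label(s): %s", paste(bad, collapse = ", ")))
  }
  data$duration_s <- as.numeric(data$duration_s)
  if (any(!is.finite(data$duration_s)) || any(data$duration_s <= 0)) {
    abort("all segment durations must be positive and finite.")
  }
  if (!is.null(session_length_s) &&
      abs(sum(data$duration_s) - session_length_s) > 1e-9) {
    abort(sprintf("segments sum to %g s, expected %g s.",
                  sum(data$duration_s), session_length_s))
  }
  structure(data[c("activity", "duration_s")],
            class = c("protocol_schedule", class(tibble())))
}

#' Default 20-minute laboratory schedule
#'
#' Mirrors the laboratory paradigm the simulator emulates: a 20-minute
#' session containing 6 minutes of smoking split evenly between hands, 52
#' seconds of packing the cigarette pack, and over 7 minutes of other
#' (non-smoking) movements, with rest periods in between. The exact ordering
#' and the breakdown of the non-packing movement time are a package choice;
#' both are configurable through [protocol_schedule()].
#'
#' @return A `protocol_schedule` totalling 1200 s.
#' @export
default_protocol_schedule <- function() {
  protocol_schedule(tibble(
    activity = c("rest", "other_movement", "packing", "smoking_left",
                 "smoking_right", "other_movement", "rest",
                 "other_movement", "rest"),
    duration_s = c(120, 150, 52, 180, 180, 150, 150, 120, 98)
  ), session_length_s = 1200)
}

# Segment table with absolute start/end in ms.
schedule_segments <- function(schedule) {
  schedule <- protocol_schedule(schedule)
  ends <- cumsum(schedule$duration_s) * 1000
  mutate(as_tibble(schedule),
         start_ms = c(0, ends[-length(ends)]),
         end_ms = ends)
}
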