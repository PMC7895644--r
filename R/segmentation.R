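#' Parameters of the puff-gesture segmenter
#'
#' The segmenter operationalizes the manual annotation signature: a puff
#' begins with a moderate drop in y (about 4 m/s^2) and a sharp drop in z
#' (about 8 m/s^2) from the resting pose, followed by a period of
#' uninterrupted, equilibrated values while the hand is at the mouth, and
#' ends when all axes return to the resting state. The x axis changes only
#' negligibly at onset and is ignored for triggering.
#'
#' @param baseline_window_s Window length for resting-pose estimation
#'   (default 30 s).
#' @param onset_fraction Fraction of the nominal onset deltas (y 4, z 8
#'   m/s^2) that must be crossed to trigger (default 0.5).
#' @param onset_delta_y,onset_delta_z Nominal onset drops in m/s^2
#'   (defaults 4 and 8).
#' @param plateau_tolerance Band around the running plateau estimate within
#'   which the hold must stay, m/s^2 (default 1.5).
#' @param min_plateau_ms Minimum plateau hold to accept a puff (default 500).
#' @param offset_return_tolerance Band around rest within which the signal
#'   must settle to close a puff, m/s^2 (default 1.5).
#' @param min_return_ms Required rest hold to confirm the end (default 300).
#' @param smoothing_window_samples Centered moving-average width
#'   (default 5, about 167 ms at 30 Hz).
#' @param refine_lookaround_s How far around a candidate plateau the
#'   boundary-refinement crossing search extends (default 3 s).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(baseline_window_s = 30,
                                onset_fraction = 0.5,
                                onset_delta_y = 4,
                                onset_delta_z = 8,
                                plateau_tolerance = 1.5,
                                min_plateau_ms = 500,
                                offset_return_tolerance = 1.5,
                                min_return_ms = 300,
                                smoothing_window_samples = 5L,
                                refine_lookaround_s = 3) {
  assert_scalar_number(onset_fraction, "onset_fraction", min = 0, max = 1,
                       strict_min = TRUE)
  assert_scalar_number(plateau_tolerance, "plateau_tolerance", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(offset_return_tolerance, "offset_return_tolerance",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(min_plateau_ms, "min_plateau_ms", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(min_return_ms, "min_return_ms", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(baseline_window_s, "baseline_window_s", min = 0,
                       strict_min = TRUE)
  structure(list(baseline_window_s = baseline_window_s,
                 onset_fraction = onset_fraction,
                 onset_delta_y = onset_delta_y,
                 onset_delta_z = onset_delta_z,
                 plateau_tolerance = plateau_tolerance,
                 min_plateau_ms = min_plateau_ms,
                 offset_return_tolerance = offset_return_tolerance,
                 min_return_ms = min_return_ms,
                 smoothing_window_samples = as.integer(smoothing_window_samples),
                 refine_lookaround_s = refine_lookaround_s),
            class = "segmentation_params")
}

#' Estimate the per-session resting wrist pose
#'
#' Poses vary across participants, so the baseline is estimated per session:
#' the window of length `baseline_window_s` minimizing the summed rolling
#' variance across axes is taken as the quietest stretch, and the pose is the
#' per-axis median over that window, with per-axis median absolute deviation
#' as dispersion. If a session consists almost entirely of one sustained
#' plateau the estimate locks onto that plateau; the 20-minute protocol this
#' package targets makes that configuration unlikely.
#'
#' @param trace An [accel_trace()].
#' @param params A [segmentation_params()].
#' @return A one-row tibble of class `resting_pose` with columns `x`, `y`,
#'   `z`, `disp_x`, `disp_y`, `disp_z`.
#' @export
estimate_resting_pose <- function(trace, params = segmentation_params()) {
  trace <- accel_trace(trace, sampling_rate = sampling_rate(trace))
  w <- max(2L, round(params$baseline_window_s * sampling_rate(trace)))
  n <- nrow(trace)
  if (n < w) {
    abort(sprintf("trace (%d samples) is shorter than the baseline window (%d samples).",
                  n, w))
  }
  roll_var <- function(v) {
    c1 <- cumsum(c(0, v)); c2 <- cumsum(c(0, v^2))
    s1 <- c1[(w + 1):(n + 1)] - c1[1:(n - w + 1)]
    s2 <- c2[(w + 1):(n + 1)] - c2[1:(n - w + 1)]
    (s2 - s1^2 / w) / (w - 1)
  }
  total <- roll_var(trace$x) + roll_var(trace$y) + roll_var(trace$z)
  i0 <- which.min(total)
  idx <- i0:(i0 + w - 1)
  pose <- tibble(
    x = stats::median(trace$x[idx]),
    y = stats::median(trace$y[idx]),
    z = stats::median(trace$z[idx]),
    disp_x = stats::mad(trace$x[idx]),
    disp_y = stats::mad(trace$y[idx]),
    disp_z = stats::mad(trace$z[idx]))
  structure(pose, class = c("resting_pose", class(tibble())))
}

# Last linear-interpolated time x crosses `level` downward at or before
# index `before`, looking back at most `lookback` samples.
last_down_crossing <- function(t, x, level, before, lookback) {
  lo <- max(1L, before - lookback)
  idx <- lo:max(lo, before)
  above <- x[idx] > level
  cross <- which(above[-length(above)] & !above[-1])
  if (!length(cross)) return(NA_real_)
  i <- idx[cross[length(cross)]]
  x0 <- x[i]; x1 <- x[i + 1]
  if (x1 == x0) return(t[i + 1])
  t[i] + (level - x0) / (x1 - x0) * (t[i + 1] - t[i])
}

# First linear-interpolated time x crosses `level` upward at or after
# index `after`, looking forward at most `lookahead` samples.
first_up_crossing <- function(t, x, level, after, lookahead) {
  hi <- min(length(x), after + lookahead)
  idx <- min(after, hi):hi
  below <- x[idx] < level
  cross <- which(below[-length(below)] & !below[-1])
  if (!length(cross)) return(NA_real_)
  i <- idx[cross[1]]
  x0 <- x[i]; x1 <- x[i + 1]
  if (x1 == x0) return(t[i + 1])
  t[i] + (level - x0) / (x1 - x0) * (t[i + 1] - t[i])
}

#' Detect puff events in an accelerometer trace
#'
#' Hysteresis detection of the puff gesture. A candidate opens when the
#' smoothed y and z both drop below the resting pose by at least
#' `onset_fraction` of the nominal onset deltas; it is accepted if the signal
#' then holds within `plateau_tolerance` of the candidate's plateau estimate
#' for at least `min_plateau_ms`. A candidate closes once all axes settle
#' back within `offset_return_tolerance` of rest for `min_return_ms`;
#' candidates not separated by such a confirmed return merge into a single
#' event (rapid multi-puffs are reported as one puff). Event boundaries are
#' then refined to the plateau edges by locating the 25% and 75% crossing
#' times of the rest-to-plateau z transition and extrapolating the linear
#' ramp, which makes the reported duration the plateau hold itself rather
#' than a threshold-dependent span.
#'
#' @param trace An [accel_trace()].
#' @param pose A `resting_pose`; estimated from the trace when `NULL`.
#' @param params A [segmentation_params()].
#' @return A [puff_events()] tibble (`hand = "unknown"`); empty when nothing
#'   is detected.
#' @export
detect_puffs <- function(trace, pose = NULL, params = segmentation_params()) {
  trace <- accel_trace(trace, sampling_rate = sampling_rate(trace))
  if (is.null(pose)) pose <- estimate_resting_pose(trace, params)
  rate <- sampling_rate(trace)
  t <- trace$t_ms
  n <- nrow(trace)
  w <- params$smoothing_window_samples
  sx <- moving_average(trace$x, w)
  sy <- moving_average(trace$y, w)
  sz <- moving_average(trace$z, w)

  f <- params$onset_fraction
  deep <- (sy <= pose$y - f * params$onset_delta_y) &
          (sz <= pose$z - f * params$onset_delta_z)
  if (!any(deep)) return(puff_events())

  min_plat <- max(2L, round(params$min_plateau_ms / 1000 * rate))
  min_ret <- max(1L, round(params$min_return_ms / 1000 * rate))
  look <- max(2L, round(params$refine_lookaround_s * rate))

  r <- rle(deep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])

  # plateau-hold acceptance: the run must contain a stable stretch
  has_hold <- purrr::map_lgl(seq_len(nrow(runs)), function(k) {
    idx <- runs$start[k]:runs$end[k]
    my <- stats::median(sy[idx]); mz <- stats::median(sz[idx])
    ok <- abs(sy[idx] - my) <= params$plateau_tolerance &
          abs(sz[idx] - mz) <= params$plateau_tolerance
    rr <- rle(ok)
    any(rr$values & rr$lengths >= min_plat)
  })
  runs <- runs[has_hold, , drop = FALSE]
  if (nrow(runs) == 0) return(puff_events())

  # confirmed return to rest between consecutive runs, else merge
  at_rest <- abs(sx - pose$x) <= params$offset_return_tolerance &
             abs(sy - pose$y) <= params$offset_return_tolerance &
             abs(sz - pose$z) <= params$offset_return_tolerance
  group <- cumsum(c(TRUE, purrr::map_lgl(seq_len(nrow(runs))[-1], function(k) {
    gap <- (runs$end[k - 1] + 1L):(runs$start[k] - 1L)
    if (length(gap) < min_ret) return(FALSE)
    rr <- rle(at_rest[gap])
    any(rr$values & rr$lengths >= min_ret)
  })))
  groups <- tibble(start = runs$start, end = runs$end, group = group) |>
    group_by(.data$group) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")

  events <- purrr::pmap(groups[c("start", "end")], function(start, end) {
    idx <- start:end
    plat_z <- stats::median(sz[idx])
    l25 <- pose$z + 0.25 * (plat_z - pose$z)
    l75 <- pose$z + 0.75 * (plat_z - pose$z)
    # linear-ramp extrapolation: plateau edge = t75 +/- half the 25->75 span
    t25d <- last_down_crossing(t, sz, l25, start, look)
    t75d <- last_down_crossing(t, sz, l75, min(start + min_plat, end), look)
    t25u <- first_up_crossing(t, sz, l25, end, look)
    t75u <- first_up_crossing(t, sz, l75, max(end - min_plat, start), look)
    s_ms <- if (!is.na(t25d) && !is.na(t75d) && t75d > t25d) {
      t75d + 0.5 * (t75d - t25d)
    } else t[start]
    e_ms <- if (!is.na(t25u) && !is.na(t75u) && t25u > t75u) {
      t75u - 0.5 * (t25u - t75u)
    } else t[end]
    c(round(s_ms), round(e_ms))
  })
  out <- tibble(start_ms = purrr::map_dbl(events, 1),
                end_ms = purrr::map_dbl(events, 2))
  # guard against refinement degeneracies: keep ordering and minimum hold
  out <- filter(out, .data$end_ms - .data$start_ms >= params$min_plateau_ms)
  if (nrow(out) > 1) {
    out$start_ms <- pmax(out$start_ms, c(-Inf, out$end_ms[-nrow(out)]))
    out <- filter(out, .data$end_ms - .data$start_ms >= params$min_plateau_ms)
  }
  puff_events(out$start_ms, out$end_ms, hand = "unknown")
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching by event-midpoint distance: candidate pairs
#' within `max_offset_ms` are ranked by midpoint distance and assigned
#' best-first. The returned counts partition both lists.
#'
#' @param detected,truth [puff_events()] tibbles (sorted).
#' @param max_offset_ms Maximum midpoint distance for a match (default 1000).
#' @return A list with `true_positives`, `false_positives`, `misses`,
#'   `precision`, `recall`, `f1`, and `pairs` (tibble of matched index pairs
#'   with their midpoint and boundary offsets in ms).
#' @export
match_events <- function(detected, truth, max_offset_ms = 1000) {
  detected <- puff_events(detected)
  truth <- puff_events(truth)
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(true_positives = 0L, false_positives = nd, misses = nt,
                precision = if (nd) 0 else NA_real_,
                recall = if (nt) 0 else NA_real_,
                f1 = if (nd || nt) 0 else NA_real_,
                pairs = tibble(detected = integer(), truth = integer(),
                               midpoint_offset_ms = numeric(),
                               start_offset_ms = numeric(),
                               end_offset_ms = numeric())))
  }
  mid_d <- (detected$start_ms + detected$end_ms) / 2
  mid_t <- (truth$start_ms + truth$end_ms) / 2
  cand <- tidyr::expand_grid(detected = seq_len(nd), truth = seq_len(nt)) |>
    mutate(dist = abs(mid_d[.data$detected] - mid_t[.data$truth])) |>
    filter(.data$dist <= max_offset_ms) |>
    arrange(.data$dist)
  used_d <- logical(nd); used_t <- logical(nt)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    di <- cand$detected[i]; ti <- cand$truth[i]
    if (!used_d[di] && !used_t[ti]) {
      used_d[di] <- used_t[ti] <- TRUE
      keep[i] <- TRUE
    }
  }
  det_start <- detected$start_ms; det_end <- detected$end_ms
  tr_start <- truth$start_ms; tr_end <- truth$end_ms
  pairs <- cand[keep, , drop = FALSE] |>
    mutate(midpoint_offset_ms = .data$dist,
           start_offset_ms = det_start[.data$detected] - tr_start[.data$truth],
           end_offset_ms = det_end[.data$detected] - tr_end[.data$truth]) |>
    select(-"dist") |>
    arrange(.data$detected)
  tp <- nrow(pairs)
  precision <- tp / nd
  recall <- tp / nt
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(true_positives = tp, false_positives = nd - tp, misses = nt - tp,
       precision = precision, recall = recall, f1 = f1, pairs = pairs)
}
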