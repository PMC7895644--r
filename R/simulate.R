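#' Simulation configuration for a laboratory smoking session
#'
#' Defines the conditions of a simulated 20-minute laboratory session: the
#' activity schedule, how many puffs each hand takes, the per-session puff
#' duration (PD) and interpuff interval (IPI) distributions, the wrist poses
#' that define the puff gesture, and the measurement noise level.
#'
#' The gesture model: at rest the wrist sits at `rest_pose`; during a puff it
#' holds `plateau_pose` (around 9, -5, -3 m/s^2 — hand at mouth). The onset
#' is a drop of about 4 m/s^2 in y and 8 m/s^2 in z (x barely moves). A truth
#' puff event spans the plateau interval; the linear rest-to-plateau ramps of
#' `transition_ms` each lie immediately outside it.
#'
#' @param seed Integer seed; identical config + seed reproduces the session
#'   bit-exactly.
#' @param schedule A [protocol_schedule()]; default [default_protocol_schedule()].
#' @param n_puffs_per_hand Puffs taken in each smoking segment (default 6).
#' @param pd_distribution,ipi_distribution Log-normal draws as
#'   `list(median_ms =, sigma =)`; defaults median PD 1500 ms (sigma 0.3) and
#'   median IPI 20000 ms (sigma 0.4).
#' @param rest_pose,plateau_pose Numeric xyz in m/s^2; defaults `c(9, -1, 5)`
#'   and `c(9, -5, -3)`.
#' @param transition_ms Rest-to-plateau ramp duration (default 500).
#' @param noise_sd Additive white accelerometer noise, m/s^2 (default 0.2).
#' @param sampling_rate Samples per second (default 30).
#' @param watch_hand Which wrist wears the watch (`"left"`); puffs taken with
#'   the other hand exist in the truth but leave no gesture in the trace.
#' @param segment_margin_ms Quiet margin kept at each end of a smoking
#'   segment (default 3000).
#' @param max_retries Resampling attempts before declaring a segment
#'   infeasible (default 100).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              schedule = default_protocol_schedule(),
                              n_puffs_per_hand = 6L,
                              pd_distribution = list(median_ms = 1500, sigma = 0.3),
                              ipi_distribution = list(median_ms = 20000, sigma = 0.4),
                              rest_pose = c(9, -1, 5),
                              plateau_pose = c(9, -5, -3),
                              transition_ms = 500,
                              noise_sd = 0.2,
                              sampling_rate = 30,
                              watch_hand = "left",
                              segment_margin_ms = 3000,
                              max_retries = 100L) {
  cfg <- list(seed = as.integer(seed), schedule = protocol_schedule(schedule),
              n_puffs_per_hand = as.integer(n_puffs_per_hand),
              pd_distribution = pd_distribution,
              ipi_distribution = ipi_distribution,
              rest_pose = as.numeric(rest_pose),
              plateau_pose = as.numeric(plateau_pose),
              transition_ms = transition_ms, noise_sd = noise_sd,
              sampling_rate = sampling_rate, watch_hand = watch_hand,
              segment_margin_ms = segment_margin_ms,
              max_retries = as.integer(max_retries))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  assert_scalar_number(cfg$n_puffs_per_hand, "n_puffs_per_hand", min = 0)
  assert_scalar_number(cfg$pd_distribution$median_ms,
                       "pd_distribution$median_ms", min = 0, strict_min = TRUE)
  assert_scalar_number(cfg$ipi_distribution$median_ms,
                       "ipi_distribution$median_ms", min = 0, strict_min = TRUE)
  assert_scalar_number(cfg$pd_distribution$sigma, "pd_distribution$sigma", min = 0)
  assert_scalar_number(cfg$ipi_distribution$sigma, "ipi_distribution$sigma", min = 0)
  assert_scalar_number(cfg$noise_sd, "noise_sd", min = 0)
  assert_scalar_number(cfg$transition_ms, "transition_ms", min = 0, strict_min = TRUE)
  assert_scalar_number(cfg$sampling_rate, "sampling_rate", min = 0, strict_min = TRUE)
  if (length(cfg$rest_pose) != 3 || length(cfg$plateau_pose) != 3) {
    abort("`rest_pose` and `plateau_pose` must be xyz triples.")
  }
  if (!cfg$watch_hand %in% c("left", "right")) {
    abort("`watch_hand` must be 'left' or 'right'.")
  }
  invisible(cfg)
}

# Draw a feasible puff train for one smoking segment; events span plateaus
# only, with transition ramps and quiet margins kept inside the segment.
draw_segment_events <- function(seg_start_ms, seg_end_ms, hand, cfg) {
  n <- cfg$n_puffs_per_hand
  if (n == 0) return(puff_events())
  lead <- cfg$segment_margin_ms + cfg$transition_ms
  avail <- (seg_end_ms - seg_start_ms) - 2 * lead
  for (attempt in seq_len(cfg$max_retries)) {
    # floor at 700 ms: shorter "puffs" are not credible inhalations (they
    # exist in device logs only as split artifacts)
    pd <- pmax(700, stats::rlnorm(n, log(cfg$pd_distribution$median_ms),
                                  cfg$pd_distribution$sigma))
    ipi <- if (n > 1) {
      stats::rlnorm(n - 1, log(cfg$ipi_distribution$median_ms),
                    cfg$ipi_distribution$sigma)
    } else numeric()
    # gaps must also fit the two ramps between consecutive plateaus
    ipi <- pmax(ipi, 2 * cfg$transition_ms + 500)
    if (sum(pd) + sum(ipi) <= avail) {
      starts <- seg_start_ms + lead + cumsum(c(0, pd[-n] + ipi))
      return(puff_events(round(starts), round(starts + pd), hand = hand))
    }
  }
  abort(sprintf(
    "could not fit %d puffs in a %.0f s smoking segment after %d attempts; reduce n_puffs_per_hand or the IPI median.",
    n, (seg_end_ms - seg_start_ms) / 1000, cfg$max_retries))
}

#' Simulate a laboratory smoking session with known ground truth
#'
#' Generates a 3-axis accelerometer trace over the full protocol schedule at
#' the configured sampling rate, together with the true puff events. During
#' each watch-hand puff the pose ramps linearly from rest to plateau over
#' `transition_ms`, holds the plateau for the puff duration, and ramps back.
#' Puffs taken with the non-watch hand are present in the truth but leave the
#' watch-side trace at rest. Packing segments add an oscillatory z
#' perturbation and `other_movement` segments add band-limited multi-axis
#' sway; neither matches the puff signature (their y excursion stays below
#' the onset threshold). White Gaussian noise of sd `noise_sd` is added to
#' every sample.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `trace` ([accel_trace()]), `truth`
#'   ([puff_events()], both hands, sorted), and `schedule` (segment table
#'   with absolute `start_ms`/`end_ms`).
#' @export
simulate_session <- function(config = simulation_config()) {
  validate_simulation_config(config)
  segs <- schedule_segments(config$schedule)
  rate <- config$sampling_rate
  total_ms <- sum(config$schedule$duration_s) * 1000
  n_samp <- round(total_ms / 1000 * rate)
  t_ms <- round((seq_len(n_samp) - 1) * 1000 / rate)

  with_seed_(config$seed, {
    truth <- list()
    for (i in seq_len(nrow(segs))) {
      act <- segs$activity[i]
      if (act %in% c("smoking_left", "smoking_right")) {
        hand <- sub("smoking_", "", act)
        truth[[length(truth) + 1]] <-
          draw_segment_events(segs$start_ms[i], segs$end_ms[i], hand, config)
      }
    }
    truth <- if (length(truth)) puff_events(bind_rows(truth)) else puff_events()

    rest <- config$rest_pose
    plat <- config$plateau_pose
    x <- rep(rest[1], n_samp)
    y <- rep(rest[2], n_samp)
    z <- rep(rest[3], n_samp)

    # render the gesture only for the hand wearing the watch
    watch_events <- truth[truth$hand == config$watch_hand, , drop = FALSE]
    for (k in seq_len(nrow(watch_events))) {
      s <- watch_events$start_ms[k]; e <- watch_events$end_ms[k]
      T <- config$transition_ms
      idx <- which(t_ms >= s - T & t_ms < e + T)
      tt <- t_ms[idx]
      alpha <- rep(1, length(idx))
      down <- tt < s
      up <- tt >= e
      alpha[down] <- (tt[down] - (s - T)) / T
      alpha[up] <- 1 - (tt[up] - e) / T
      x[idx] <- rest[1] + alpha * (plat[1] - rest[1])
      y[idx] <- rest[2] + alpha * (plat[2] - rest[2])
      z[idx] <- rest[3] + alpha * (plat[3] - rest[3])
    }

    # stylized confounder motions; contract: never match the puff signature
    # at zero noise (y excursion < half the 4 m/s^2 onset delta)
    for (i in seq_len(nrow(segs))) {
      idx <- which(t_ms >= segs$start_ms[i] & t_ms < segs$end_ms[i])
      tt <- (t_ms[idx] - segs$start_ms[i]) / 1000
      if (segs$activity[i] == "packing") {
        z[idx] <- z[idx] + 3 * sin(2 * pi * 1.2 * tt)
      } else if (segs$activity[i] == "other_movement") {
        f <- stats::runif(3, c(0.3, 0.5, 0.7), c(0.8, 1.2, 1.6))
        ph <- stats::runif(3, 0, 2 * pi)
        x[idx] <- x[idx] + 1.2 * sin(2 * pi * f[1] * tt + ph[1])
        y[idx] <- y[idx] + 1.4 * sin(2 * pi * f[2] * tt + ph[2])
        z[idx] <- z[idx] + 2.5 * sin(2 * pi * f[3] * tt + ph[3])
      }
    }

    if (config$noise_sd > 0) {
      x <- x + stats::rnorm(n_samp, 0, config$noise_sd)
      y <- y + stats::rnorm(n_samp, 0, config$noise_sd)
      z <- z + stats::rnorm(n_samp, 0, config$noise_sd)
    }

    list(trace = accel_trace(tibble(t_ms = t_ms, x = x, y = y, z = z),
                             sampling_rate = rate),
         truth = truth,
         schedule = segs)
  })
}

#' Artifact configuration for simulated device logs
#'
#' Models the characteristic artifacts of mouthpiece topography logs: a long
#' spurious leading interval (device power-on to first puff), occasional
#' splitting of one physical puff into two records separated by a sub-second
#' interval with a milliseconds-long fragment, and measurement jitter on
#' reported durations.
#'
#' @param seed Integer seed for the artifact draws.
#' @param leading_ipi_ms Interval prepended as record 1's preceding IPI
#'   (default 75000, i.e. over one minute).
#' @param split_probability Per-puff chance of being reported as two records
#'   (default 0).
#' @param split_fragment_pd_ms Duration of the spurious fragment record
#'   (default 5).
#' @param split_gap_ms Sub-second interval separating the split pair
#'   (default 330).
#' @param jitter_sd_ms Gaussian noise added to every reported PD/IPI
#'   (default 0).
#' @return A list of class `cress_artifact_config`.
#' @export
cress_artifact_config <- function(seed = 1L, leading_ipi_ms = 75000,
                                  split_probability = 0,
                                  split_fragment_pd_ms = 5,
                                  split_gap_ms = 330,
                                  jitter_sd_ms = 0) {
  assert_scalar_number(split_probability, "split_probability", min = 0, max = 1)
  assert_scalar_number(split_fragment_pd_ms, "split_fragment_pd_ms",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(split_gap_ms, "split_gap_ms", min = 0, strict_min = TRUE)
  assert_scalar_number(leading_ipi_ms, "leading_ipi_ms", min = 0)
  assert_scalar_number(jitter_sd_ms, "jitter_sd_ms", min = 0)
  structure(list(seed = as.integer(seed), leading_ipi_ms = leading_ipi_ms,
                 split_probability = split_probability,
                 split_fragment_pd_ms = split_fragment_pd_ms,
                 split_gap_ms = split_gap_ms, jitter_sd_ms = jitter_sd_ms),
            class = "cress_artifact_config")
}

#' Simulate a device log from true puff events
#'
#' Converts a truth event list into an ordered per-puff log as a mouthpiece
#' device would report it: `ipi_ms` precedes each puff, record 1 carries the
#' configured device-on lead interval, and the configured artifact modes are
#' injected. With all artifact rates and jitter at zero the log's PD/IPI
#' equal the truth-derived topography exactly (plus the leading interval).
#'
#' @param truth A [puff_events()] list.
#' @param artifact A [cress_artifact_config()].
#' @return A [cress_log()].
#' @export
simulate_cress_log <- function(truth, artifact = cress_artifact_config()) {
  truth <- puff_events(truth)
  if (nrow(truth) == 0) return(cress_log())
  pd <- truth$end_ms - truth$start_ms
  ipi <- c(artifact$leading_ipi_ms,
           truth$start_ms[-1] - truth$end_ms[-nrow(truth)])

  with_seed_(artifact$seed, {
    split <- stats::runif(length(pd)) < artifact$split_probability
    min_main <- artifact$split_fragment_pd_ms + artifact$split_gap_ms + 1
    split <- split & pd > min_main
    rec_pd <- list(); rec_ipi <- list()
    for (i in seq_along(pd)) {
      if (split[i]) {
        rec_pd[[length(rec_pd) + 1]] <-
          c(pd[i] - artifact$split_gap_ms - artifact$split_fragment_pd_ms,
            artifact$split_fragment_pd_ms)
        rec_ipi[[length(rec_ipi) + 1]] <- c(ipi[i], artifact$split_gap_ms)
      } else {
        rec_pd[[length(rec_pd) + 1]] <- pd[i]
        rec_ipi[[length(rec_ipi) + 1]] <- ipi[i]
      }
    }
    out_pd <- unlist(rec_pd); out_ipi <- unlist(rec_ipi)
    if (artifact$jitter_sd_ms > 0) {
      out_pd <- pmax(1, out_pd + stats::rnorm(length(out_pd), 0, artifact$jitter_sd_ms))
      out_ipi <- pmax(0, out_ipi + stats::rnorm(length(out_ipi), 0, artifact$jitter_sd_ms))
    }
    # opaque flow-side fields, filled with plausible values
    vol <- stats::runif(length(out_pd), 35, 70)
    avg_flow <- stats::runif(length(out_pd), 25, 45)
    peak_flow <- avg_flow * stats::runif(length(out_pd), 1.3, 1.9)
    cress_log(tibble(
      puff_volume_ml = round(vol, 1),
      avg_flow = round(avg_flow, 1),
      peak_flow = round(peak_flow, 1),
      time_of_peak_flow_ms = round(0.4 * out_pd),
      pd_ms = round(out_pd),
      ipi_ms = round(out_ipi)))
  })
}

#' Simulate a cohort of laboratory sessions
#'
#' Draws per-participant topography parameters (median PD and IPI vary
#' log-normally across participants), simulates each session and its paired
#' device log, and assembles per-participant metadata including visual puff
#' counts taken from the truth. Recording failures can be emulated by
#' flagging participants as having incomplete device-side or watch-side data
#' (disjoint sets by default, mirroring exclusion accounting where each
#' failure has a single cause).
#'
#' @param n_participants Number of sessions (>= 1).
#' @param config Template [simulation_config()]; per-participant seeds are
#'   derived from `config$seed`.
#' @param artifact A [cress_artifact_config()] applied to every log.
#' @param n_incomplete_cress,n_incomplete_aspire Number of participants whose
#'   device-side / watch-side recording is flagged incomplete.
#' @param between_sigma Log-normal sigma of the across-participant spread of
#'   median PD and IPI (default 0.2).
#' @param vary_counts Draw each participant's puffs-per-hand from a Poisson
#'   around the template count (default `TRUE`), clamped to at least 3 and to
#'   what fits the smoking segment given that participant's drawn IPI median.
#' @return A list of class `smoketop_cohort`; each element has `meta` (one-row
#'   tibble), `trace`, `truth`, `cress`.
#' @export
simulate_cohort <- function(n_participants,
                            config = simulation_config(),
                            artifact = cress_artifact_config(),
                            n_incomplete_cress = 0,
                            n_incomplete_aspire = 0,
                            between_sigma = 0.2,
                            vary_counts = TRUE) {
  assert_scalar_number(n_participants, "n_participants", min = 1)
  if (n_incomplete_cress + n_incomplete_aspire > n_participants) {
    abort("more incomplete participants requested than participants.")
  }
  ids <- with_seed_(derive_seed(config$seed, 999),
                    sample.int(n_participants))
  cress_bad <- ids[seq_len(n_incomplete_cress)]
  aspire_bad <- ids[n_incomplete_cress + seq_len(n_incomplete_aspire)]

  purrr::map(seq_len(n_participants), function(p) {
    pseed <- derive_seed(config$seed, p)
    draws <- with_seed_(derive_seed(pseed, 1), list(
      scale = stats::rlnorm(2, 0, between_sigma),
      n = stats::rpois(1, config$n_puffs_per_hand)))
    cfg_p <- config
    cfg_p$seed <- pseed
    cfg_p$pd_distribution$median_ms <- config$pd_distribution$median_ms * draws$scale[1]
    cfg_p$ipi_distribution$median_ms <- config$ipi_distribution$median_ms * draws$scale[2]
    if (vary_counts && config$n_puffs_per_hand > 0) {
      # clamp the drawn count to what the smoking segment can hold given this
      # participant's IPI median, so the session stays feasible
      seg_ms <- min(config$schedule$duration_s[
        startsWith(config$schedule$activity, "smoking")]) * 1000
      avail <- seg_ms - 2 * (config$segment_margin_ms + config$transition_ms)
      n_p <- max(3L, draws$n)
      while (n_p > 3L &&
             n_p * cfg_p$pd_distribution$median_ms +
             (n_p - 1) * cfg_p$ipi_distribution$median_ms * 1.15 > avail) {
        n_p <- n_p - 1L
      }
      cfg_p$n_puffs_per_hand <- n_p
    }
    sess <- simulate_session(cfg_p)
    art_p <- artifact
    art_p$seed <- derive_seed(pseed, 2)
    log_p <- simulate_cress_log(sess$truth, art_p)
    meta <- tibble(
      participant_id = sprintf("P%02d", p),
      visual_puff_count_left = sum(sess$truth$hand == "left"),
      visual_puff_count_right = sum(sess$truth$hand == "right"),
      complete_aspire = !(p %in% aspire_bad),
      complete_cress = !(p %in% cress_bad))
    list(meta = meta, trace = sess$trace, truth = sess$truth,
         cress = log_p, schedule = sess$schedule, config = cfg_p)
  }) |>
    structure(class = "smoketop_cohort")
}

#' Per-participant metadata of a simulated cohort
#' @param cohort A `smoketop_cohort` from [simulate_cohort()].
#' @return A tibble, one row per participant.
#' @export
cohort_meta <- function(cohort) {
  bind_rows(purrr::map(cohort, "meta"))
}
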