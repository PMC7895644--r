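#' Configuration of a full pipeline run
#'
#' Bundles every stage's configuration: cohort simulation, device-log
#' artifact injection, gesture segmentation, log cleaning, and outlier
#' substitution. A single global seed derives per-stage seeds by stable
#' offsets, so any stage can be rerun in isolation and the whole run is
#' reproducible end to end.
#'
#' @param seed Global integer seed.
#' @param n_participants Cohort size (default 8).
#' @param n_incomplete_cress,n_incomplete_aspire Participants flagged as
#'   having incomplete device-side / watch-side recordings.
#' @param simulation A [simulation_config()].
#' @param artifacts A [cress_artifact_config()].
#' @param segmentation A [segmentation_params()].
#' @param cleaning A [cleaning_params()].
#' @param rule An [outlier_rule()].
#' @param tol Count-concordance tolerance (default 2).
#' @param output_dir Directory for run artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_participants = 8L,
                       n_incomplete_cress = 0L,
                       n_incomplete_aspire = 0L,
                       simulation = simulation_config(seed = derive_seed(seed, 1)),
                       artifacts = cress_artifact_config(seed = derive_seed(seed, 2)),
                       segmentation = segmentation_params(),
                       cleaning = cleaning_params(),
                       rule = outlier_rule(),
                       tol = 2,
                       output_dir = tempfile("smoketop-run-")) {
  assert_scalar_number(n_participants, "n_participants", min = 1)
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 n_incomplete_cress = as.integer(n_incomplete_cress),
                 n_incomplete_aspire = as.integer(n_incomplete_aspire),
                 simulation = simulation, artifacts = artifacts,
                 segmentation = segmentation, cleaning = cleaning,
                 rule = rule, tol = tol, output_dir = output_dir),
            class = "run_config")
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, checks every invariant, and either returns
#' the assembled [run_config()] or aborts with one message per violated
#' field, each naming the field's path (e.g. `simulation.noise_sd`).
#'
#' @param path Path to a YAML file. Recognized top-level keys: `seed`,
#'   `n_participants`, `n_incomplete_cress`, `n_incomplete_aspire`, `tol`,
#'   `output_dir`, and the blocks `simulation`, `artifacts`, `segmentation`,
#'   `cleaning`, `outlier_rule`; unknown keys are rejected.
#' @return A [run_config()].
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(sprintf("could not parse `%s`: %s", path, conditionMessage(e)))
  })
  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)

  known <- c("seed", "n_participants", "n_incomplete_cress",
             "n_incomplete_aspire", "tol", "output_dir", "simulation",
             "artifacts", "segmentation", "cleaning", "outlier_rule")
  for (k in setdiff(names(raw), known)) note(sprintf("unknown key `%s`", k))

  num <- function(block, field, min = -Inf, max = Inf, strict = FALSE) {
    path_name <- if (is.null(block)) field else paste(block, field, sep = ".")
    v <- if (is.null(block)) raw[[field]] else raw[[block]][[field]]
    if (is.null(v)) return(NULL)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      note(sprintf("`%s` must be a single finite number", path_name))
      return(NULL)
    }
    if ((strict && v <= min) || (!strict && v < min) || v > max) {
      note(sprintf("`%s` out of range (got %s)", path_name, v))
      return(NULL)
    }
    v
  }

  seed <- num(NULL, "seed") %||% 1L
  n_participants <- num(NULL, "n_participants", min = 1) %||% 8L
  n_inc_c <- num(NULL, "n_incomplete_cress", min = 0) %||% 0L
  n_inc_a <- num(NULL, "n_incomplete_aspire", min = 0) %||% 0L
  tol <- num(NULL, "tol", min = 0) %||% 2

  sim_args <- list(seed = derive_seed(seed, 1))
  s <- raw$simulation
  if (!is.null(s)) {
    v <- num("simulation", "noise_sd", min = 0); if (!is.null(v)) sim_args$noise_sd <- v
    v <- num("simulation", "n_puffs_per_hand", min = 0); if (!is.null(v)) sim_args$n_puffs_per_hand <- v
    v <- num("simulation", "transition_ms", min = 0, strict = TRUE); if (!is.null(v)) sim_args$transition_ms <- v
    v <- num("simulation", "sampling_rate", min = 0, strict = TRUE); if (!is.null(v)) sim_args$sampling_rate <- v
    if (!is.null(s$pd_distribution)) {
      m <- s$pd_distribution$median_ms; sg <- s$pd_distribution$sigma
      if (!is.null(m) && (!is.numeric(m) || m <= 0)) note("`simulation.pd_distribution.median_ms` must be > 0")
      if (!is.null(sg) && (!is.numeric(sg) || sg < 0)) note("`simulation.pd_distribution.sigma` must be >= 0")
      sim_args$pd_distribution <- utils::modifyList(
        list(median_ms = 1500, sigma = 0.3), s$pd_distribution)
    }
    if (!is.null(s$ipi_distribution)) {
      m <- s$ipi_distribution$median_ms; sg <- s$ipi_distribution$sigma
      if (!is.null(m) && (!is.numeric(m) || m <= 0)) note("`simulation.ipi_distribution.median_ms` must be > 0")
      if (!is.null(sg) && (!is.numeric(sg) || sg < 0)) note("`simulation.ipi_distribution.sigma` must be >= 0")
      sim_args$ipi_distribution <- utils::modifyList(
        list(median_ms = 20000, sigma = 0.4), s$ipi_distribution)
    }
    if (!is.null(s$watch_hand)) {
      if (!s$watch_hand %in% c("left", "right")) {
        note("`simulation.watch_hand` must be 'left' or 'right'")
      } else sim_args$watch_hand <- s$watch_hand
    }
    if (!is.null(s$rest_pose)) sim_args$rest_pose <- s$rest_pose
    if (!is.null(s$plateau_pose)) sim_args$plateau_pose <- s$plateau_pose
  }

  art_args <- list(seed = derive_seed(seed, 2))
  a <- raw$artifacts
  if (!is.null(a)) {
    v <- num("artifacts", "split_probability", min = 0, max = 1); if (!is.null(v)) art_args$split_probability <- v
    v <- num("artifacts", "leading_ipi_ms", min = 0); if (!is.null(v)) art_args$leading_ipi_ms <- v
    v <- num("artifacts", "split_fragment_pd_ms", min = 0, strict = TRUE); if (!is.null(v)) art_args$split_fragment_pd_ms <- v
    v <- num("artifacts", "split_gap_ms", min = 0, strict = TRUE); if (!is.null(v)) art_args$split_gap_ms <- v
    v <- num("artifacts", "jitter_sd_ms", min = 0); if (!is.null(v)) art_args$jitter_sd_ms <- v
  }

  seg_args <- list()
  g <- raw$segmentation
  if (!is.null(g)) {
    for (field in c("baseline_window_s", "plateau_tolerance", "min_plateau_ms",
                    "offset_return_tolerance", "min_return_ms",
                    "smoothing_window_samples")) {
      v <- num("segmentation", field, min = 0, strict = TRUE)
      if (!is.null(v)) seg_args[[field]] <- v
    }
    v <- num("segmentation", "onset_fraction", min = 0, max = 1, strict = TRUE)
    if (!is.null(v)) seg_args$onset_fraction <- v
  }

  cl_args <- list()
  cl <- raw$cleaning
  if (!is.null(cl)) {
    v <- num("cleaning", "min_plausible_pd_ms", min = 0, strict = TRUE); if (!is.null(v)) cl_args$min_plausible_pd_ms <- v
    v <- num("cleaning", "leading_ipi_threshold_ms", min = 0, strict = TRUE); if (!is.null(v)) cl_args$leading_ipi_threshold_ms <- v
    if (!is.null(cl$leading_ipi_rule)) cl_args$leading_ipi_rule <- cl$leading_ipi_rule
    if (!is.null(cl$merge_fragments)) cl_args$merge_fragments <- cl$merge_fragments
  }

  or_args <- list()
  o <- raw$outlier_rule
  if (!is.null(o)) {
    if (!is.null(o$method)) or_args$method <- o$method
    v <- num("outlier_rule", "mad_k", min = 0, strict = TRUE); if (!is.null(v)) or_args$mad_k <- v
    v <- num("outlier_rule", "min_ipi_ms", min = 0); if (!is.null(v)) or_args$min_ipi_ms <- v
    v <- num("outlier_rule", "max_ipi_ms", min = 0, strict = TRUE); if (!is.null(v)) or_args$max_ipi_ms <- v
    min_i <- or_args$min_ipi_ms %||% 1000
    max_i <- or_args$max_ipi_ms %||% 120000
    if (min_i >= max_i) note("`outlier_rule`: min_ipi_ms must be < max_ipi_ms")
  }
  if ((n_inc_c + n_inc_a) > n_participants) {
    note("`n_incomplete_cress` + `n_incomplete_aspire` exceeds `n_participants`")
  }

  if (length(errors)) {
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", errors, collapse = "\n")))
  }
  run_config(seed = seed, n_participants = n_participants,
             n_incomplete_cress = n_inc_c, n_incomplete_aspire = n_inc_a,
             simulation = do.call(simulation_config, sim_args),
             artifacts = do.call(cress_artifact_config, art_args),
             segmentation = do.call(segmentation_params, seg_args),
             cleaning = do.call(cleaning_params, cl_args),
             rule = do.call(outlier_rule, or_args),
             tol = tol,
             output_dir = raw$output_dir %||% tempfile("smoketop-run-"))
}

write_topography_json <- function(series, path) {
  jsonlite::write_json(list(pd_ms = series$pd_ms, ipi_ms = series$ipi_ms,
                            source = series$source),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Execute the full pipeline and write all artifacts
#'
#' Runs simulate -> detect -> topography -> clean/correct -> compare as one
#' reproducible run. Every intermediate is written in the package's tabular
#' formats under `config$output_dir`, and a manifest records the
#' configuration, per-stage record counts, and an MD5 checksum per artifact;
#' an identical configuration yields identical checksums.
#'
#' @param config A [run_config()] (or a YAML path, routed through
#'   [validate_config()]).
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return The manifest: a tibble with `participant_id`, `stage`, `artifact`,
#'   `path`, `n_records`, `md5`. The agreement summary is attached as
#'   attribute `summary`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))

  say("stage simulate: %d participants (seed %d)", config$n_participants,
      config$seed)
  cohort <- simulate_cohort(config$n_participants,
                            config = config$simulation,
                            artifact = config$artifacts,
                            n_incomplete_cress = config$n_incomplete_cress,
                            n_incomplete_aspire = config$n_incomplete_aspire)

  rows <- list()
  add <- function(pid, stage, artifact, path, n) {
    rows[[length(rows) + 1]] <<- tibble(
      participant_id = pid, stage = stage, artifact = artifact,
      path = basename(path), n_records = n,
      md5 = unname(tools::md5sum(path)))
  }

  for (s in cohort) {
    pid <- s$meta$participant_id
    stem <- file.path(out, pid)
    tryCatch({
      write_accel_trace(s$trace, paste0(stem, "_trace.csv"))
      add(pid, "simulate", "trace", paste0(stem, "_trace.csv"), nrow(s$trace))
      write_events(s$truth, paste0(stem, "_truth_events.csv"))
      add(pid, "simulate", "truth_events", paste0(stem, "_truth_events.csv"),
          nrow(s$truth))
      write_cress_log(s$cress, paste0(stem, "_cress_log.csv"))
      add(pid, "simulate", "cress_log", paste0(stem, "_cress_log.csv"),
          nrow(s$cress))

      detected <- detect_puffs(s$trace, params = config$segmentation)
      write_events(detected, paste0(stem, "_detected_events.csv"))
      add(pid, "detect", "detected_events",
          paste0(stem, "_detected_events.csv"), nrow(detected))

      watch_hand <- s$config$watch_hand %||% "left"
      seg <- s$schedule[s$schedule$activity == paste0("smoking_", watch_hand), ]
      watch <- events_to_topography(
        restrict_to_window(detected, seg$start_ms[1], seg$end_ms[1]),
        source = "aspire")
      write_topography_json(watch, paste0(stem, "_watch_topography.json"))
      add(pid, "topography", "watch_topography",
          paste0(stem, "_watch_topography.json"), length(watch$pd_ms))

      raw <- cress_to_topography(s$cress, drop_leading_ipi = TRUE)
      write_topography_json(raw, paste0(stem, "_cress_topography.json"))
      add(pid, "topography", "cress_topography",
          paste0(stem, "_cress_topography.json"), length(raw$pd_ms))

      corrected <- ccress_pipeline(s$cress, config$cleaning, config$rule)
      write_topography_json(corrected$series,
                            paste0(stem, "_corrected_topography.json"))
      add(pid, "correct", "corrected_topography",
          paste0(stem, "_corrected_topography.json"),
          length(corrected$series$pd_ms))
    }, error = function(e) {
      abort(sprintf("pipeline failed for %s: %s", pid, conditionMessage(e)))
    })
  }

  say("stage compare: pooling %d sessions", length(cohort))
  summary <- withCallingHandlers(
    run_comparison(cohort, segmentation = config$segmentation,
                   cleaning = config$cleaning, rule = config$rule,
                   tol = config$tol),
    message = function(m) if (quiet) invokeRestart("muffleMessage"))
  summary_path <- file.path(out, "summary.json")
  jsonlite::write_json(list(per_participant = summary$per_participant,
                            pooled = summary$pooled),
                       summary_path, auto_unbox = TRUE, digits = NA)
  add("", "compare", "summary", summary_path, nrow(summary$per_participant))

  manifest <- bind_rows(rows)
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("smoketop")),
         seed = config$seed,
         n_participants = config$n_participants,
         artifacts = manifest),
    manifest_path, auto_unbox = TRUE, digits = NA)
  say("wrote %d artifacts + manifest to %s", nrow(manifest), out)
  attr(manifest, "summary") <- summary
  manifest
}
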