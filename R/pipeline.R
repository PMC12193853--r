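#' Assemble the full run configuration
#'
#' Houses every fixed constant of the analysis in one place, defaulting to
#' the study's printed values: 5-minute glucose backfill, 15/15/30-minute
#' forward-fill limits, the <4 mmol/L for >=15 minutes label rule, the
#' 180-minute nocturnal cutoff, ten undersampling random states and L1 = L2
#' regularization of 10.
#'
#' @param simulate A [cohort_config()] describing the synthetic cohort, or
#'   `NULL` when reading from `input_dir`.
#' @param input_dir Directory of per-participant raw data (layout of
#'   [write_cohort()]); ignored when `simulate` is given.
#' @param fill_limits Named imputation limits in minutes.
#' @param glucose_threshold Labeling threshold, mmol/L (strict `<`).
#' @param min_event_minutes Minimum qualifying event duration.
#' @param nocturnal_cutoff Truncation cutoff for prolonged night events,
#'   minutes.
#' @param seeds Undersampling random states.
#' @param alpha,lambda Tree-ensemble L1/L2 regularization.
#' @param night_sd_hours,min_night_hours Sleep-consistency screen (see
#'   [night_schedule_consistent()]).
#' @param out_dir Optional directory for result tables and the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = cohort_config(),
                       input_dir = NULL,
                       fill_limits = c(glucose = 5, hrv = 15, rr = 15,
                                       bos = 30),
                       glucose_threshold = 4,
                       min_event_minutes = 15,
                       nocturnal_cutoff = 180,
                       seeds = 1:10,
                       alpha = 10,
                       lambda = 10,
                       night_sd_hours = 3,
                       min_night_hours = 3,
                       out_dir = NULL) {
  structure(list(simulate = simulate, input_dir = input_dir,
                 fill_limits = fill_limits,
                 glucose_threshold = glucose_threshold,
                 min_event_minutes = min_event_minutes,
                 nocturnal_cutoff = nocturnal_cutoff,
                 seeds = seeds, alpha = alpha, lambda = lambda,
                 night_sd_hours = night_sd_hours,
                 min_night_hours = min_night_hours,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full per-participant preprocessing chain
#'
#' Raw streams to modeling-ready artifacts: minute-grid alignment, bounded
#' imputation, outcome labeling, diurnal segmentation, event-to-segment
#' assignment, nocturnal truncation and causal feature engineering.
#'
#' @param streams Long stream tibble for one participant.
#' @param diary The participant's diary.
#' @param participant_id Identifier.
#' @param config A [run_config()].
#' @return List: `timeline` (featured, labeled, segmented), `segments`
#'   (with `contains_event`), `events`, `eligibility`, `include_meal`.
#' @export
prepare_participant <- function(streams, diary, participant_id,
                                config = run_config()) {
  tl <- align_to_minute_grid(streams) |>
    impute_timeline(limits = config$fill_limits) |>
    label_hypoglycemia(threshold = config$glucose_threshold,
                       min_duration = config$min_event_minutes)
  segments <- assign_segments(diary, participant_id)
  tl <- segment_timeline(tl, segments)
  events <- hypo_events(tl, config$glucose_threshold,
                        config$min_event_minutes) |>
    assign_events_to_segments(segments)
  trunc <- truncate_prolonged_nocturnal(tl, events,
                                        cutoff = config$nocturnal_cutoff)
  tl <- trunc$timeline
  events <- trunc$events
  segments <- mark_event_segments(segments, events)
  include_meal <- sum(diary$entry_type == "meal") > 0
  tl <- compute_features(tl, diary, include_meal = include_meal)
  list(timeline = tl, segments = segments, events = events,
       eligibility = qualify_participant_segments(events, segments),
       include_meal = include_meal)
}

#' Execute the end-to-end pipeline
#'
#' Simulate (or ingest) the cohort, preprocess every participant, build one
#' personalized model per modelable (participant, day/night) pair via the
#' leave-hypo-segment-out protocol, and aggregate discrimination, event
#' detection and feature-category importance into a cohort report.
#' Participants whose night schedule fails the consistency screen skip night
#' modeling; participants without any qualifying event are excluded.
#'
#' @param config A [run_config()].
#' @return A `hypowatch_report`; see [tidy.hypowatch_report()],
#'   [glance.hypowatch_report()] and [autoplot.hypowatch_report()].
#' @examples
#' \donttest{
#' cfg <- run_config(simulate = cohort_config(n_participants = 1,
#'                                            days_per_participant = 4,
#'                                            day_event_rate = 1, seed = 2),
#'                   seeds = 1:2)
#' rep <- run_pipeline(cfg)
#' glance(rep)
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
  } else {
    if (is.null(config$input_dir)) stop("neither simulate nor input_dir set")
    pdirs <- list.dirs(config$input_dir, recursive = FALSE)
    cohort <- purrr::map_dfr(pdirs, function(p) {
      raw <- read_participant_dir(p)
      tibble::tibble(participant_id = basename(p),
                     streams = list(raw$streams), diary = list(raw$diary),
                     events = list(NULL))
    })
  }
  fits <- list()
  prepared <- list()
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$participant_id[i]
    prep <- prepare_participant(cohort$streams[[i]], cohort$diary[[i]], pid,
                                config)
    prepared[[pid]] <- prep
    for (kd in c("day", "night")) {
      elig <- prep$eligibility
      if (!elig$modelable[elig$kind == kd]) next
      if (kd == "night" &&
          !night_schedule_consistent(prep$segments,
                                     config$night_sd_hours,
                                     config$min_night_hours)) next
      segs <- prep$segments[prep$segments$kind == kd, ]
      if (nrow(segs) < 2) next
      fm <- build_feature_matrix(prep$timeline, prep$segments, kd,
                                 include_meal = prep$include_meal)
      evs <- prep$events[!is.na(prep$events$kind) & prep$events$kind == kd, ]
      fit <- fit_personalized(
        fm, segs, evs, seeds = config$seeds, participant_id = pid, kind = kd,
        alpha = config$alpha, lambda = config$lambda)
      if (any(fit$iterations$valid)) fits[[length(fits) + 1L]] <- fit
    }
  }
  if (!length(fits)) {
    warning("no modelable participants: no qualifying hypoglycemic events")
  }
  models <- purrr::map_dfr(fits, summarise_personalized)
  report <- structure(list(
    models = models,
    fits = fits,
    importance = list(day = cohort_importance(fits, "day"),
                      night = cohort_importance(fits, "night")),
    prepared = prepared,
    config = config
  ), class = "hypowatch_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a cohort report's tables and manifest to disk
#'
#' @param report A `hypowatch_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$models, file.path(dir, "models.csv"),
                   row.names = FALSE)
  for (kd in c("day", "night")) {
    imp <- report$importance[[kd]]
    if (nrow(imp))
      utils::write.csv(imp, file.path(dir, paste0("importance_", kd, ".csv")),
                       row.names = FALSE)
  }
  cfg <- report$config
  manifest <- list(
    seeds = cfg$seeds, alpha = cfg$alpha, lambda = cfg$lambda,
    fill_limits = as.list(cfg$fill_limits),
    glucose_threshold = cfg$glucose_threshold,
    min_event_minutes = cfg$min_event_minutes,
    nocturnal_cutoff = cfg$nocturnal_cutoff,
    simulate = if (!is.null(cfg$simulate)) unclass(cfg$simulate),
    r_version = as.character(getRversion()),
    xgboost_version = as.character(utils::packageVersion("xgboost")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
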