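#' @importFrom rlang .data
#' @importFrom stats rnorm rpois runif rbinom sd setNames
NULL

sim_origin <- function() as.POSIXct("2024-03-01 00:00:00", tz = "UTC")

minute_time <- function(origin, minute) origin + 60 * round(minute)

# Jittered wake/sleep schedule in minutes from the origin. Day d spans
# wake[d] -> sleep[d]; night d spans sleep[d] -> wake[d + 1]; a closing wake
# entry on day D+1 terminates the last night.
sim_schedule <- function(config, pseed) {
  d <- config$days_per_participant
  set.seed(participant_seed(pseed, 1))
  jit <- function(n) round(rnorm(n, 0, config$sleep_jitter_sd))
  wake <- (seq_len(d + 1) - 1) * 1440 + config$wake_hour * 60 + jit(d + 1)
  sleep <- (seq_len(d) - 1) * 1440 + config$sleep_onset_hour * 60 + jit(d)
  list(wake = wake, sleep = sleep,
       total_minutes = wake[d + 1], n_days = d)
}

#' Generate a participant diary
#'
#' Produces the manually documented entries the pipeline consumes: mealtimes,
#' short-acting insulin doses (each meal followed by a dose with probability
#' `insulin_prob_per_meal`), and nightly sleep-onset/wake pairs with
#' configurable jitter. A closing wake entry on the morning after the last
#' study day terminates the final night.
#'
#' @param config A [cohort_config()].
#' @param pseed Integer participant seed (see [participant_seed()]).
#' @return A tibble with columns `timestamp` (POSIXct, minute resolution) and
#'   `entry_type` (one of `meal`, `insulin`, `sleep_onset`, `wake`).
#' @export
generate_diary <- function(config, pseed) {
  origin <- sim_origin()
  sch <- sim_schedule(config, pseed)
  set.seed(participant_seed(pseed, 2))
  entries <- list()
  for (d in seq_len(sch$n_days)) {
    wake_m <- sch$wake[d]
    sleep_m <- sch$sleep[d]
    entries[[length(entries) + 1L]] <-
      tibble::tibble(minute = wake_m, entry_type = "wake")
    # meals spread through the waking span, jittered
    k <- config$meal_count_per_day
    if (k > 0) {
      slots <- wake_m + 60 + (seq_len(k) - 0.5) / k * (sleep_m - wake_m - 180)
      meals <- sort(round(slots + rnorm(k, 0, 40)))
      meals <- pmin(pmax(meals, wake_m + 15), sleep_m - 30)
      entries[[length(entries) + 1L]] <-
        tibble::tibble(minute = meals, entry_type = "meal")
      dosed <- runif(k) < config$insulin_prob_per_meal
      if (any(dosed)) {
        doses <- meals[dosed] + round(runif(sum(dosed), 5, 20))
        entries[[length(entries) + 1L]] <-
          tibble::tibble(minute = doses, entry_type = "insulin")
      }
    }
    entries[[length(entries) + 1L]] <-
      tibble::tibble(minute = sleep_m, entry_type = "sleep_onset")
  }
  entries[[length(entries) + 1L]] <-
    tibble::tibble(minute = sch$wake[sch$n_days + 1], entry_type = "wake")
  dplyr::bind_rows(entries) |>
    dplyr::arrange(.data$minute) |>
    dplyr::transmute(timestamp = minute_time(origin, .data$minute),
                     entry_type = .data$entry_type)
}

# Diurnal windows (minutes from origin) implied by a diary's sleep entries.
diary_windows <- function(config, pseed) {
  sch <- sim_schedule(config, pseed)
  d <- sch$n_days
  list(day = cbind(start = sch$wake[seq_len(d)], end = sch$sleep),
       night = cbind(start = sch$sleep, end = sch$wake[seq_len(d) + 1]))
}

# Draw non-overlapping intervals (start on the CGM grid) inside [lo, hi),
# keeping >= gap minutes clear of previously placed intervals.
place_intervals <- function(n, lo, hi, dur_range, existing, gap = 15,
                            grid = 5) {
  placed <- existing
  out <- NULL
  for (i in seq_len(n)) {
    for (try in 1:40) {
      dur <- grid * round(runif(1, dur_range[1], dur_range[2]) / grid)
      dur <- max(dur, grid * ceiling(dur_range[1] / grid))
      if (hi - lo < dur) break
      s <- grid * round(runif(1, lo, hi - dur) / grid)
      s <- min(max(s, lo), hi - dur)
      e <- s + dur
      clear <- is.null(placed) || nrow(placed) == 0 ||
        all(e + gap <= placed[, 1] | s - gap >= placed[, 2])
      if (clear) {
        placed <- rbind(placed, c(s, e))
        out <- rbind(out, c(s, e))
        break
      }
    }
  }
  list(new = out, all = placed)
}

#' Generate a synthetic continuous-glucose trace with injected events
#'
#' Simulates a mean-reverting interstitial glucose process sampled every
#' 5 minutes around a euglycemic baseline (default 7.0 mmol/L). Ground-truth
#' hypoglycemic events are drawn per diurnal segment (Poisson with the
#' configured day/night rates), aligned to the 5-minute sampling grid, and the
#' trace is forced below 4.0 mmol/L for their full duration. Outside events
#' the trace is kept at or above 4.5 mmol/L, except for occasional transient
#' (sub-15-minute) dips that exercise the minimum-duration rule downstream.
#'
#' @inheritParams generate_diary
#' @param diary Diary tibble from [generate_diary()] (supplies the sleep
#'   schedule that defines day and night segments for event placement).
#' @return A list with `stream` (tibble `timestamp`, `value`) and `events`
#'   (tibble `start`, `end`, `duration_min`, `kind`), where an event spans
#'   minutes `[start, end)`.
#' @export
generate_glucose_trace <- function(config, diary, pseed) {
  origin <- sim_origin()
  win <- diary_windows(config, pseed)
  total <- sim_schedule(config, pseed)$total_minutes
  set.seed(participant_seed(pseed, 3))

  place_in <- function(windows, rate, kind, placed) {
    evs <- NULL
    for (r in seq_len(nrow(windows))) {
      n <- rpois(1, rate)
      if (n == 0) next
      res <- place_intervals(n, windows[r, "start"] + 10,
                             windows[r, "end"] - 10,
                             config$event_duration_range, placed)
      placed <- res$all
      if (!is.null(res$new))
        evs <- rbind(evs, cbind(res$new, r))
    }
    list(events = evs, placed = placed)
  }
  dres <- place_in(win$day, config$day_event_rate, "day", NULL)
  nres <- place_in(win$night, config$night_event_rate, "night", dres$placed)
  col <- function(x, j) if (is.null(x)) numeric(0) else x[, j]
  events <- tibble::tibble(
    start = c(col(dres$events, 1), col(nres$events, 1)),
    end = c(col(dres$events, 2), col(nres$events, 2)),
    kind = rep(c("day", "night"),
               c(NROW(dres$events), NROW(nres$events)))
  ) |>
    dplyr::arrange(.data$start) |>
    dplyr::mutate(duration_min = .data$end - .data$start)

  # short dips (< 15 min) that must not qualify as events
  dips <- NULL
  placed <- nres$placed
  all_win <- rbind(win$day, win$night)
  for (r in seq_len(nrow(all_win))) {
    n <- rpois(1, config$transient_dip_rate)
    if (n == 0) next
    res <- place_intervals(n, all_win[r, "start"] + 10, all_win[r, "end"] - 10,
                           c(5, 10), placed, gap = 20)
    placed <- res$all
    dips <- rbind(dips, res$new)
  }

  grid <- seq(0, total, by = 5)
  k <- 0.1
  g <- numeric(length(grid))
  g[1] <- config$glucose_baseline
  noise <- rnorm(length(grid), 0, config$noise_sd[["glucose"]])
  for (i in seq_along(grid)[-1])
    g[i] <- g[i - 1] + k * (config$glucose_baseline - g[i - 1]) + noise[i]
  g <- pmax(g, 4.5)

  dip_shape <- function(idx, nadir) {
    frac <- (seq_along(idx) - 0.5) / length(idx)
    pmin(3.95, pmax(2.5, nadir + (3.9 - nadir) * abs(2 * frac - 1) +
                      rnorm(length(idx), 0, 0.08)))
  }
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      idx <- which(grid >= events$start[i] & grid < events$end[i])
      g[idx] <- dip_shape(idx, 3.1)
    }
  }
  for (j in seq_len(NROW(dips))) {
    idx <- which(grid >= dips[j, 1] & grid < dips[j, 2])
    g[idx] <- dip_shape(idx, 3.6)
  }

  list(
    stream = tibble::tibble(timestamp = minute_time(origin, grid),
                            value = round(g, 2)),
    events = dplyr::transmute(events,
                              start = minute_time(origin, .data$start),
                              end = minute_time(origin, .data$end),
                              duration_min = .data$duration_min,
                              kind = .data$kind)
  )
}

#' Generate smartwatch sensor streams
#'
#' Emits the six wearable channels at their nominal cadences: heart rate,
#' step count and active energy every minute; HRV every 15 minutes during
#' sleep and on a Bernoulli-thinned 15-minute grid while awake (emulating
#' measurement in restful states only); respiratory rate every 15 minutes and
#' blood oxygen saturation every 30 minutes, during sleep only. Waking
#' activity follows a two-state (rest/active) Markov chain driving zero-
#' inflated step and energy bursts, with heart rate coupled to activity.
#' During ground-truth event minutes (optionally lagged by `effect_lag`) the
#' configured physiological effects are added to HR, HRV, RR and BOS.
#'
#' @inheritParams generate_glucose_trace
#' @param events Ground-truth event tibble from [generate_glucose_trace()].
#' @return Named list of stream tibbles (`timestamp`, `value`) for channels
#'   `hr`, `hrv`, `bos`, `rr`, `steps`, `energy`.
#' @export
generate_wearable_streams <- function(config, diary, events, pseed) {
  origin <- sim_origin()
  win <- diary_windows(config, pseed)
  total <- sim_schedule(config, pseed)$total_minutes
  set.seed(participant_seed(pseed, 4))

  mins <- seq(0, total - 1)
  in_windows <- function(m, w) {
    out <- logical(length(m))
    for (r in seq_len(nrow(w)))
      out <- out | (m >= w[r, "start"] & m < w[r, "end"])
    out
  }
  asleep <- in_windows(mins, win$night)
  ev_min <- integer(0)
  if (nrow(events)) {
    s <- as.numeric(difftime(events$start, origin, units = "mins"))
    e <- as.numeric(difftime(events$end, origin, units = "mins"))
    ev_min <- unlist(Map(function(a, b) seq(a, b - 1), s, e))
  }
  in_event <- mins %in% (ev_min + config$effect_lag)

  # two-state activity chain over waking minutes
  active <- logical(length(mins))
  state <- FALSE
  for (i in seq_along(mins)) {
    if (asleep[i]) {
      state <- FALSE
    } else {
      state <- if (state) runif(1) >= 0.25 else runif(1) < 0.08
    }
    active[i] <- state
  }
  steps <- integer(length(mins))
  steps[active] <- rpois(sum(active), 90)
  drift <- !asleep & !active & runif(length(mins)) < 0.1
  steps[drift] <- rpois(sum(drift), 12)
  energy <- round(steps * 0.06 + ifelse(asleep, 0, abs(rnorm(length(mins), 0.3, 0.2))), 2)
  energy[asleep] <- 0

  hr <- config$hr_baseline - 8 * asleep + 0.1 * steps +
    config$hr_effect * in_event + rnorm(length(mins), 0, config$noise_sd[["hr"]])
  hr <- round(pmax(hr, 35))

  grid_in <- function(w, by) {
    unlist(lapply(seq_len(nrow(w)), function(r)
      seq(w[r, "start"], w[r, "end"] - 1, by = by)))
  }
  hrv_night <- grid_in(win$night, 15)
  hrv_day <- grid_in(win$day, 15)
  hrv_day <- hrv_day[runif(length(hrv_day)) < config$hrv_day_keep_prob]
  hrv_min <- sort(c(hrv_night, hrv_day))
  hrv_val <- config$hrv_baseline + 8 * (hrv_min %in% mins[asleep]) +
    config$hrv_effect * (hrv_min %in% mins[in_event]) +
    rnorm(length(hrv_min), 0, config$noise_sd[["hrv"]])
  hrv_val <- round(pmax(hrv_val, 5), 1)

  rr_min <- grid_in(win$night, 15)
  rr_val <- round(pmax(config$rr_baseline +
                         config$rr_effect * (rr_min %in% mins[in_event]) +
                         rnorm(length(rr_min), 0, config$noise_sd[["rr"]]), 6), 1)
  bos_min <- grid_in(win$night, 30)
  bos_val <- round(pmin(100, config$bos_baseline +
                          config$bos_effect * (bos_min %in% mins[in_event]) +
                          rnorm(length(bos_min), 0, config$noise_sd[["bos"]])), 1)

  stream <- function(m, v) tibble::tibble(timestamp = minute_time(origin, m),
                                          value = as.numeric(v))
  list(hr = stream(mins, hr),
       hrv = stream(hrv_min, hrv_val),
       bos = stream(bos_min, bos_val),
       rr = stream(rr_min, rr_val),
       steps = stream(mins, steps),
       energy = stream(mins, energy))
}

#' Simulate a synthetic wearable cohort
#'
#' Runs the diary, glucose and wearable generators for every participant,
#' deriving one reproducible seed per participant from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A nested tibble with one row per participant: `participant_id`,
#'   `streams` (list column of long tibbles `channel`, `timestamp`, `value`),
#'   `diary` (list of diary tibbles) and `events` (list of ground-truth event
#'   tibbles).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 1,
#'                                         days_per_participant = 2, seed = 3))
#' cohort$events[[1]]
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  rows <- purrr::map(seq_len(config$n_participants), function(i) {
    pseed <- participant_seed(config$seed, i)
    diary <- generate_diary(config, pseed)
    glu <- generate_glucose_trace(config, diary, pseed)
    wear <- generate_wearable_streams(config, diary, glu$events, pseed)
    streams <- dplyr::bind_rows(
      c(list(glucose = glu$stream), wear), .id = "channel")
    tibble::tibble(
      participant_id = sprintf("P%02d", i),
      streams = list(streams),
      diary = list(diary),
      events = list(glu$events)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a simulated cohort to plain-text files
#'
#' One CSV per channel per participant (`timestamp`, `value`), a diary CSV
#' (`timestamp`, `entry_type`) and a ground-truth JSON of event intervals,
#' under one directory per participant.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of participant directories written.
#' @export
write_cohort <- function(cohort, dir) {
  dirs <- purrr::pmap_chr(cohort, function(participant_id, streams, diary,
                                           events) {
    pdir <- file.path(dir, participant_id)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    for (ch in unique(streams$channel)) {
      s <- streams[streams$channel == ch, c("timestamp", "value")]
      utils::write.csv(
        data.frame(timestamp = fmt(s$timestamp), value = s$value),
        file.path(pdir, paste0(ch, ".csv")), row.names = FALSE)
    }
    utils::write.csv(
      data.frame(timestamp = fmt(diary$timestamp),
                 entry_type = diary$entry_type),
      file.path(pdir, "diary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(events = data.frame(start = fmt(events$start), end = fmt(events$end),
                               duration_min = events$duration_min,
                               kind = events$kind)),
      file.path(pdir, "ground_truth.json"), auto_unbox = TRUE)
    pdir
  })
  invisible(dirs)
}

#' Read one participant's raw streams and diary back from disk
#'
#' Accepts the layout written by [write_cohort()] (the same schema works for
#' real device exports saved per channel).
#'
#' @param pdir Participant directory containing `<channel>.csv` files and
#'   `diary.csv`.
#' @return List with `streams` (long tibble) and `diary`.
#' @export
read_participant_dir <- function(pdir) {
  files <- list.files(pdir, pattern = "\\.csv$", full.names = TRUE)
  chans <- setdiff(sub("\\.csv$", "", basename(files)), "diary")
  parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S",
                                     tz = "UTC")
  streams <- purrr::map(chans, function(ch) {
    d <- utils::read.csv(file.path(pdir, paste0(ch, ".csv")))
    tibble::tibble(channel = ch, timestamp = parse_ts(d$timestamp),
                   value = as.numeric(d$value))
  }) |> dplyr::bind_rows()
  d <- utils::read.csv(file.path(pdir, "diary.csv"))
  list(streams = streams,
       diary = tibble::tibble(timestamp = parse_ts(d$timestamp),
                              entry_type = d$entry_type))
}
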