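#' Cut a participant's record into day and night segments
#'
#' Uses the diary's sleep entries as the authoritative sleep/wake record: a
#' day segment spans wake to the following sleep onset, a night segment spans
#' sleep onset to the following wake. Segment identifiers encode participant,
#' calendar date of segment start, and kind. Anything before the first wake
#' entry (a partial first day) or after the last wake entry (a partial last
#' night) is dropped. A wake entry followed directly by another wake (a night
#' with no logged sleep onset) drops the span between them with a warning;
#' two consecutive sleep-onset entries are an error naming the date, since
#' the day/night structure is then ambiguous.
#'
#' @param diary Diary tibble (`timestamp`, `entry_type`).
#' @param participant_id Identifier used in segment ids.
#' @return Segment tibble: `segment_id`, `participant_id`, `kind`
#'   (`"day"`/`"night"`), `start`, `end` (POSIXct, half-open).
#' @export
assign_segments <- function(diary, participant_id = "P01") {
  sl <- diary |>
    dplyr::filter(.data$entry_type %in% c("wake", "sleep_onset")) |>
    dplyr::arrange(.data$timestamp)
  first_wake <- match("wake", sl$entry_type)
  if (is.na(first_wake)) stop("diary contains no wake entries")
  sl <- sl[first_wake:nrow(sl), ]
  segs <- list()
  i <- 1L
  while (i < nrow(sl)) {
    a <- sl$entry_type[i]
    b <- sl$entry_type[i + 1L]
    if (a == "sleep_onset" && b == "sleep_onset") {
      stop("non-alternating sleep entries: consecutive sleep_onset on ",
           format(sl$timestamp[i], "%Y-%m-%d"))
    }
    if (a == "wake" && b == "wake") {
      warning("missing sleep_onset between ",
              format(sl$timestamp[i], "%Y-%m-%d %H:%M"), " and ",
              format(sl$timestamp[i + 1L], "%Y-%m-%d %H:%M"),
              "; dropping that day/night span")
      i <- i + 1L
      next
    }
    kind <- if (a == "wake") "day" else "night"
    segs[[length(segs) + 1L]] <- tibble::tibble(
      kind = kind, start = sl$timestamp[i], end = sl$timestamp[i + 1L])
    i <- i + 1L
  }
  if (!length(segs)) stop("diary yields no complete day or night segments")
  dplyr::bind_rows(segs) |>
    dplyr::mutate(
      participant_id = participant_id,
      segment_id = sprintf("%s_%s_%s", participant_id,
                           format(.data$start, "%Y%m%d"), .data$kind),
      .before = 1L) |>
    dplyr::relocate("segment_id", "participant_id", "kind", "start", "end")
}

#' Attach segment membership to a timeline
#'
#' Adds a `segment_id` column; minutes outside every segment (the trimmed
#' partial first day / last night) get `NA` and take no part in modeling.
#'
#' @param timeline Timeline tibble.
#' @param segments Segment tibble from [assign_segments()].
#' @return The timeline with `segment_id`.
#' @export
segment_timeline <- function(timeline, segments) {
  id <- rep(NA_character_, nrow(timeline))
  for (i in seq_len(nrow(segments))) {
    sel <- timeline$time >= segments$start[i] & timeline$time < segments$end[i]
    id[sel] <- segments$segment_id[i]
  }
  timeline$segment_id <- id
  timeline
}

#' Flag segments containing at least one qualifying event
#'
#' `contains_event` is `TRUE` iff one or more qualifying event onsets lie in
#' the segment; multiple events still count once — the flag drives the
#' leave-hypo-segment-out split, which holds out whole segments.
#'
#' @param segments Segment tibble.
#' @param events Events with `segment_id` (see
#'   [assign_events_to_segments()]).
#' @return `segments` with a logical `contains_event` column.
#' @export
mark_event_segments <- function(segments, events) {
  segments$contains_event <-
    segments$segment_id %in% events$segment_id[!is.na(events$segment_id)]
  segments
}

#' Heuristic screen for inconsistent sleep schedules
#'
#' Night models are unreliable for participants with erratic sleep (shift
#' work, sleep restriction): time-of-day features then carry no stable
#' nocturnal signature. Night modeling is allowed only when the SD of
#' sleep-onset hour stays below `sd_threshold_hours` and every night lasts at
#' least `min_night_hours`.
#'
#' @param segments Segment tibble.
#' @param sd_threshold_hours Maximum tolerated SD of sleep-onset hour.
#' @param min_night_hours Minimum tolerated night duration, hours.
#' @return `TRUE` if night modeling is allowed.
#' @export
night_schedule_consistent <- function(segments, sd_threshold_hours = 3,
                                      min_night_hours = 3) {
  nights <- segments[segments$kind == "night", ]
  if (nrow(nights) == 0) return(FALSE)
  onset_hour <- as.numeric(format(nights$start, "%H")) +
    as.numeric(format(nights$start, "%M")) / 60
  # unwrap around midnight so 23:30 and 00:30 are one hour apart
  onset_hour <- ifelse(onset_hour < 12, onset_hour + 24, onset_hour)
  dur_h <- as.numeric(difftime(nights$end, nights$start, units = "hours"))
  (nrow(nights) == 1 || stats::sd(onset_hour) <= sd_threshold_hours) &&
    all(dur_h >= min_night_hours)
}
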