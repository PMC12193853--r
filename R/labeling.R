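#' Label hypoglycemic minutes on an imputed timeline
#'
#' Applies the study outcome rule: a minute is positive when it belongs to a
#' maximal run of consecutive minutes with glucose strictly below `threshold`
#' (4.0 mmol/L) lasting at least `min_duration` minutes (15). Minutes with
#' missing glucose break runs and are labeled 0, so events are never
#' fabricated across sensor gaps.
#'
#' @param timeline Timeline tibble with an (imputed) `glucose` column.
#' @param threshold Glucose threshold, mmol/L (strict `<`).
#' @param min_duration Minimum qualifying run length, minutes.
#' @return The timeline with an integer `hypo` column (0/1).
#' @seealso [hypo_events()] for the event list implied by the same rule.
#' @export
label_hypoglycemia <- function(timeline, threshold = 4, min_duration = 15) {
  if (!"glucose" %in% names(timeline))
    stop("timeline has no glucose column; cannot label hypoglycemia")
  below <- !is.na(timeline$glucose) & timeline$glucose < threshold
  r <- rle(below)
  keep <- r$values & r$lengths >= min_duration
  timeline$hypo <- as.integer(inverse.rle(list(values = keep,
                                               lengths = r$lengths)))
  timeline
}

#' Extract qualifying hypoglycemic events from a timeline
#'
#' Returns one row per maximal qualifying run under the same rule as
#' [label_hypoglycemia()]. `start` is the first positive minute and `end` the
#' minute after the last (half-open interval), so `duration_min` equals the
#' number of labeled minutes.
#'
#' @inheritParams label_hypoglycemia
#' @return Tibble with `event_id`, `start`, `end` (POSIXct) and
#'   `duration_min`, plus a `truncated` flag (all `FALSE` here; see
#'   [truncate_prolonged_nocturnal()]).
#' @export
hypo_events <- function(timeline, threshold = 4, min_duration = 15) {
  tl <- label_hypoglycemia(timeline, threshold, min_duration)
  r <- rle(tl$hypo == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values)
  tibble::tibble(
    event_id = seq_along(qual),
    start = tl$time[starts[qual]],
    end = tl$time[ends[qual]] + 60,
    duration_min = r$lengths[qual],
    truncated = FALSE
  )
}

#' Assign events to diurnal segments by onset
#'
#' An event belongs to the segment containing its first minute, so an episode
#' straddling a wake or sleep boundary is attributed to where it began.
#' Events starting outside every segment (e.g., in trimmed partial days) get
#' `NA` and are dropped from modeling.
#'
#' @param events Event tibble from [hypo_events()].
#' @param segments Segment tibble from [assign_segments()].
#' @return `events` with `segment_id` and `kind` columns.
#' @export
assign_events_to_segments <- function(events, segments) {
  idx <- purrr::map_int(seq_len(nrow(events)), function(i) {
    j <- which(segments$start <= events$start[i] &
                 events$start[i] < segments$end)
    if (length(j) == 1L) j else NA_integer_
  })
  events$segment_id <- segments$segment_id[idx]
  events$kind <- segments$kind[idx]
  events
}

#' Truncate prolonged nocturnal events at a cutoff
#'
#' Nocturnal events longer than `cutoff` minutes keep their first `cutoff`
#' labeled minutes; positive labels beyond that are reset to 0 and the event
#' is marked `truncated`. Daytime events are untouched — the rule exists
#' because very long overnight episodes would otherwise dominate a night
#' segment's positive class.
#'
#' @param timeline Labeled timeline (with `hypo`).
#' @param events Events with segment assignment (see
#'   [assign_events_to_segments()]).
#' @param cutoff Maximum labeled nocturnal event length, minutes.
#' @return List with the adjusted `timeline` and `events`.
#' @export
truncate_prolonged_nocturnal <- function(timeline, events, cutoff = 180) {
  long_night <- which(!is.na(events$kind) & events$kind == "night" &
                        events$duration_min > cutoff)
  for (i in long_night) {
    cut_time <- events$start[i] + 60 * cutoff
    drop <- timeline$time >= cut_time & timeline$time < events$end[i]
    timeline$hypo[drop] <- 0L
    events$end[i] <- cut_time
    events$duration_min[i] <- cutoff
    events$truncated[i] <- TRUE
  }
  list(timeline = timeline, events = events)
}

#' Decide which participant-by-diurnal-kind models are buildable
#'
#' A (participant, day|night) pair is modelable iff at least one qualifying
#' event falls in that kind's segments; participants with no qualifying event
#' anywhere are excluded entirely, mirroring how participants with no or very
#' short episodes cannot contribute a personalized model.
#'
#' @param events Events with `kind` (see [assign_events_to_segments()]).
#' @param segments Segment tibble for the same participant.
#' @return Tibble with `kind`, `n_events`, `modelable`.
#' @export
qualify_participant_segments <- function(events, segments) {
  counts <- events |>
    dplyr::filter(!is.na(.data$kind)) |>
    dplyr::count(.data$kind, name = "n_events")
  tibble::tibble(kind = c("day", "night")) |>
    dplyr::left_join(counts, by = "kind") |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L),
                  modelable = .data$n_events > 0L &
                    .data$kind %in% segments$kind)
}
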