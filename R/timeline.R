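CHANNELS <- c("glucose", "hr", "hrv", "bos", "rr", "steps", "energy")
FILL_LIMITS <- c(glucose = 5, hrv = 15, rr = 15, bos = 30)

#' Align raw sensor streams onto a one-minute grid
#'
#' Merges all of a participant's channels into a single minute-resolution
#' table spanning the earliest to the latest observation. Each observation is
#' assigned to its containing minute; multiple observations falling in the
#' same minute are reduced by their mean. Every channel gets a companion
#' `<channel>_flag` column recording imputation provenance, initialised to
#' `"observed"` or `"missing"`.
#'
#' @param streams Long tibble with columns `channel`, `timestamp`, `value`
#'   (as produced by [simulate_cohort()]), or a named list of per-channel
#'   tibbles (`timestamp`, `value`).
#' @return A timeline tibble: `time` (POSIXct, one row per minute), one value
#'   column and one flag column per channel.
#' @examples
#' s <- tibble::tibble(channel = "hr",
#'                     timestamp = as.POSIXct("2024-01-01", tz = "UTC") +
#'                       60 * 0:9,
#'                     value = 70 + 0:9)
#' align_to_minute_grid(s)
#' @export
align_to_minute_grid <- function(streams) {
  if (is.list(streams) && !is.data.frame(streams)) {
    streams <- dplyr::bind_rows(streams, .id = "channel")
  }
  stopifnot(all(c("channel", "timestamp", "value") %in% names(streams)))
  if (nrow(streams) == 0) stop("empty stream set: nothing to align")
  bad <- streams |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(mono = !is.unsorted(as.numeric(.data$timestamp),
                                         strictly = FALSE)) |>
    dplyr::filter(!.data$mono)
  if (nrow(bad) > 0)
    stop("non-monotonic timestamps in channel(s): ",
         paste(bad$channel, collapse = ", "))
  if (any(!is.finite(streams$value)))
    stop("non-finite values in input streams")
  glu <- streams$value[streams$channel == "glucose"]
  if (length(glu) && any(glu <= 0)) stop("glucose values must be positive")

  floored <- streams |>
    dplyr::mutate(time = as.POSIXct(60 * (as.numeric(.data$timestamp) %/% 60),
                                    origin = "1970-01-01", tz = "UTC")) |>
    dplyr::group_by(.data$channel, .data$time) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")

  grid <- tibble::tibble(
    time = seq(min(floored$time), max(floored$time), by = 60))
  wide <- floored |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value")
  tl <- dplyr::left_join(grid, wide, by = "time")
  for (ch in intersect(CHANNELS, names(tl))) {
    tl[[paste0(ch, "_flag")]] <- ifelse(is.na(tl[[ch]]), "missing", "observed")
  }
  tl
}

#' Backfill glucose over a bounded horizon
#'
#' Fills each missing glucose minute from the nearest subsequent observation
#' at most `limit` minutes ahead, flagging it `"backfilled"`; minutes farther
#' than `limit` from the next observation stay missing. This is the only
#' place future data touches a cell, and the bound keeps it within one CGM
#' sampling interval.
#'
#' @param timeline Timeline tibble from [align_to_minute_grid()].
#' @param limit Maximum look-ahead in minutes (default 5, the CGM cadence).
#' @return The timeline with glucose filled and flags updated.
#' @export
backfill_glucose <- function(timeline, limit = 5) {
  if (!"glucose" %in% names(timeline)) return(timeline)
  x <- timeline$glucose
  flag <- timeline$glucose_flag
  obs <- which(flag == "observed")
  if (length(obs)) {
    # distance (rows == minutes) to the next observation
    nxt <- rev(cummin(rev(replace(rep(Inf, length(x)), obs, obs))))
    dist <- nxt - seq_along(x)
    fill <- is.na(x) & is.finite(nxt) & dist <= limit
    x[fill] <- x[nxt[fill]]
    flag[fill] <- "backfilled"
  }
  timeline$glucose <- x
  timeline$glucose_flag <- flag
  timeline
}

#' Forward-fill a sparse channel with a leakage-safe limit
#'
#' Fills missing minutes of `hrv`, `rr` or `bos` from the most recent prior
#' observation within `limit` minutes, flagging them `"forward_filled"`. The
#' limits default to each channel's measurement cadence (15 min for HRV and
#' respiratory rate, 30 min for blood oxygen saturation) so no value is
#' carried beyond one sampling interval and nothing is ever filled from the
#' future. Heart rate, steps and energy are never imputed and calling this on
#' them is an error.
#'
#' @inheritParams backfill_glucose
#' @param channel One of `"hrv"`, `"rr"`, `"bos"`.
#' @param limit Maximum carry-forward in minutes; defaults to the channel's
#'   cadence.
#' @return The timeline with the channel filled and flags updated.
#' @export
forward_fill_limited <- function(timeline, channel,
                                 limit = FILL_LIMITS[[channel]]) {
  if (!channel %in% c("hrv", "rr", "bos"))
    stop("channel '", channel, "' is never imputed; forward filling applies ",
         "to hrv, rr and bos only")
  if (!channel %in% names(timeline)) return(timeline)
  x <- timeline[[channel]]
  fl <- timeline[[paste0(channel, "_flag")]]
  obs <- which(fl == "observed")
  if (length(obs)) {
    prv <- cummax(replace(rep(-Inf, length(x)), obs, obs))
    dist <- seq_along(x) - prv
    fill <- is.na(x) & is.finite(prv) & dist > 0 & dist <= limit
    x[fill] <- x[prv[fill]]
    fl[fill] <- "forward_filled"
  }
  timeline[[channel]] <- x
  timeline[[paste0(channel, "_flag")]] <- fl
  timeline
}

#' Apply the full imputation schedule to a timeline
#'
#' Glucose backfill (5 min) plus limited forward fill of HRV and respiratory
#' rate (15 min) and blood oxygen saturation (30 min). Heart rate, step count
#' and active energy are left untouched; the downstream tree ensemble handles
#' their missing minutes natively.
#'
#' @inheritParams backfill_glucose
#' @param limits Named numeric vector of per-channel limits (minutes);
#'   defaults to `c(glucose = 5, hrv = 15, rr = 15, bos = 30)`.
#' @return The imputed timeline.
#' @export
impute_timeline <- function(timeline, limits = FILL_LIMITS) {
  timeline <- backfill_glucose(timeline, limits[["glucose"]])
  for (ch in c("hrv", "rr", "bos")) {
    timeline <- forward_fill_limited(timeline, ch, limits[[ch]])
  }
  timeline
}
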