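#' Trailing rolling mean over non-missing minutes
#'
#' Mean over the window ending at the current minute (current value plus the
#' previous `window_minutes - 1`), computed over the non-missing values in
#' the window; `NA` when the whole window is missing. Trailing orientation is
#' what keeps the features causal. Windows at the start of the record shrink
#' to the available history.
#'
#' @param x Numeric minute-grid series (may contain `NA`).
#' @param window_minutes Window length in minutes.
#' @param allowed Optional set of permitted window lengths; a window outside
#'   it is an error. The canonical heart-rate windows are 10, 30 and 60.
#' @return Numeric vector, same length as `x`.
#' @examples
#' rolling_mean(c(60, 70, 80), 3)
#' @export
rolling_mean <- function(x, window_minutes, allowed = NULL) {
  check_window(window_minutes, allowed)
  w <- as.integer(window_minutes)
  n <- length(x)
  cs <- cumsum(ifelse(is.na(x), 0, x))
  cn <- cumsum(!is.na(x))
  lag_cs <- c(rep(0, w), cs)[seq_len(n)]
  lag_cn <- c(rep(0, w), cn)[seq_len(n)]
  num <- cs - lag_cs
  den <- cn - lag_cn
  ifelse(den > 0, num / den, NA_real_)
}

#' Trailing rolling sum over a window
#'
#' As [rolling_mean()] but summing; missing minutes contribute 0, matching
#' the count semantics of step and energy channels (an unrecorded minute adds
#' no steps). Canonical windows are 30 and 60 minutes.
#'
#' @inheritParams rolling_mean
#' @export
rolling_sum <- function(x, window_minutes, allowed = NULL) {
  check_window(window_minutes, allowed)
  w <- as.integer(window_minutes)
  n <- length(x)
  cs <- cumsum(ifelse(is.na(x), 0, x))
  cs - c(rep(0, w), cs)[seq_len(n)]
}

check_window <- function(window, allowed) {
  if (length(window) != 1 || window < 1)
    stop("window_minutes must be a single positive number")
  if (!is.null(allowed) && !window %in% allowed)
    stop("window of ", window, " min is not in the configured set (",
         paste(allowed, collapse = ", "), ")")
  invisible(window)
}

#' HRV change since the previous measurement
#'
#' At each observed HRV minute, the difference from the previous observation;
#' the value is held constant until the next observation and is missing
#' before the second observation of the record (no prior measurement to
#' difference against). Uses raw observations, not forward-filled values, so
#' the feature reflects true measurement-to-measurement change.
#'
#' @param values Minute-grid HRV column (any state of imputation).
#' @param flags Matching provenance flags; only `"observed"` cells count as
#'   measurements.
#' @return Numeric minute-grid series of deltas.
#' @export
hrv_delta_series <- function(values, flags) {
  n <- length(values)
  out <- rep(NA_real_, n)
  obs <- which(flags == "observed")
  if (length(obs) >= 2) {
    d <- diff(values[obs])
    # delta known from each observation (2nd onward) until the next one
    starts <- obs[-1]
    ends <- c(obs[-(1:2)] - 1L, n)
    for (k in seq_along(starts)) out[starts[k]:ends[k]] <- d[k]
  }
  out
}

#' Cyclic encoding of clock time
#'
#' Maps the fractional hour of day h onto the unit circle:
#' `sin(2*pi*h/24)`, `cos(2*pi*h/24)`, so 23:59 and 00:00 are neighbours and
#' the pair always satisfies sin^2 + cos^2 = 1.
#'
#' @param time POSIXct vector.
#' @return Tibble with `tod_sin`, `tod_cos`.
#' @examples
#' encode_time_of_day(as.POSIXct("2024-01-01 06:00", tz = "UTC"))
#' @export
encode_time_of_day <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  tibble::tibble(tod_sin = sin(2 * pi * h / 24),
                 tod_cos = cos(2 * pi * h / 24))
}

#' Whole hours since the last logged meal
#'
#' Ordinal feature: `floor()` of the hours elapsed since the most recent meal
#' entry at or before each query time, capped at `cap_hours`; missing before
#' the first recorded meal.
#'
#' @param meal_times POSIXct vector of meal entries (any order).
#' @param at POSIXct vector of query times.
#' @param cap_hours Upper bound on the ordinal value (bounds the overnight
#'   range).
#' @return Numeric vector of whole hours.
#' @export
time_since_last_meal <- function(meal_times, at, cap_hours = 12) {
  meal_times <- sort(meal_times)
  idx <- findInterval(as.numeric(at), as.numeric(meal_times))
  out <- rep(NA_real_, length(at))
  has <- idx > 0
  out[has] <- pmin(cap_hours, floor(
    (as.numeric(at[has]) - as.numeric(meal_times[idx[has]])) / 3600))
  out
}

#' Insulin-on-board fraction from diary doses
#'
#' Stepwise decay of the most recent short-acting dose over the four hours
#' after administration: 100% during the first hour, then 75%, 50% and 25%
#' in hours two to four, and 0 beyond four hours or when no dose was logged.
#' Hour boundaries are half-open toward the later step (a value exactly k
#' hours after the dose belongs to hour k), and a new dose resets the clock —
#' doses are diary ticks without dosage, so stacking is not modeled.
#'
#' @param dose_times POSIXct vector of insulin entries.
#' @param at POSIXct vector of query times.
#' @return Numeric vector with values in {1, 0.75, 0.5, 0.25, 0}.
#' @examples
#' d <- as.POSIXct("2024-01-01 08:00", tz = "UTC")
#' insulin_on_board(d, d + 3600 * c(0.5, 1.5, 2.5, 3.5, 5))
#' @export
insulin_on_board <- function(dose_times, at) {
  dose_times <- sort(dose_times)
  idx <- findInterval(as.numeric(at), as.numeric(dose_times))
  out <- numeric(length(at))
  has <- idx > 0
  hrs <- (as.numeric(at[has]) - as.numeric(dose_times[idx[has]])) / 3600
  out[has] <- c(1, 0.75, 0.5, 0.25)[pmax(1, ceiling(hrs))] |>
    (\(v) ifelse(hrs > 4, 0, v))()
  out[is.na(out)] <- 0
  out
}

#' Compute every engineered feature on a minute-grid timeline
#'
#' Adds the full feature set in one pass: heart-rate rolling means (10/30/60
#' min), last HRV value and HRV delta, last blood-oxygen and respiratory-rate
#' values, step and energy rolling sums (30/60 min), cyclic time-of-day, time
#' since last meal and insulin on board. Every feature at minute t depends on
#' data at minutes <= t only.
#'
#' @param timeline Imputed timeline from [impute_timeline()].
#' @param diary Diary tibble (meals and insulin entries are consumed here).
#' @param include_meal Set `FALSE` for participants with incomplete meal
#'   records, who are modeled without the mealtime-derived feature.
#' @return The timeline with feature columns appended.
#' @export
compute_features <- function(timeline, diary, include_meal = TRUE) {
  tl <- timeline
  tl$hr_ra10 <- rolling_mean(tl$hr, 10, allowed = c(10, 30, 60))
  tl$hr_ra30 <- rolling_mean(tl$hr, 30, allowed = c(10, 30, 60))
  tl$hr_ra60 <- rolling_mean(tl$hr, 60, allowed = c(10, 30, 60))
  tl$hrv_last <- tl$hrv
  tl$hrv_delta <- hrv_delta_series(tl$hrv, tl$hrv_flag)
  tl$bos_last <- if ("bos" %in% names(tl)) tl$bos else NA_real_
  tl$rr_last <- if ("rr" %in% names(tl)) tl$rr else NA_real_
  tl$steps_rs30 <- rolling_sum(tl$steps, 30, allowed = c(30, 60))
  tl$steps_rs60 <- rolling_sum(tl$steps, 60, allowed = c(30, 60))
  tl$energy_rs30 <- rolling_sum(tl$energy, 30, allowed = c(30, 60))
  tl$energy_rs60 <- rolling_sum(tl$energy, 60, allowed = c(30, 60))
  tod <- encode_time_of_day(tl$time)
  tl$tod_sin <- tod$tod_sin
  tl$tod_cos <- tod$tod_cos
  if (include_meal) {
    meals <- diary$timestamp[diary$entry_type == "meal"]
    tl$time_since_meal <- time_since_last_meal(meals, tl$time)
  }
  doses <- diary$timestamp[diary$entry_type == "insulin"]
  tl$insulin_on_board <- insulin_on_board(doses, tl$time)
  tl
}

#' Feature schemas for the waking and sleeping models
#'
#' The waking model sees 13 inputs (cardiac, activity, time-of-day, manual);
#' the sleeping model swaps the four activity features for the two nocturnal
#' respiratory channels (blood oxygen saturation and respiratory rate).
#' Participants without meal records lose `time_since_meal` from either
#' schema.
#'
#' @param kind `"day"` or `"night"`.
#' @param include_meal Whether the mealtime-derived feature is available.
#' @return Character vector of feature column names.
#' @export
feature_schema <- function(kind, include_meal = TRUE) {
  common <- c("hr_ra10", "hr_ra30", "hr_ra60", "hrv_last", "hrv_delta",
              "tod_sin", "tod_cos",
              if (include_meal) "time_since_meal", "insulin_on_board")
  extra <- switch(kind,
                  day = c("steps_rs30", "steps_rs60",
                          "energy_rs30", "energy_rs60"),
                  night = c("bos_last", "rr_last"),
                  stop("unknown diurnal kind: ", kind))
  c(setdiff(common, c("tod_sin", "tod_cos", "time_since_meal",
                      "insulin_on_board")),
    extra,
    intersect(common, c("tod_sin", "tod_cos", "time_since_meal",
                        "insulin_on_board")))
}

#' Assemble the per-minute feature matrix for one diurnal kind
#'
#' Subsets the fully featured timeline to the segments of the requested kind
#' and keeps the schema columns plus the minute timestamp, segment id and
#' label.
#'
#' @param features Timeline from [compute_features()], already carrying
#'   `segment_id` (see [segment_timeline()]) and `hypo` labels.
#' @param segments Segment tibble.
#' @param kind `"day"` or `"night"`.
#' @param include_meal Whether the mealtime feature is present.
#' @return Tibble: `time`, `segment_id`, schema feature columns, `hypo`.
#' @export
build_feature_matrix <- function(features, segments, kind,
                                 include_meal = TRUE) {
  schema <- feature_schema(kind, include_meal)
  keep <- segments$segment_id[segments$kind == kind]
  features |>
    dplyr::filter(.data$segment_id %in% keep) |>
    dplyr::select("time", "segment_id", dplyr::all_of(schema), "hypo")
}
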