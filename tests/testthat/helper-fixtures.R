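# shared fixture builders; everything is generated in code at test time

t0 <- function() as.POSIXct("2024-03-01 00:00:00", tz = "UTC")

# minute-grid timeline straight from per-channel minute vectors (NA = missing)
mk_timeline <- function(...) {
  chans <- list(...)
  n <- max(lengths(chans))
  tl <- tibble::tibble(time = t0() + 60 * (seq_len(n) - 1))
  for (ch in names(chans)) {
    v <- rep(NA_real_, n)
    v[seq_along(chans[[ch]])] <- chans[[ch]]
    tl[[ch]] <- v
    tl[[paste0(ch, "_flag")]] <- ifelse(is.na(v), "missing", "observed")
  }
  tl
}

tiny_config <- function(...) {
  defaults <- list(n_participants = 1, days_per_participant = 3,
                   day_event_rate = 1, night_event_rate = 0.6,
                   sleep_jitter_sd = 10, seed = 42)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# independent run-labeling oracle: slide every 15-minute window and mark
# minutes covered by a fully-below window
oracle_label <- function(glucose, threshold = 4, min_duration = 15) {
  below <- !is.na(glucose) & glucose < threshold
  lab <- integer(length(glucose))
  if (length(glucose) >= min_duration) {
    for (s in seq_len(length(glucose) - min_duration + 1)) {
      w <- s:(s + min_duration - 1)
      if (all(below[w])) lab[w] <- 1L
    }
  }
  lab
}

# independent Youden oracle: direct loop over every cut-point
oracle_youden_j <- function(scores, labels) {
  best <- -Inf
  for (t in unique(scores)) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

# check every imputed cell's distance to its source observation
check_fill_limits <- function(tl, limits = c(glucose = 5, hrv = 15, rr = 15,
                                             bos = 30)) {
  ok <- TRUE
  for (ch in intersect(names(limits), names(tl))) {
    fl <- tl[[paste0(ch, "_flag")]]
    obs <- which(fl == "observed")
    for (i in which(fl %in% c("backfilled", "forward_filled"))) {
      if (fl[i] == "backfilled") {
        src <- obs[obs > i]
        ok <- ok && length(src) > 0 && min(src) - i <= limits[[ch]]
      } else {
        src <- obs[obs < i]
        ok <- ok && length(src) > 0 && i - max(src) <= limits[[ch]]
      }
    }
  }
  ok
}

# one prepared participant, cached across tests in a session
prepared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- run_config(simulate = tiny_config(days_per_participant = 5))
      cohort <- simulate_cohort(cfg$simulate)
      cache <<- prepare_participant(cohort$streams[[1]], cohort$diary[[1]],
                                    "P01", cfg)
    }
    cache
  }
})
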