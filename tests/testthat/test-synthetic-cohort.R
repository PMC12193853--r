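test_that("config validation rejects unlabelable or degenerate settings", {
  expect_error(cohort_config(event_duration_range = c(10, 30)), ">= 15")
  expect_error(cohort_config(insulin_prob_per_meal = 1.5), "insulin_prob")
  expect_error(cohort_config(day_event_rate = -1), "rates")
  expect_error(cohort_config(event_duration_range = c(20, 2000)),
               "shortest diurnal segment")
})

test_that("zero-rate cohorts never produce a labelable glucose run", {
  cfg <- tiny_config(day_event_rate = 0, night_event_rate = 0,
                     transient_dip_rate = 0.5)
  pseed <- participant_seed(cfg$seed, 1)
  diary <- generate_diary(cfg, pseed)
  glu <- generate_glucose_trace(cfg, diary, pseed)
  expect_equal(nrow(glu$events), 0)
  tl <- align_to_minute_grid(list(glucose = glu$stream)) |>
    backfill_glucose()
  expect_equal(nrow(hypo_events(tl)), 0)
})

test_that("injected events are recoverable from the emitted trace", {
  cfg <- tiny_config()
  pseed <- participant_seed(cfg$seed, 1)
  diary <- generate_diary(cfg, pseed)
  glu <- generate_glucose_trace(cfg, diary, pseed)
  expect_gt(nrow(glu$events), 0)

  # a 20-min truth event covers >= 4 raw CGM samples below threshold
  for (i in seq_len(nrow(glu$events))) {
    in_ev <- glu$stream$timestamp >= glu$events$start[i] &
      glu$stream$timestamp < glu$events$end[i]
    expect_gte(sum(glu$stream$value[in_ev] < 4),
               glu$events$duration_min[i] / 5)
  }

  # the labeler recovers the truth set with start/end within one sample
  tl <- align_to_minute_grid(list(glucose = glu$stream)) |> backfill_glucose()
  found <- hypo_events(tl)
  expect_equal(nrow(found), nrow(glu$events))
  dt_start <- abs(as.numeric(difftime(found$start, glu$events$start,
                                      units = "mins")))
  dt_end <- abs(as.numeric(difftime(found$end, glu$events$end,
                                    units = "mins")))
  expect_true(all(dt_start <= 5) && all(dt_end <= 5))
})

test_that("simulation is seed-deterministic and seeds differentiate", {
  cfg <- tiny_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- tiny_config(seed = 43)
  c <- simulate_cohort(cfg2)
  expect_false(identical(a$streams[[1]], c$streams[[1]]))
})

test_that("wearable streams respect their nominal cadences", {
  cfg <- tiny_config()
  pseed <- participant_seed(cfg$seed, 1)
  diary <- generate_diary(cfg, pseed)
  glu <- generate_glucose_trace(cfg, diary, pseed)
  w <- generate_wearable_streams(cfg, diary, glu$events, pseed)

  expect_true(all(diff(as.numeric(w$hr$timestamp)) == 60))
  expect_true(all(diff(as.numeric(w$steps$timestamp)) == 60))
  expect_true(all(diff(as.numeric(glu$stream$timestamp)) == 300))
  # nocturnal channels: spacing is a multiple of the cadence inside nights
  gaps_rr <- diff(as.numeric(w$rr$timestamp)) / 60
  expect_true(all(gaps_rr %% 15 == 0 | gaps_rr > 15 * 15))
  # a full sleep window yields duration/15 RR and duration/30 BOS samples,
  # and nocturnal HRV sits on an unthinned 15-min grid
  sl <- diary$timestamp[diary$entry_type == "sleep_onset"][1]
  wk <- diary$timestamp[diary$entry_type == "wake"]
  wk <- wk[wk > sl][1]
  dur <- as.numeric(difftime(wk, sl, units = "mins"))
  n_rr <- sum(w$rr$timestamp >= sl & w$rr$timestamp < wk)
  n_bos <- sum(w$bos$timestamp >= sl & w$bos$timestamp < wk)
  expect_equal(n_rr, ceiling(dur / 15))
  expect_equal(n_bos, ceiling(dur / 30))
  hrv_night <- w$hrv$timestamp[w$hrv$timestamp >= sl & w$hrv$timestamp < wk]
  expect_true(all(diff(as.numeric(hrv_night)) == 15 * 60))

  # activity is silent during sleep
  asleep <- rep(FALSE, nrow(w$steps))
  sls <- diary$timestamp[diary$entry_type == "sleep_onset"]
  wks <- diary$timestamp[diary$entry_type == "wake"]
  for (s in sls) {
    nxt <- min(wks[wks > s])
    asleep <- asleep | (w$steps$timestamp >= s & w$steps$timestamp < nxt)
  }
  expect_true(all(w$steps$value[asleep] == 0))
  expect_true(all(w$energy$value[asleep] == 0))
})

test_that("the injected heart-rate effect is recoverable from the stream", {
  cfg <- tiny_config(hr_effect = 10, days_per_participant = 6)
  pseed <- participant_seed(cfg$seed, 1)
  diary <- generate_diary(cfg, pseed)
  glu <- generate_glucose_trace(cfg, diary, pseed)
  w <- generate_wearable_streams(cfg, diary, glu$events, pseed)
  # nocturnal events only: daytime HR is confounded by activity
  nev <- glu$events[glu$events$kind == "night", ]
  skip_if(nrow(nev) == 0, "no night events drawn for this seed")
  deltas <- purrr::map_dbl(seq_len(nrow(nev)), function(i) {
    inside <- w$hr$timestamp >= nev$start[i] & w$hr$timestamp < nev$end[i]
    around <- (w$hr$timestamp >= nev$start[i] - 3600 &
                 w$hr$timestamp < nev$start[i]) |
      (w$hr$timestamp >= nev$end[i] & w$hr$timestamp < nev$end[i] + 3600)
    mean(w$hr$value[inside]) - mean(w$hr$value[around])
  })
  expect_lt(abs(mean(deltas) - 10), 3)
})

test_that("diary structure follows the configuration", {
  cfg <- tiny_config(meal_count_per_day = 3, insulin_prob_per_meal = 1,
                     sleep_jitter_sd = 0, days_per_participant = 10)
  diary <- generate_diary(cfg, participant_seed(cfg$seed, 1))
  expect_equal(sum(diary$entry_type == "meal"), 30)
  expect_equal(sum(diary$entry_type == "insulin"), 30)
  onsets <- diary$timestamp[diary$entry_type == "sleep_onset"]
  expect_equal(length(unique(format(onsets, "%H:%M"))), 1)
  # no insulin entries without meals
  cfg0 <- tiny_config(insulin_prob_per_meal = 0)
  diary0 <- generate_diary(cfg0, participant_seed(cfg0$seed, 1))
  expect_equal(sum(diary0$entry_type == "insulin"), 0)
})

test_that("cohort round-trips through the on-disk CSV/JSON layout", {
  cohort <- simulate_cohort(tiny_config(days_per_participant = 2))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_participant_dir(file.path(dir, "P01"))
  orig <- dplyr::arrange(cohort$streams[[1]], .data$channel, .data$timestamp)
  got <- dplyr::arrange(back$streams, .data$channel, .data$timestamp)
  expect_equal(got$value, orig$value)
  expect_equal(got$timestamp, orig$timestamp)
  expect_equal(back$diary$entry_type, cohort$diary[[1]]$entry_type)
})
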