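#' Configuration for a synthetic wearable cohort
#'
#' Bundles every knob of the synthetic-data generator: cohort size, diary
#' structure, hypoglycemic event rates and durations, the physiological
#' responses injected during events, channel baselines and noise levels.
#' Defaults mirror the study conditions the pipeline is designed for
#' (10 days of free-living data per participant, 5-min CGM, minute-level
#' heart rate and activity, sparse HRV, nocturnal-only respiratory channels).
#'
#' The injected effect sizes are illustrative: the source study does not
#' report hypoglycemia effect magnitudes on its own wearable channels, so the
#' defaults encode the direction and a plausible scale of the known
#' counter-regulatory response (tachycardia, reduced vagal HRV, mild
#' hyperventilation, slight desaturation).
#'
#' @param n_participants Number of participants to simulate.
#' @param days_per_participant Days of data per participant (study design: 10).
#' @param sleep_onset_hour,wake_hour Nominal sleep schedule, hours of day.
#' @param sleep_jitter_sd Per-night jitter of sleep onset and wake, minutes.
#' @param day_event_rate,night_event_rate Expected hypoglycemic events per
#'   day segment / night segment (Poisson).
#' @param event_duration_range Event duration bounds in minutes; the minimum
#'   must be at least 15 so every injected event is labelable under the
#'   15-minute rule.
#' @param transient_dip_rate Expected sub-15-minute glucose dips per segment;
#'   these exercise the duration filter and must never become events.
#' @param hr_effect Heart-rate change during events, bpm (positive = rise).
#' @param hrv_effect HRV change during events, ms (negative = suppression).
#' @param rr_effect Respiratory-rate change during events, breaths/min.
#' @param bos_effect Blood-oxygen-saturation change during events, percentage
#'   points.
#' @param effect_lag Minutes between event onset and physiological response.
#' @param glucose_baseline Euglycemic mean, mmol/L.
#' @param hr_baseline,hrv_baseline,bos_baseline,rr_baseline Channel baselines
#'   (bpm, ms, %, breaths/min).
#' @param noise_sd Named numeric vector of per-channel Gaussian noise SDs;
#'   any subset of `glucose`, `hr`, `hrv`, `bos`, `rr` overrides the default.
#' @param hrv_day_keep_prob Probability that a daytime 15-min HRV slot is
#'   emitted (Bernoulli thinning emulating "restful states only" sampling).
#' @param meal_count_per_day Meals logged per day.
#' @param insulin_prob_per_meal Probability that a meal is followed by a
#'   short-acting insulin dose entry.
#' @param seed Integer seed; participant seeds are derived from it.
#'
#' @return A `cohort_config` list.
#' @examples
#' cfg <- cohort_config(n_participants = 2, seed = 7)
#' cfg$days_per_participant
#' @export
cohort_config <- function(n_participants = 4,
                          days_per_participant = 10,
                          sleep_onset_hour = 23,
                          wake_hour = 7,
                          sleep_jitter_sd = 20,
                          day_event_rate = 0.6,
                          night_event_rate = 0.35,
                          event_duration_range = c(20, 90),
                          transient_dip_rate = 0.15,
                          hr_effect = 10,
                          hrv_effect = -15,
                          rr_effect = 2,
                          bos_effect = -1.5,
                          effect_lag = 0,
                          glucose_baseline = 7,
                          hr_baseline = 70,
                          hrv_baseline = 45,
                          bos_baseline = 97,
                          rr_baseline = 14,
                          noise_sd = NULL,
                          hrv_day_keep_prob = 0.5,
                          meal_count_per_day = 3,
                          insulin_prob_per_meal = 0.9,
                          seed = 1L) {
  default_noise <- c(glucose = 0.25, hr = 3, hrv = 8, bos = 0.5, rr = 1)
  if (!is.null(noise_sd)) {
    stopifnot(!is.null(names(noise_sd)),
              all(names(noise_sd) %in% names(default_noise)))
    default_noise[names(noise_sd)] <- noise_sd
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    days_per_participant = as.integer(days_per_participant),
    sleep_onset_hour = sleep_onset_hour,
    wake_hour = wake_hour,
    sleep_jitter_sd = sleep_jitter_sd,
    day_event_rate = day_event_rate,
    night_event_rate = night_event_rate,
    event_duration_range = as.numeric(event_duration_range),
    transient_dip_rate = transient_dip_rate,
    hr_effect = hr_effect,
    hrv_effect = hrv_effect,
    rr_effect = rr_effect,
    bos_effect = bos_effect,
    effect_lag = effect_lag,
    glucose_baseline = glucose_baseline,
    hr_baseline = hr_baseline,
    hrv_baseline = hrv_baseline,
    bos_baseline = bos_baseline,
    rr_baseline = rr_baseline,
    noise_sd = default_noise,
    hrv_day_keep_prob = hrv_day_keep_prob,
    meal_count_per_day = as.integer(meal_count_per_day),
    insulin_prob_per_meal = insulin_prob_per_meal,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1L) stop("n_participants must be >= 1")
  if (cfg$days_per_participant < 1L) stop("days_per_participant must be >= 1")
  if (length(cfg$event_duration_range) != 2 ||
      cfg$event_duration_range[1] > cfg$event_duration_range[2])
    stop("event_duration_range must be (min, max) with min <= max")
  if (cfg$event_duration_range[1] < 15)
    stop("event_duration_range minimum must be >= 15 minutes so injected ",
         "events satisfy the labeling rule")
  if (cfg$day_event_rate < 0 || cfg$night_event_rate < 0 ||
      cfg$transient_dip_rate < 0)
    stop("event rates must be >= 0")
  if (cfg$insulin_prob_per_meal < 0 || cfg$insulin_prob_per_meal > 1)
    stop("insulin_prob_per_meal must lie in [0, 1]")
  if (cfg$hrv_day_keep_prob < 0 || cfg$hrv_day_keep_prob > 1)
    stop("hrv_day_keep_prob must lie in [0, 1]")
  # shortest segment must be able to host the longest event
  seg_min <- 60 * min(24 - (cfg$sleep_onset_hour - cfg$wake_hour),
                      cfg$sleep_onset_hour - cfg$wake_hour)
  if (cfg$event_duration_range[2] > seg_min)
    stop("event_duration_range maximum (", cfg$event_duration_range[2],
         " min) exceeds the shortest diurnal segment (", seg_min, " min)")
  invisible(cfg)
}

#' Derive a reproducible per-participant seed
#'
#' Fans the global cohort seed out to one seed per participant so that a
#' participant can be re-simulated in isolation and match the full-cohort run.
#'
#' @param seed Global integer seed.
#' @param i Participant index (1-based).
#' @return An integer seed below 2^31.
#' @export
participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}
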