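# small labeled feature table: k segments, optionally separable on feature x
mk_features <- function(n_seg = 5, n_per = 120, event_segs = 1:2,
                        separable = TRUE, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_seg), function(s) {
    hypo <- integer(n_per)
    if (s %in% event_segs) hypo[30:59] <- 1L  # one 30-min event per segment
    x <- rnorm(n_per)
    if (separable) x <- x + 4 * hypo
    tibble::tibble(
      time = t0() + 86400 * s + 60 * (seq_len(n_per) - 1),
      segment_id = paste0("seg", s),
      x = x, z = rnorm(n_per), hypo = hypo)
  })
}

seg_table <- function(fm) {
  fm |>
    dplyr::group_by(segment_id) |>
    dplyr::summarise(start = min(time), end = max(time) + 60,
                     contains_event = any(hypo == 1L), .groups = "drop") |>
    dplyr::mutate(participant_id = "P", kind = "day")
}

ev_table <- function(fm) {
  fm |>
    dplyr::filter(hypo == 1L) |>
    dplyr::group_by(segment_id) |>
    dplyr::summarise(start = min(time), end = max(time) + 60,
                     .groups = "drop") |>
    dplyr::mutate(event_id = dplyr::row_number(),
                  duration_min = as.numeric(difftime(end, start, "mins")),
                  truncated = FALSE, kind = "day")
}

test_that("the split plan holds out each event-bearing segment exactly once", {
  fm <- mk_features(n_seg = 10, event_segs = c(2, 5, 9))
  plan <- make_split_plan(seg_table(fm))
  expect_equal(nrow(plan), 3)
  expect_setequal(plan$test_segment_id, paste0("seg", c(2, 5, 9)))
  for (i in seq_len(nrow(plan))) {
    expect_equal(length(plan$train_segment_ids[[i]]), 9)
    expect_false(plan$test_segment_id[i] %in% plan$train_segment_ids[[i]])
  }
  # all segments event-bearing: still one iteration per segment
  all_ev <- seg_table(mk_features(n_seg = 5, event_segs = 1:5))
  expect_equal(nrow(make_split_plan(all_ev)), 5)
  # degenerate inputs
  expect_error(make_split_plan(seg_table(mk_features(event_segs = 0))),
               "not modelable")
  expect_error(make_split_plan(seg_table(mk_features(n_seg = 1))),
               "single-segment")
})

test_that("undersampling balances 1:1, reproducibly, preserving order", {
  fm <- mk_features(n_seg = 6, event_segs = 1)
  bal <- undersample_majority(fm, seed = 3)
  expect_equal(sum(bal$hypo == 1), sum(bal$hypo == 0))
  expect_equal(sum(bal$hypo == 1), sum(fm$hypo == 1))
  expect_false(is.unsorted(bal$time))
  expect_identical(bal, undersample_majority(fm, seed = 3))
  expect_false(identical(bal, undersample_majority(fm, seed = 4)))
  # fewer negatives than positives: keep everything, never upsample
  few <- fm[c(which(fm$hypo == 1), which(fm$hypo == 0)[1:5]), ]
  expect_equal(nrow(undersample_majority(few, 1)), nrow(few))
  expect_error(undersample_majority(fm[fm$hypo == 0, ], 1), "no positive")
})

test_that("standardization uses training statistics only", {
  train <- tibble::tibble(a = c(60, 70, 80), b = 1, hypo = c(0, 1, 0))
  test <- tibble::tibble(a = 80, b = 5, hypo = 1)
  sc <- standardize(train, test, c("a", "b"))
  expect_equal(sc$test$a, (80 - 70) / 10)
  # constant column: centered, not divided
  expect_equal(sc$train$b, c(0, 0, 0))
  expect_equal(sc$test$b, 4)
  # missing cells stay missing
  train_na <- tibble::tibble(a = c(1, NA, 3), hypo = c(0, 1, 0))
  sc2 <- standardize(train_na, train_na, "a")
  expect_true(is.na(sc2$train$a[2]))
})

test_that("the tree ensemble separates separable data and is deterministic", {
  fm <- mk_features(n_seg = 4, event_segs = 1:2, separable = TRUE)
  segs <- seg_table(fm)
  plan <- make_split_plan(segs)
  train <- fm[fm$segment_id %in% plan$train_segment_ids[[1]], ]
  test <- fm[fm$segment_id == plan$test_segment_id[1], ]
  bal <- undersample_majority(train, 1)
  m <- fit_tree_ensemble(bal, c("x", "z"))
  s <- predict_scores(m, test)
  expect_true(all(s >= 0 & s <= 1))
  yd <- youden_threshold(s, test$hypo)
  expect_equal(as.numeric(pROC::auc(pROC::roc(test$hypo, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))), 1)
  expect_equal(yd$j, 1)
  # refitting with identical data reproduces identical scores
  m2 <- fit_tree_ensemble(bal, c("x", "z"))
  expect_identical(predict_scores(m2, test), s)
  expect_error(fit_tree_ensemble(bal[bal$hypo == 1, ], c("x", "z")),
               "single class")
})

test_that("Youden search matches the brute-force oracle on random vectors", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    scores <- round(runif(n), 3)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    yd <- youden_threshold(scores, labels)
    expect_equal(yd$j, oracle_youden_j(scores, labels), tolerance = 1e-12)
    expect_equal(yd$j, yd$sensitivity + yd$specificity - 1)
  }
  expect_error(youden_threshold(runif(5), rep(1, 5)), "both classes")
  # worked case: any threshold in (0.2, 0.8] achieves J = 1
  yd <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(yd$j, 1)
  expect_equal(yd$threshold, 0.8)
})

test_that("iteration evaluation reports detection and flags degenerate tests", {
  fm <- mk_features(n_seg = 3, event_segs = 1)
  test <- fm[fm$segment_id == "seg1", ]
  events <- ev_table(fm)
  # oracle scorer: 1 inside events, 0 outside
  res <- evaluate_iteration(as.numeric(test$hypo), test, events)
  expect_true(res$valid)
  expect_equal(res$auroc, 1)
  expect_true(all(res$detection$detected_any))
  expect_true(all(res$detection$detected_first15))
  # all-negative test segment cannot be scored
  res2 <- evaluate_iteration(runif(120), fm[fm$segment_id == "seg2", ],
                             events[0, ])
  expect_false(res2$valid)
  expect_true(is.na(res2$auroc))
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(11)
  scores <- runif(200)
  labels <- rbinom(200, 1, plogis(3 * scores - 1.5))
  a1 <- evaluate_iteration(scores,
                           tibble::tibble(time = t0() + 60 * 1:200,
                                          hypo = labels),
                           ev_table(mk_features())[0, ])$auroc
  a2 <- evaluate_iteration(qlogis(pmin(pmax(scores, 1e-6), 1 - 1e-6)) / 10,
                           tibble::tibble(time = t0() + 60 * 1:200,
                                          hypo = labels),
                           ev_table(mk_features())[0, ])$auroc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("fit_personalized keeps train/test segments disjoint and aggregates", {
  fm <- mk_features(n_seg = 5, event_segs = 1:2, separable = TRUE)
  fit <- fit_personalized(fm, seg_table(fm), ev_table(fm), seeds = 1:2,
                          participant_id = "P", kind = "day")
  expect_s3_class(fit, "hypo_personalized")
  expect_equal(nrow(fit$iterations), 2 * 2)  # iterations x seeds
  for (i in seq_len(nrow(fit$plan)))
    expect_false(fit$plan$test_segment_id[i] %in%
                   fit$plan$train_segment_ids[[i]])
  rep <- summarise_personalized(fit)
  expect_true(rep$auroc >= min(fit$iterations$auroc) &
                rep$auroc <= max(fit$iterations$auroc))
  # identity: a single iteration x seed aggregates to itself
  fm1 <- mk_features(n_seg = 3, event_segs = 1)
  fit1 <- fit_personalized(fm1, seg_table(fm1), ev_table(fm1), seeds = 7,
                           participant_id = "P", kind = "day")
  expect_equal(summarise_personalized(fit1)$auroc, fit1$iterations$auroc)
  # two iterations with known metrics average evenly over iterations
  manual <- fit
  manual$iterations <- tibble::tibble(
    iteration = c(1, 1, 2, 2), seed = c(1, 2, 1, 2), valid = TRUE,
    auroc = c(0.55, 0.65, 0.8, 0.8), sensitivity = 0.5, specificity = 0.5)
  expect_equal(summarise_personalized(manual)$auroc, mean(c(0.6, 0.8)))
})

test_that("stronger injected cardiac effects raise detectability", {
  aurocs <- purrr::map_dbl(c(0, 8, 16), function(eff) {
    cfg <- run_config(
      simulate = tiny_config(days_per_participant = 5, hr_effect = eff,
                             hrv_effect = -eff, night_event_rate = 0.3,
                             seed = 21),
      seeds = 1:2)
    rep <- run_pipeline(cfg)
    mean(rep$models$auroc[rep$models$kind == "day"])
  })
  expect_gt(stats::cor(c(0, 8, 16), aurocs), 0)
  expect_gt(aurocs[3], aurocs[1])
})
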