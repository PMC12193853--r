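#' Build the iterative leave-hypo-segment-out split plan
#'
#' One iteration per event-bearing segment: that segment becomes the test
#' set and every other segment of the same participant and diurnal kind
#' (event-bearing or not) forms the training set. Random row-level splits
#' would leak across the strongly autocorrelated minute series, and a purely
#' temporal split cannot guarantee events on both sides, so whole diurnal
#' segments are the split unit.
#'
#' @param segments Segment tibble for one participant and one kind, with
#'   `contains_event` (see [mark_event_segments()]).
#' @return Tibble `iteration`, `test_segment_id`, `train_segment_ids`
#'   (list column).
#' @export
make_split_plan <- function(segments) {
  if (length(unique(segments$kind)) > 1)
    stop("split plans are built per diurnal kind; mixed kinds supplied")
  if (nrow(segments) < 2)
    stop("cannot split a single-segment dataset")
  test_ids <- segments$segment_id[segments$contains_event]
  if (length(test_ids) == 0)
    stop("no event-bearing segment: participant/kind is not modelable")
  tibble::tibble(
    iteration = seq_along(test_ids),
    test_segment_id = test_ids,
    train_segment_ids = purrr::map(test_ids,
                                   ~ setdiff(segments$segment_id, .x))
  )
}

#' Randomly undersample the majority class to balance training data
#'
#' Negatives are sampled without replacement down to the positive count
#' (1:1); positives are untouched, the temporal order of retained rows is
#' preserved, and the draw is reproducible per seed. Test data is never
#' touched — it keeps the natural imbalance.
#'
#' @param rows Training feature rows with a binary `hypo` label column.
#' @param seed Integer random state for the draw.
#' @return The balanced subset of `rows`, original order preserved.
#' @export
undersample_majority <- function(rows, seed) {
  pos <- which(rows$hypo == 1L)
  neg <- which(rows$hypo == 0L)
  if (length(pos) == 0)
    stop("no positive rows in training data: split plan invalid")
  if (length(neg) > length(pos)) {
    old <- .Random.seed_save()
    set.seed(seed)
    neg <- sort(sample(neg, length(pos)))
    .Random.seed_restore(old)
  }
  rows[sort(c(pos, neg)), ]
}

# keep undersampling from perturbing the caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Standardize features on training statistics only
#'
#' Per-feature z-scores with mean and SD estimated on the training rows and
#' applied unchanged to the test rows, so no test-set information reaches the
#' scaler. Missing cells stay missing; zero-SD (constant) features are
#' centered but not divided.
#'
#' @param train,test Feature tibbles sharing `feature_cols`.
#' @param feature_cols Character vector of columns to scale.
#' @return List `train`, `test`, `center`, `scale`.
#' @export
standardize <- function(train, test, feature_cols) {
  center <- purrr::map_dbl(feature_cols, ~ mean(train[[.x]], na.rm = TRUE))
  scale <- purrr::map_dbl(feature_cols, ~ stats::sd(train[[.x]], na.rm = TRUE))
  names(center) <- names(scale) <- feature_cols
  center[is.na(center)] <- 0
  scale[is.na(scale) | scale == 0] <- 1
  apply_scale <- function(d) {
    for (f in feature_cols) d[[f]] <- (d[[f]] - center[[f]]) / scale[[f]]
    d
  }
  list(train = apply_scale(train), test = apply_scale(test),
       center = center, scale = scale)
}

#' Fit the gradient-boosted tree classifier
#'
#' Binary gradient-boosted decision trees with both L1 (`alpha`) and L2
#' (`lambda`) regularization set to 10 to curb overfitting on the small
#' per-participant training sets; remaining hyperparameters sit at the
#' library defaults (eta 0.3, depth 6, 100 rounds) and are recorded on the
#' returned object. Missing feature cells are handled natively by the tree
#' learner's default directions.
#'
#' @param train Balanced, standardized training rows with `hypo` labels.
#' @param feature_cols Feature column names (order fixes the model schema).
#' @param alpha,lambda L1/L2 regularization weights.
#' @param nrounds Boosting rounds.
#' @param eta Learning rate.
#' @param max_depth Maximum tree depth.
#' @return A `hypo_model` object wrapping the booster.
#' @export
fit_tree_ensemble <- function(train, feature_cols, alpha = 10, lambda = 10,
                              nrounds = 100, eta = 0.3, max_depth = 6) {
  if (length(unique(train$hypo)) < 2)
    stop("training data contains a single class")
  x <- as.matrix(train[, feature_cols])
  storage.mode(x) <- "double"
  dtrain <- xgboost::xgb.DMatrix(x, label = train$hypo, missing = NA)
  params <- list(objective = "binary:logistic", alpha = alpha,
                 lambda = lambda, eta = eta, max_depth = max_depth,
                 nthread = 1, seed = 0)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, feature_cols = feature_cols,
                 params = c(params, nrounds = nrounds)),
            class = "hypo_model")
}

#' Score new minutes with a fitted model
#'
#' @param model A `hypo_model` from [fit_tree_ensemble()].
#' @param newdata Feature rows carrying the model's feature columns.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_scores <- function(model, newdata) {
  missing_cols <- setdiff(model$feature_cols, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks model features: ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(newdata[, model$feature_cols])
  storage.mode(x) <- "double"
  as.numeric(stats::predict(model$booster,
                            xgboost::xgb.DMatrix(x, missing = NA)))
}

#' Operating point maximizing Youden's J
#'
#' Exhaustive search over every distinct score as a cut-point (prediction
#' positive when score >= threshold): the threshold maximizing
#' J = sensitivity + specificity - 1 is returned, ties broken toward the
#' higher (more specific) threshold.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary 0/1 labels (both classes required).
#' @return List `threshold`, `j`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("Youden threshold needs both classes present")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord]
  # at threshold t: positive iff score >= t; evaluate at the end of each tie
  # group of the descending sort, one candidate per distinct score
  ends <- c(which(diff(s_sorted) != 0), length(s_sorted))
  sens <- cumsum(l_sorted == 1)[ends] / n_pos
  spec <- (n_neg - cumsum(l_sorted == 0)[ends]) / n_neg
  j <- sens + spec - 1
  best <- which.max(j)  # candidates descend: first max = highest threshold
  list(threshold = s_sorted[ends][best], j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}

auroc <- function(scores, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Evaluate one split iteration on its held-out segment
#'
#' Computes the AUROC over every test minute, the Youden operating point on
#' the test scores, and per-event detection: whether any minute of the event
#' scores above threshold (`detected_any`) and whether that happens within
#' the event's first 15 minutes (`detected_first15`). A test segment whose
#' minutes are all one class leaves discrimination undefined and the
#' iteration is flagged invalid.
#'
#' @param scores Scores for the test rows.
#' @param test Test feature rows (`time`, `hypo`).
#' @param events Event tibble restricted to the test segment.
#' @return List of metrics plus a per-event detection tibble.
#' @export
evaluate_iteration <- function(scores, test, events) {
  if (length(unique(test$hypo)) < 2) {
    return(list(valid = FALSE, auroc = NA_real_, threshold = NA_real_,
                sensitivity = NA_real_, specificity = NA_real_,
                detection = tibble::tibble()))
  }
  auc <- auroc(scores, test$hypo)
  yd <- youden_threshold(scores, test$hypo)
  detection <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    in_ev <- test$time >= events$start[i] & test$time < events$end[i]
    first15 <- in_ev & test$time < events$start[i] + 15 * 60
    tibble::tibble(
      event_start = events$start[i],
      detected_any = any(scores[in_ev] >= yd$threshold),
      detected_first15 = any(scores[first15] >= yd$threshold))
  })
  list(valid = TRUE, auroc = auc, threshold = yd$threshold,
       sensitivity = yd$sensitivity, specificity = yd$specificity,
       detection = detection)
}

#' Train and evaluate one personalized model
#'
#' Runs the full leave-hypo-segment-out protocol for one participant and one
#' diurnal kind: for every iteration of the split plan and every
#' undersampling seed, balance the training segments, standardize on the
#' training rows, fit the regularized tree ensemble, score the held-out
#' segment, and record discrimination, the Youden operating point, per-event
#' detection and mean absolute Shapley attributions on the test rows.
#'
#' @param feature_matrix Output of [build_feature_matrix()].
#' @param segments Segment tibble filtered to this participant and kind,
#'   with `contains_event`.
#' @param events Qualifying events of this participant and kind.
#' @param seeds Undersampling random states (default 10 states).
#' @param participant_id,kind Identifiers carried into the result.
#' @param ... Passed to [fit_tree_ensemble()].
#' @return A `hypo_personalized` object: `$iterations` (one row per
#'   iteration x seed), `$detection`, `$attributions`, identifiers and the
#'   split plan.
#' @export
fit_personalized <- function(feature_matrix, segments, events, seeds = 1:10,
                             participant_id = NA_character_,
                             kind = NA_character_, ...) {
  plan <- make_split_plan(segments)
  feature_cols <- setdiff(names(feature_matrix),
                          c("time", "segment_id", "hypo"))
  iter_rows <- list()
  det_rows <- list()
  attr_rows <- list()
  for (it in seq_len(nrow(plan))) {
    test_id <- plan$test_segment_id[it]
    train_all <- feature_matrix[feature_matrix$segment_id %in%
                                  plan$train_segment_ids[[it]], ]
    test <- feature_matrix[feature_matrix$segment_id == test_id, ]
    ev_test <- events[!is.na(events$segment_id) &
                        events$segment_id == test_id, ]
    if (sum(train_all$hypo == 1L) == 0) {
      # holding out the only event-bearing segment leaves nothing to learn
      # from; the iteration is recorded as invalid rather than fitted
      iter_rows[[length(iter_rows) + 1L]] <- tibble::tibble(
        iteration = it, test_segment_id = test_id, seed = NA_integer_,
        valid = FALSE, auroc = NA_real_, threshold = NA_real_,
        sensitivity = NA_real_, specificity = NA_real_)
      next
    }
    for (s in seeds) {
      train <- undersample_majority(train_all, s)
      sc <- standardize(train, test, feature_cols)
      model <- fit_tree_ensemble(sc$train, feature_cols, ...)
      scores <- predict_scores(model, sc$test)
      res <- evaluate_iteration(scores, test, ev_test)
      iter_rows[[length(iter_rows) + 1L]] <- tibble::tibble(
        iteration = it, test_segment_id = test_id, seed = s,
        valid = res$valid, auroc = res$auroc, threshold = res$threshold,
        sensitivity = res$sensitivity, specificity = res$specificity)
      if (nrow(res$detection)) {
        det_rows[[length(det_rows) + 1L]] <-
          dplyr::mutate(res$detection, iteration = it, seed = s)
      }
      ab <- colMeans(abs(feature_attributions(model, sc$test)$contributions))
      attr_rows[[length(attr_rows) + 1L]] <- tibble::tibble(
        iteration = it, seed = s, feature = names(ab), mean_abs = ab)
    }
  }
  structure(list(
    participant_id = participant_id, kind = kind, plan = plan,
    feature_cols = feature_cols,
    iterations = dplyr::bind_rows(iter_rows),
    detection = dplyr::bind_rows(det_rows),
    attributions = dplyr::bind_rows(attr_rows)
  ), class = "hypo_personalized")
}

#' Aggregate a personalized model's iterations into a report row
#'
#' Averages each metric over undersampling seeds within an iteration, then
#' over iterations, so every held-out event segment carries equal weight.
#' Detection rates pool all (event x seed) detection flags.
#'
#' @param fit A `hypo_personalized` object.
#' @return One-row tibble of aggregated metrics.
#' @export
summarise_personalized <- function(fit) {
  per_iter <- fit$iterations |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(dplyr::across(c("auroc", "sensitivity", "specificity"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  det <- fit$detection
  tibble::tibble(
    participant_id = fit$participant_id,
    kind = fit$kind,
    n_iterations = nrow(fit$plan),
    n_events = if (nrow(det)) length(unique(det$event_start)) else 0L,
    auroc = mean(per_iter$auroc),
    sensitivity = mean(per_iter$sensitivity),
    specificity = mean(per_iter$specificity),
    detected_any_rate = if (nrow(det)) mean(det$detected_any) else NA_real_,
    detected_first15_rate = if (nrow(det)) mean(det$detected_first15)
                            else NA_real_
  )
}
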