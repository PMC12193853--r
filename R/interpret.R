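#' Per-row Shapley feature attributions for a fitted model
#'
#' Exact tree-path Shapley values computed by the booster itself
#' (`predcontrib`): for every row, each feature's additive contribution to
#' the model's margin (log-odds) output. Local accuracy holds exactly — the
#' bias plus the per-row contributions reproduce the margin prediction.
#'
#' @param model A `hypo_model` from [fit_tree_ensemble()].
#' @param rows Feature rows to explain (typically an iteration's test rows).
#' @return List with `contributions` (matrix, rows x features), `bias`
#'   (per-row expected margin) and `margin` (reconstructed output).
#' @export
feature_attributions <- function(model, rows) {
  missing_cols <- setdiff(model$feature_cols, names(rows))
  if (length(missing_cols))
    stop("rows lack model features: ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(rows[, model$feature_cols])
  storage.mode(x) <- "double"
  contrib <- stats::predict(model$booster,
                            xgboost::xgb.DMatrix(x, missing = NA),
                            predcontrib = TRUE)
  contrib <- as.matrix(contrib)
  colnames(contrib) <- c(model$feature_cols, "BIAS")
  k <- ncol(contrib)
  list(contributions = contrib[, -k, drop = FALSE],
       bias = contrib[, k],
       margin = rowSums(contrib))
}

#' Map feature names to the reporting categories
#'
#' Cardiac (heart rate and HRV features), activity (step and energy rolling
#' sums), respiratory (blood oxygen saturation, respiratory rate), time
#' (cyclic hour-of-day pair) and manual (time since last meal, insulin on
#' board).
#'
#' @param features Character vector of schema feature names.
#' @return Character vector of categories, same length.
#' @export
feature_categories <- function(features) {
  cat <- dplyr::case_when(
    grepl("^hr_|^hrv_", features) ~ "cardiac",
    grepl("^steps_|^energy_", features) ~ "activity",
    features %in% c("bos_last", "rr_last") ~ "respiratory",
    grepl("^tod_", features) ~ "time",
    features %in% c("time_since_meal", "insulin_on_board") ~ "manual",
    TRUE ~ NA_character_
  )
  if (anyNA(cat))
    stop("unmapped feature(s): ", paste(features[is.na(cat)], collapse = ", "))
  cat
}

#' Relative feature and category importance for one personalized model
#'
#' Mean absolute attributions are averaged over all iterations and
#' undersampling seeds, then normalized to percentages within the model, so
#' the shares sum to 100. Category importance is the sum of its member
#' features' shares.
#'
#' @param fit A `hypo_personalized` object (carries `$attributions`).
#' @return Tibble `feature`, `category`, `importance_pct`.
#' @export
aggregate_importance <- function(fit) {
  by_feature <- fit$attributions |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_abs = mean(.data$mean_abs), .groups = "drop")
  total <- sum(by_feature$mean_abs)
  by_feature |>
    dplyr::mutate(
      category = feature_categories(.data$feature),
      importance_pct = if (total > 0) 100 * .data$mean_abs / total
                       else 100 / dplyr::n()) |>
    dplyr::select("feature", "category", "importance_pct") |>
    dplyr::arrange(dplyr::desc(.data$importance_pct))
}

#' Category-level importance table
#'
#' @param importance Per-feature table from [aggregate_importance()].
#' @return Tibble `category`, `importance_pct`, descending.
#' @export
category_importance <- function(importance) {
  importance |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(importance_pct = sum(.data$importance_pct),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$importance_pct))
}

#' Cohort-average importance across personalized models
#'
#' Per-model percentages are averaged feature-wise across all models of the
#' same diurnal kind (percentage averaging keeps models comparable despite
#' differing attribution scales), then renormalized to sum to 100.
#'
#' @param fits List of `hypo_personalized` objects.
#' @param kind `"day"` or `"night"`.
#' @return Tibble `feature`, `category`, `importance_pct`.
#' @export
cohort_importance <- function(fits, kind) {
  fits <- purrr::keep(fits, ~ .x$kind == kind)
  if (!length(fits)) return(tibble::tibble())
  per_model <- purrr::map_dfr(fits, aggregate_importance, .id = "model")
  per_model |>
    dplyr::group_by(.data$feature, .data$category) |>
    dplyr::summarise(importance_pct = mean(.data$importance_pct),
                     .groups = "drop") |>
    dplyr::mutate(importance_pct = 100 * .data$importance_pct /
                    sum(.data$importance_pct)) |>
    dplyr::arrange(dplyr::desc(.data$importance_pct))
}
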