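#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cohort report into one row per personalized model
#'
#' @param x A `hypowatch_report` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble with participant, diurnal kind, iteration/event counts and
#'   the averaged AUROC, sensitivity, specificity and detection rates.
#' @method tidy hypowatch_report
#' @export
tidy.hypowatch_report <- function(x, ...) {
  x$models
}

#' One-row cohort summary of a report
#'
#' Cohort-level means and SDs over the personalized models, plus event
#' detection rates pooled over every modeled event.
#'
#' @inheritParams tidy.hypowatch_report
#' @return One-row tibble.
#' @method glance hypowatch_report
#' @export
glance.hypowatch_report <- function(x, ...) {
  m <- x$models
  det <- dplyr::bind_rows(purrr::map(x$fits, "detection"))
  tibble::tibble(
    n_models = nrow(m),
    n_day_models = sum(m$kind == "day"),
    n_night_models = sum(m$kind == "night"),
    n_events = sum(m$n_events),
    mean_auroc = mean(m$auroc),
    sd_auroc = stats::sd(m$auroc),
    mean_sensitivity = mean(m$sensitivity),
    mean_specificity = mean(m$specificity),
    detected_any_rate = if (nrow(det)) mean(det$detected_any) else NA_real_,
    detected_first15_rate = if (nrow(det)) mean(det$detected_first15)
                            else NA_real_
  )
}

#' Tidy one personalized model fit
#'
#' @param x A `hypo_personalized` object.
#' @param ... Unused.
#' @return The per-iteration-by-seed metric tibble.
#' @method tidy hypo_personalized
#' @export
tidy.hypo_personalized <- function(x, ...) {
  dplyr::mutate(x$iterations, participant_id = x$participant_id,
                kind = x$kind, .before = 1L)
}

#' @method glance hypo_personalized
#' @export
glance.hypo_personalized <- function(x, ...) {
  summarise_personalized(x)
}

#' @export
print.hypowatch_report <- function(x, ...) {
  g <- glance(x)
  cat("<hypowatch_report>\n")
  cat(sprintf("  %d personalized models (%d day, %d night), %d events\n",
              g$n_models, g$n_day_models, g$n_night_models, g$n_events))
  if (g$n_models > 0) {
    cat(sprintf("  AUROC %.2f +/- %.2f | sens %.2f | spec %.2f\n",
                g$mean_auroc, g$sd_auroc, g$mean_sensitivity,
                g$mean_specificity))
    cat(sprintf("  events detected: %.1f%% any time, %.1f%% in first 15 min\n",
                100 * g$detected_any_rate, 100 * g$detected_first15_rate))
  }
  invisible(x)
}

#' Plot per-model discrimination for a cohort report
#'
#' One point per personalized model (AUROC by participant, colored by
#' diurnal kind) with the cohort mean as a dashed line.
#'
#' @param object A `hypowatch_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hypowatch_report
#' @export
autoplot.hypowatch_report <- function(object, ...) {
  m <- object$models
  ggplot2::ggplot(m, ggplot2::aes(x = .data$participant_id, y = .data$auroc,
                                  color = .data$kind)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = mean(m$auroc), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        color = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "AUROC", color = "Model",
                  title = "Personalized model discrimination") +
    ggplot2::theme_minimal()
}

#' Bar chart of feature-category importance
#'
#' @param report A `hypowatch_report`.
#' @param kind `"day"` or `"night"`.
#' @return A ggplot object.
#' @export
plot_importance <- function(report, kind = "day") {
  imp <- report$importance[[kind]]
  if (!nrow(imp)) stop("no ", kind, " models in this report")
  cat_imp <- category_importance(imp)
  ggplot2::ggplot(cat_imp,
                  ggplot2::aes(x = stats::reorder(.data$category,
                                                  .data$importance_pct),
                               y = .data$importance_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative importance (%)",
                  title = paste("Feature-category importance,", kind,
                                "models")) +
    ggplot2::theme_minimal()
}

#' Plot a labeled glucose trace with detected events
#'
#' Diagnostic view of one participant's glucose column with the labeling
#' threshold and qualifying event spans shaded.
#'
#' @param timeline Labeled timeline (with `hypo`).
#' @param events Event tibble from [hypo_events()].
#' @param threshold Labeling threshold to draw.
#' @return A ggplot object.
#' @export
plot_glucose <- function(timeline, events, threshold = 4) {
  p <- ggplot2::ggplot(timeline, ggplot2::aes(x = .data$time,
                                              y = .data$glucose)) +
    ggplot2::geom_line(color = "grey30", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = NULL, y = "Glucose (mmol/L)") +
    ggplot2::theme_minimal()
  if (nrow(events)) {
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.15)
  }
  p
}
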