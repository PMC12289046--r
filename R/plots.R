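#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-trial metric distributions of a matching experiment
#'
#' Boxplots of the per-trial values of each ranking metric, for the
#' ensemble and (optionally) the strongest single-channel baselines.
#'
#' @param object A `match_experiment`.
#' @param models Model identifiers to show; default: the ensemble plus
#'   the baseline with the best mean HR-30.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot match_experiment
#' @export
autoplot.match_experiment <- function(object, models = NULL, ...) {
  m <- object$metrics
  if (is.null(models)) {
    base <- m |>
      dplyr::filter(.data$model != "ensemble", .data$metric == "hr30") |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(v = mean(.data$value), .groups = "drop") |>
      dplyr::arrange(-.data$v)
    models <- c("ensemble", utils::head(base$model, 1))
  }
  m <- dplyr::filter(m, .data$model %in% models)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$model, y = .data$value,
                                  fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "per-trial score") +
    ggplot2::theme_bw()
}

#' Plot a hit-ratio curve
#'
#' Hit ratio against the cutoff `n` for one evaluation.
#'
#' @param object A `match_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot match_eval
#' @export
autoplot.match_eval <- function(object, ...) {
  df <- tibble::tibble(
    n = as.numeric(sub("^hr", "", names(object$hr))),
    hr = unname(object$hr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$hr)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "cutoff n", y = "hit ratio") +
    ggplot2::theme_bw()
}

#' Plot aggregated permutation importances
#'
#' Mean decline per feature and metric, features ordered by importance.
#'
#' @param object An `importance_report` from [aggregate_importance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot importance_report
#' @export
autoplot.importance_report <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    feature = stats::reorder(.data$feature, .data$mean_importance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_importance,
                                   y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "mean performance decline", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot a feature-ablation report
#'
#' Mean decline (with confidence interval) after removing each feature
#' group, per metric.
#'
#' @param object An `ablation_report` from [feature_ablation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ablation_report
#' @export
autoplot.ablation_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group,
                                       y = .data$decline)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           width = 0.2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "removed feature group",
                  y = "performance decline (full - ablated)") +
    ggplot2::theme_bw()
}
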