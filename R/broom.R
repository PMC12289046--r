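#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ranking evaluation
#'
#' @param x A `match_eval` from [evaluate_ranking()].
#' @param ... Unused.
#' @return Tibble with columns `metric`, `value`.
#' @method tidy match_eval
#' @export
tidy.match_eval <- function(x, ...) {
  vals <- c(x$hr, mrr = x$mrr)
  tibble::tibble(metric = names(vals), value = unname(vals))
}

#' @rdname tidy.match_eval
#' @method glance match_eval
#' @export
glance.match_eval <- function(x, ...) {
  out <- tibble::as_tibble(as.list(c(x$hr, mrr = x$mrr)))
  out$n_sources <- x$n_sources
  out
}

#' Tidy the cross-validation table of a trained match forest
#'
#' @param x A `match_forest` from [tune_and_train()].
#' @param ... Unused.
#' @return The per-grid-point CV tibble (metric is `NA` when the grid had
#'   a single point and CV was skipped).
#' @method tidy match_forest
#' @export
tidy.match_forest <- function(x, ...) x$cv_results

#' @rdname tidy.match_forest
#' @method glance match_forest
#' @export
glance.match_forest <- function(x, ...) {
  dplyr::bind_cols(
    x$params,
    tibble::tibble(selection_metric = x$selection_metric,
                   n_features = length(x$features),
                   oob_error = x$fit$prediction.error))
}

#' Tidy per-trial metrics of a matching experiment
#'
#' @param x A `match_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return Tibble with columns `trial_id`, `model`, `metric`, `value`
#'   (the ensemble plus every single-channel baseline ranker).
#' @method tidy match_experiment
#' @export
tidy.match_experiment <- function(x, ...) x$metrics

#' @rdname tidy.match_experiment
#' @method glance match_experiment
#' @export
glance.match_experiment <- function(x, ...) {
  x$metrics |>
    dplyr::filter(.data$model == "ensemble") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd")) |>
    dplyr::mutate(n_trials = length(x$trials))
}
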