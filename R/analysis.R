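#' Paired t-test comparison of two models across trials
#'
#' Two-sided paired t-test of per-trial metric values, aligned by trial,
#' with the mean difference (`a - b`) and its t-based 95% confidence
#' interval.  When the per-trial differences have zero variance the test
#' statistic is undefined: the comparison is flagged `degenerate`, the
#' p-value is `NA` and the interval collapses to the mean difference.
#'
#' @param a,b Numeric vectors of per-trial scores, same trials in the same
#'   order.
#' @param labels Length-2 character vector naming the two models.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row `paired_comparison` tibble with means, SDs, mean
#'   difference, confidence interval, t statistic, df and p-value.
#' @export
paired_compare <- function(a, b, labels = c("a", "b"), conf_level = 0.95) {
  if (length(a) != length(b)) {
    stop("score vectors differ in length (", length(a), " vs ", length(b),
         ")", call. = FALSE)
  }
  if (length(a) < 2L) stop("need at least 2 paired trials", call. = FALSE)
  d <- a - b
  degenerate <- isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0
  if (degenerate) {
    stat <- NA_real_; p <- NA_real_
    ci <- c(mean(d), mean(d))
  } else {
    tt <- stats::t.test(a, b, paired = TRUE, conf.level = conf_level)
    stat <- unname(tt$statistic); p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  }
  tibble::new_tibble(
    tibble::tibble(
      model_a = labels[1], model_b = labels[2], n = length(a),
      mean_a = mean(a), mean_b = mean(b),
      sd_a = stats::sd(a), sd_b = stats::sd(b),
      mean_diff = mean(d), conf_low = ci[1], conf_high = ci[2],
      statistic = stat, df = length(a) - 1L, p_value = p,
      degenerate = degenerate),
    class = "paired_comparison")
}

#' Compare the ensemble with baseline rankers across trials
#'
#' Convenience wrapper extracting per-trial metric values from a
#' [run_experiment()] result and running [paired_compare()] per metric.
#'
#' @param experiment A `match_experiment`.
#' @param model_a,model_b Model identifiers as they appear in
#'   `experiment$metrics$model` (e.g. `"ensemble"`, `"hash1_on_label"`).
#' @param metrics Metric names (default: all present).
#' @return `paired_comparison` tibble, one row per metric (column
#'   `metric` first).
#' @export
compare_models <- function(experiment, model_a = "ensemble", model_b,
                           metrics = NULL) {
  m <- experiment$metrics
  if (is.null(metrics)) metrics <- unique(m$metric)
  rows <- lapply(metrics, function(mt) {
    av <- extract_metric(m, model_a, mt)
    bv <- extract_metric(m, model_b, mt)
    out <- paired_compare(av, bv, labels = c(model_a, model_b))
    dplyr::bind_cols(tibble::tibble(metric = mt), out)
  })
  dplyr::bind_rows(rows)
}

extract_metric <- function(metrics, model, metric) {
  rows <- metrics[metrics$model == model & metrics$metric == metric, ]
  if (!nrow(rows)) {
    stop("no per-trial values for model '", model, "', metric '", metric,
         "'", call. = FALSE)
  }
  rows$value[order(rows$trial_id)]
}

#' Permutation feature importance on a held-out pair table
#'
#' For each feature, its values are shuffled across the whole held-out
#' pair table (`n_repeats` independent shuffles), the pairs are re-scored
#' and re-ranked, and the importance is the decline
#' `baseline - mean(permuted)` of each ranking metric.  Negative declines
#' are possible (permuting a harmful feature can improve a metric).
#' Permuting a feature the forest never splits on changes nothing, so its
#' importance is exactly 0.
#'
#' @param model A `match_forest`.
#' @param test_tbl Labeled held-out feature table (all candidates per
#'   source, as in the test split of [run_experiment()]).
#' @param metrics Metric names (default `c("hr5", "hr10", "mrr")`).
#' @param n_repeats Shuffles per feature (default 5).
#' @param seed Integer seed.
#' @param features Features to permute (default: the model's features).
#' @return Tibble with columns `feature`, `metric`, `baseline`,
#'   `importance` (the mean decline), `n_repeats`.
#' @export
permutation_importance <- function(model, test_tbl,
                                   metrics = c("hr5", "hr10", "mrr"),
                                   n_repeats = 5L, seed = 1L,
                                   features = NULL) {
  if (is.null(features)) features <- model$features
  unknown <- setdiff(features, model$features)
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cutoffs <- metric_cutoffs(metrics)
  base_eval <- rank_and_eval(test_tbl,
                             predict_prob(model$fit, test_tbl,
                                          model$features), cutoffs)
  baseline <- vapply(metrics, metric_value, numeric(1), eval = base_eval)
  n <- nrow(test_tbl)
  rows <- list()
  for (fi in seq_along(features)) {
    f <- features[fi]
    perm_vals <- matrix(NA_real_, n_repeats, length(metrics))
    for (r in seq_len(n_repeats)) {
      idx <- with_local_seed(derive_seed(seed, fi, r), sample.int(n))
      shuffled <- test_tbl
      shuffled[[f]] <- test_tbl[[f]][idx]
      ev <- rank_and_eval(
        shuffled, predict_prob(model$fit, shuffled, model$features),
        cutoffs)
      perm_vals[r, ] <- vapply(metrics, metric_value, numeric(1),
                               eval = ev)
    }
    rows[[fi]] <- tibble::tibble(
      feature = f, metric = metrics, baseline = unname(baseline),
      importance = unname(baseline) - colMeans(perm_vals),
      n_repeats = n_repeats)
  }
  dplyr::bind_rows(rows)
}

metric_cutoffs <- function(metrics) {
  hr <- metrics[startsWith(metrics, "hr")]
  n <- as.numeric(sub("^hr", "", hr))
  if (length(n) && anyNA(n)) stop("unknown metric name(s): ",
                                  paste(hr[is.na(n)], collapse = ", "),
                                  call. = FALSE)
  if (length(n)) sort(unique(n)) else c(30)
}

#' Permutation importance across every trial of an experiment
#'
#' Runs [permutation_importance()] on each trial's held-out test pairs
#' (the experiment must have been run with `keep_models = TRUE`) and
#' aggregates with [aggregate_importance()].
#'
#' @param experiment A `match_experiment` with kept models.
#' @param metrics,n_repeats,seed,features See [permutation_importance()].
#' @return List with `per_trial` (trial-level declines) and `report`
#'   (the aggregated `importance_report`).
#' @export
experiment_importance <- function(experiment,
                                  metrics = c("hr5", "hr10", "mrr"),
                                  n_repeats = 5L, seed = 1L,
                                  features = NULL) {
  per_trial <- lapply(experiment$trials, function(tr) {
    if (is.null(tr$model)) {
      stop("experiment was run with keep_models = FALSE", call. = FALSE)
    }
    test_tbl <- experiment$pair_matrix[
      experiment$pair_matrix$source_name %in% tr$test_sources, ]
    imp <- permutation_importance(tr$model, test_tbl, metrics, n_repeats,
                                  seed = derive_seed(seed, tr$trial_id),
                                  features = features)
    dplyr::bind_cols(tibble::tibble(trial_id = tr$trial_id), imp)
  })
  per_trial <- dplyr::bind_rows(per_trial)
  list(per_trial = per_trial, report = aggregate_importance(per_trial))
}

#' Aggregate per-trial permutation importances
#'
#' Two complementary views, computed per metric: the mean importance
#' (mean decline over trials) and the mean within-trial rank (features
#' ranked 1..p by decreasing importance inside each trial, ties averaged,
#' then averaged across trials).
#'
#' @param per_trial Tibble with columns `trial_id`, `feature`, `metric`,
#'   `importance` (as produced by [experiment_importance()]).
#' @return An `importance_report` tibble: `metric`, `feature`,
#'   `mean_importance`, `mean_rank`, `n_trials`, sorted by decreasing
#'   mean importance within metric.
#' @export
aggregate_importance <- function(per_trial) {
  stopifnot(nrow(per_trial) > 0L)
  per_trial |>
    dplyr::group_by(.data$trial_id, .data$metric) |>
    dplyr::mutate(rank_in_trial = rank(-.data$importance,
                                       ties.method = "average")) |>
    dplyr::group_by(.data$metric, .data$feature) |>
    dplyr::summarise(mean_importance = mean(.data$importance),
                     mean_rank = mean(.data$rank_in_trial),
                     n_trials = dplyr::n_distinct(.data$trial_id),
                     .groups = "drop") |>
    dplyr::arrange(.data$metric, -.data$mean_importance) |>
    tibble::new_tibble(class = "importance_report")
}

#' Feature-group ablation analysis
#'
#' Re-runs the full experiment once per feature group with that group's
#' columns removed, under the same master seed (hence identical splits,
#' down-sampling and fold draws), and compares the full model with each
#' ablated model by paired t-tests per metric.  Groups must partition the
#' feature set (default: embedding-derived 12, fuzzy-derived 3, other 6).
#'
#' @param experiment A `match_experiment` (its stored configuration and
#'   pair matrix are reused).
#' @param groups Named list of feature-column groups; default
#'   [default_feature_groups()].
#' @param metrics Metrics to compare (default: all recorded).
#' @return An `ablation_report` tibble: per group and metric, the full
#'   model mean, the ablated mean, the mean decline with confidence
#'   interval and the paired p-value.
#' @export
feature_ablation <- function(experiment, groups = NULL, metrics = NULL) {
  cfg <- experiment$config
  pm <- experiment$pair_matrix
  all_features <- cfg$features
  if (is.null(groups)) {
    groups <- default_feature_groups(attr(pm, "methods"))
  }
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, all_features)) {
    stop("feature groups must partition the feature set (",
         length(all_features), " features)", call. = FALSE)
  }
  if (is.null(metrics)) {
    metrics <- unique(experiment$metrics$metric)
  }
  full_vals <- lapply(metrics, function(mt) {
    extract_metric(experiment$metrics, "ensemble", mt)
  })
  names(full_vals) <- metrics
  rows <- list()
  for (g in names(groups)) {
    keep <- setdiff(all_features, groups[[g]])
    if (!length(keep)) {
      stop("group '", g, "' removes every feature", call. = FALSE)
    }
    ab <- run_experiment(
      NULL, NULL, experiment$truth, pair_matrix = pm,
      n_trials = cfg$n_trials, k_negatives = cfg$k_negatives,
      grid = cfg$grid, selection_metric = cfg$selection_metric,
      folds = cfg$folds, cutoffs = cfg$cutoffs,
      master_seed = cfg$master_seed, features = keep,
      baselines = FALSE, permute_labels = cfg$permute_labels,
      keep_models = FALSE)
    for (mt in metrics) {
      abl <- extract_metric(ab$metrics, "ensemble", mt)
      cmp <- paired_compare(full_vals[[mt]], abl,
                            labels = c("full", paste0("w/o ", g)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, metric = mt,
        full_mean = cmp$mean_a, ablated_mean = cmp$mean_b,
        decline = cmp$mean_diff, conf_low = cmp$conf_low,
        conf_high = cmp$conf_high, p_value = cmp$p_value,
        degenerate = cmp$degenerate)
    }
  }
  tibble::new_tibble(dplyr::bind_rows(rows), class = "ablation_report")
}
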