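# run code under a local, restorable RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic per-trial seed from the master seed; kept inside the
# 32-bit signed integer range
derive_seed <- function(master_seed, trial_id, step = 0L) {
  (as.numeric(master_seed) + 1299721 * trial_id + 9973 * step) %%
    2147483629 + 1
}

#' Randomized train/test splits over source variables
#'
#' Splits the matched source variables into training and test sets, by
#' source variable (never by pair), once per trial.  With the default 4:1
#' ratio, `floor(0.8 N)` sources train and the rest test (347 sources give
#' 277/70).  Per-trial seeds are derived deterministically from
#' `master_seed` and the trial id, so the whole experiment is reproducible.
#'
#' @param sources Character vector of matched source variable names.
#' @param n_trials Number of independent splits (default 50).
#' @param train_frac Training fraction (default 0.8, i.e. 4:1).
#' @param master_seed Integer master seed.
#' @return Tibble with columns `trial_id`, `seed`, `train`, `test` (the
#'   last two are list-columns of variable names).
#' @export
make_trial_splits <- function(sources, n_trials = 50L, train_frac = 0.8,
                              master_seed = 1L) {
  sources <- unique(as.character(sources))
  n <- length(sources)
  if (n < 5L) stop("need at least 5 matched sources to split", call. = FALSE)
  n_train <- floor(train_frac * n)
  if (n_train < 1L || n_train >= n) {
    stop("infeasible train/test ratio for ", n, " sources", call. = FALSE)
  }
  rows <- lapply(seq_len(n_trials), function(t) {
    s <- derive_seed(master_seed, t)
    idx <- with_local_seed(s, sample.int(n, n_train))
    list(trial_id = t, seed = s,
         train = sources[sort(idx)], test = sources[-sort(idx)])
  })
  tibble::tibble(
    trial_id = vapply(rows, `[[`, numeric(1), "trial_id"),
    seed = vapply(rows, `[[`, numeric(1), "seed"),
    train = lapply(rows, `[[`, "train"),
    test = lapply(rows, `[[`, "test"))
}

#' Down-sample negative training pairs
#'
#' For each positive training instance (a truth pair whose source is in
#' the training split), `k` target variables that do not match the source
#' are drawn uniformly without replacement to form negative pairs.  All
#' truth targets of the source are excluded from its negative pool (not
#' just the instance's own), and a source's negatives contain no
#' duplicates: a source with `m` positives receives
#' `min(m * k, pool size)` distinct negatives.  Test sets are never
#' down-sampled.
#'
#' @param train_sources Character vector of training source names (or a
#'   one-row slice of [make_trial_splits()]).
#' @param truth A `match_table`.
#' @param target_dict Target `study_dictionary`, or a character vector of
#'   target variable names (the candidate pool).
#' @param k Negatives per positive instance (default 200; 0 gives
#'   positives only).
#' @param seed Integer seed for the draws.
#' @return Tibble with columns `source_name`, `target_name`, `label`;
#'   positives first within each source.  Warns when a pool is smaller
#'   than `m * k` and all of it is taken.
#' @export
downsample_negatives <- function(train_sources, truth, target_dict,
                                 k = 200L, seed = 1L) {
  if (is.data.frame(train_sources)) train_sources <- train_sources$train[[1]]
  if (is.list(train_sources)) train_sources <- unlist(train_sources)
  stopifnot(k >= 0L)
  pos <- truth[truth$source %in% train_sources, ]
  if (!nrow(pos)) stop("no positive instances in the training split",
                       call. = FALSE)
  all_targets <- if (is.data.frame(target_dict)) {
    target_dict$variable_name
  } else {
    as.character(target_dict)
  }
  idx <- truth_index(pos)
  short_pool <- character(0)
  out <- with_local_seed(seed, {
    parts <- lapply(names(idx), function(s) {
      truths <- idx[[s]]
      pool <- setdiff(all_targets, truth_targets(truth, s))
      want <- length(truths) * k
      n_neg <- min(want, length(pool))
      if (n_neg < want) short_pool <<- c(short_pool, s)
      neg <- if (n_neg > 0L) sample(pool, n_neg) else character(0)
      tibble::tibble(
        source_name = s,
        target_name = c(truths, neg),
        label = rep(c(1L, 0L), c(length(truths), length(neg))))
    })
    dplyr::bind_rows(parts)
  })
  if (length(short_pool)) {
    warning("negative pool smaller than requested for source(s): ",
            paste(short_pool, collapse = ", "), "; took the whole pool")
  }
  out
}

# attach features to (source, target, label) pairs from a pair matrix
training_features <- function(pairs, pair_matrix) {
  key_p <- paste(pairs$source_name, pairs$target_name, sep = "\r")
  key_m <- paste(pair_matrix$source_name, pair_matrix$target_name,
                 sep = "\r")
  i <- match(key_p, key_m)
  if (anyNA(i)) {
    stop("pair matrix does not cover ", sum(is.na(i)),
         " training pair(s); build it over all matched sources",
         call. = FALSE)
  }
  out <- pair_matrix[i, ]
  out$label <- pairs$label
  out
}

#' Default random-forest hyperparameter grid
#'
#' Five tuned dimensions: number of trees, maximum tree depth (0 =
#' unbounded), split criterion, minimum node size for a split, and the
#' number of features tried per split (`"sqrt"` for `floor(sqrt(p))`,
#' `"half"` for `floor(p / 2)`).
#'
#' @return Tibble of grid points (row order is the tie-breaking order).
#' @export
rf_default_grid <- function() {
  g <- expand.grid(num_trees = c(100L, 300L, 500L),
                   max_depth = c(0L, 10L, 20L),
                   splitrule = c("gini", "extratrees"),
                   min_node_size = c(2L, 10L),
                   mtry = c("sqrt", "half"),
                   stringsAsFactors = FALSE)
  tibble::as_tibble(g)
}

resolve_mtry <- function(mtry, p) {
  if (is.numeric(mtry)) return(max(1L, min(p, as.integer(mtry))))
  switch(as.character(mtry),
         sqrt = max(1L, floor(sqrt(p))),
         half = max(1L, floor(p / 2)),
         stop("unknown mtry spec: ", mtry, call. = FALSE))
}

fit_forest <- function(data, features, params, seed) {
  ranger::ranger(
    x = as.data.frame(data[features]),
    y = factor(data$label, levels = c(0L, 1L)),
    probability = TRUE,
    num.trees = params$num_trees,
    max.depth = params$max_depth,
    splitrule = params$splitrule,
    min.node.size = params$min_node_size,
    mtry = resolve_mtry(params$mtry, length(features)),
    seed = seed, num.threads = 1L, verbose = FALSE)
}

predict_prob <- function(fit, data, features) {
  p <- stats::predict(fit, data = as.data.frame(data[features]),
                      num.threads = 1L, verbose = FALSE)$predictions
  as.numeric(p[, "1"])
}

# rank a labeled pair table per source by an arbitrary score vector and
# evaluate against its own labels; sources without a positive pair (which
# can occur inside CV folds, e.g. under label permutation) carry no truth
# target and are excluded from the metric
rank_and_eval <- function(tbl, score, cutoffs = c(5, 10, 15, 20, 30)) {
  truth <- as_match_table(
    tbl[tbl$label == 1L, c("source_name", "target_name")])
  ranked <- rank_by_source(tbl, score)
  ranked <- ranked[names(ranked) %in% unique(truth$source)]
  evaluate_ranking(ranked, truth, cutoffs)
}

rank_by_source <- function(tbl, score) {
  srcs <- unique(tbl$source_name)
  out <- lapply(srcs, function(s) {
    i <- tbl$source_name == s
    rank_candidates(stats::setNames(score[i], tbl$target_name[i]))
  })
  names(out) <- srcs
  out
}

#' Tune and train the random-forest match classifier
#'
#' Grid search over [rf_default_grid()] (or any grid) with k-fold
#' cross-validation grouped by source variable: all candidate pairs of a
#' source stay in the same fold, so the validation ranking metric is well
#' defined within each fold and near-duplicate pairs never leak across
#' folds.  For every grid point the mean validation metric (HR-30 or MRR,
#' rankings computed within each fold's own down-sampled candidate sets)
#' is recorded; the best point (ties: first in grid order) is refit on the
#' full training set.  A single-point grid skips cross-validation.
#'
#' @param train_tbl Training feature table (a [build_pair_matrix()] subset
#'   with down-sampled negatives, see [downsample_negatives()]).
#' @param grid Hyperparameter tibble (columns of [rf_default_grid()]).
#' @param selection_metric `"hr30"` or `"mrr"`.
#' @param folds Number of grouped CV folds (default 5).
#' @param seed Integer seed (fold assignment and forest fits).
#' @param features Feature columns; defaults to every column except the
#'   pair identifiers and label.
#' @return A `match_forest` object: the fitted forest, the chosen
#'   hyperparameters, and the per-grid-point CV table.
#' @export
tune_and_train <- function(train_tbl, grid = rf_default_grid(),
                           selection_metric = c("hr30", "mrr"),
                           folds = 5L, seed = 1L, features = NULL) {
  selection_metric <- match.arg(selection_metric)
  if (!nrow(grid)) stop("empty hyperparameter grid", call. = FALSE)
  if (is.null(features)) features <- feature_cols(train_tbl)
  missing <- setdiff(features, names(train_tbl))
  if (length(missing)) {
    stop("training table is missing feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cutoffs <- if (selection_metric == "mrr") c(30) else c(30)
  cv_metric <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1L) {
    fold_of <- assign_grouped_folds(train_tbl, folds, seed)
    for (g in seq_len(nrow(grid))) {
      fold_scores <- vapply(seq_len(folds), function(f) {
        tr <- train_tbl[fold_of != f, ]
        va <- train_tbl[fold_of == f, ]
        fit <- fit_forest(tr, features, grid[g, ],
                          seed = derive_seed(seed, g, f))
        ev <- rank_and_eval(va, predict_prob(fit, va, features), cutoffs)
        metric_value(ev, selection_metric)
      }, numeric(1))
      cv_metric[g] <- mean(fold_scores)
    }
    best <- which.max(cv_metric)
  } else {
    best <- 1L
  }
  fit <- fit_forest(train_tbl, features, grid[best, ], seed = seed)
  structure(
    list(fit = fit, params = grid[best, ],
         cv_results = dplyr::bind_cols(
           grid, tibble::tibble(cv_metric = cv_metric)),
         selection_metric = selection_metric,
         features = features, seed = seed),
    class = "match_forest")
}

# grouped fold assignment; re-draws (up to 10 times) if a fold ends up
# without a positive pair
assign_grouped_folds <- function(train_tbl, folds, seed) {
  srcs <- unique(train_tbl$source_name)
  if (length(srcs) < folds) {
    stop("fewer sources (", length(srcs), ") than folds (", folds, ")",
         call. = FALSE)
  }
  for (attempt in seq_len(10L)) {
    perm <- with_local_seed(derive_seed(seed, 0L, attempt),
                            sample(srcs))
    fold_src <- stats::setNames(rep_len(seq_len(folds), length(perm)), perm)
    fold_of <- unname(fold_src[train_tbl$source_name])
    pos_per_fold <- tapply(train_tbl$label, fold_of, sum)
    if (length(pos_per_fold) == folds && all(pos_per_fold > 0)) {
      return(fold_of)
    }
  }
  stop("could not build ", folds,
       " grouped folds with positives in every fold", call. = FALSE)
}

#' @export
print.match_forest <- function(x, ...) {
  cat("# Random-forest match classifier (selected by ",
      x$selection_metric, ")\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Score and rank candidate pairs with a trained model
#'
#' Predicts the positive-class probability of every pair and ranks each
#' source's candidates by it with median-rank tie resolution (probability
#' ties are never broken by target order).
#'
#' @param model A `match_forest`.
#' @param pair_tbl Feature table covering the pairs to rank (the feature
#'   columns must match the training schema).
#' @return Named list of [rank_candidates()] tibbles, one per source, with
#'   the probability table in `attr(, "probabilities")`.
#' @export
predict_and_rank <- function(model, pair_tbl) {
  missing <- setdiff(model$features, names(pair_tbl))
  if (length(missing)) {
    stop("pair table is missing model feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prob <- predict_prob(model$fit, pair_tbl, model$features)
  ranked <- rank_by_source(pair_tbl, prob)
  attr(ranked, "probabilities") <- tibble::tibble(
    source_name = pair_tbl$source_name,
    target_name = pair_tbl$target_name,
    prob = prob)
  ranked
}

#' Run the full repeated-trial matching experiment
#'
#' The complete ensemble protocol: the matched source variables are split
#' into training and test sets (4:1) once per trial; training negatives
#' are down-sampled to `k_negatives` per positive; the forest is tuned by
#' grouped cross-validated grid search and refit; the test set keeps every
#' negative (the full candidate list per test source) and is ranked by the
#' predicted match probability; hit ratios and MRR are recorded per trial
#' for the ensemble and, optionally, for each similarity feature used
#' alone as a baseline ranker.
#'
#' @param source_dict,target_dict The two study dictionaries.
#' @param truth A `match_table` of curated alignments.
#' @param backends Embedding backends (default [default_backends()]).
#' @param pair_matrix Optional precomputed [build_pair_matrix()] table
#'   covering all matched sources (built on demand otherwise).
#' @param n_trials Number of randomized trials (default 50).
#' @param k_negatives Negatives per positive instance (default 200; capped
#'   at the available pool).
#' @param grid Hyperparameter grid (default [rf_default_grid()]).
#' @param selection_metric `"hr30"` or `"mrr"`.
#' @param folds Grouped CV folds (default 5).
#' @param cutoffs Hit-ratio cutoffs for evaluation.
#' @param master_seed Integer seed controlling every random draw.
#' @param features Feature columns to train on (default: all 21).
#' @param baselines Also evaluate every similarity feature as a
#'   single-channel ranker (default TRUE).
#' @param permute_labels Permute training labels within each trial
#'   (negative control; test labels are untouched).
#' @param keep_models Retain each trial's fitted model (needed for
#'   [experiment_importance()]).
#' @return A `match_experiment` object with elements `trials` (per-trial
#'   results incl. predictions), `metrics` (tidy per-trial metric table),
#'   `splits`, `pair_matrix`, `truth` and `config`.
#' @export
run_experiment <- function(source_dict, target_dict, truth,
                           backends = default_backends(),
                           pair_matrix = NULL,
                           n_trials = 50L, k_negatives = 200L,
                           grid = rf_default_grid(),
                           selection_metric = "hr30", folds = 5L,
                           cutoffs = c(5, 10, 15, 20, 30),
                           master_seed = 1L, features = NULL,
                           baselines = TRUE, permute_labels = FALSE,
                           keep_models = FALSE) {
  if (is.null(truth) || !nrow(truth)) {
    stop("no matched sources: the match table is empty", call. = FALSE)
  }
  if (is.null(pair_matrix)) {
    pair_matrix <- build_pair_matrix(source_dict, target_dict, truth,
                                     backends = backends)
  }
  if (is.null(features)) features <- feature_cols(pair_matrix)
  target_pool <- if (!is.null(target_dict)) {
    target_dict$variable_name
  } else {
    unique(pair_matrix$target_name)
  }
  matched <- intersect(unique(truth$source),
                       unique(pair_matrix$source_name))
  if (!length(matched)) {
    stop("no matched sources covered by the pair matrix", call. = FALSE)
  }
  splits <- make_trial_splits(matched, n_trials = n_trials,
                              master_seed = master_seed)
  sim_features <- intersect(
    similarity_feature_names(attr(pair_matrix, "methods") %||%
                               character(0)),
    names(pair_matrix))
  trials <- vector("list", n_trials)
  metric_rows <- list()
  for (t in seq_len(n_trials)) {
    res <- tryCatch(
      run_one_trial(splits[t, ], pair_matrix, truth, target_pool,
                    k_negatives, grid, selection_metric, folds, cutoffs,
                    master_seed, features, baselines && length(sim_features),
                    sim_features, permute_labels, keep_models),
      error = function(e) {
        stop("trial ", t, ": ", conditionMessage(e), call. = FALSE)
      })
    trials[[t]] <- res
    metric_rows[[t]] <- res$metric_rows
  }
  metrics <- dplyr::bind_rows(metric_rows)
  structure(
    list(trials = trials, metrics = metrics, splits = splits,
         pair_matrix = pair_matrix, truth = truth,
         config = list(n_trials = n_trials, k_negatives = k_negatives,
                       grid = grid, selection_metric = selection_metric,
                       folds = folds, cutoffs = cutoffs,
                       master_seed = master_seed, features = features,
                       baselines = baselines,
                       permute_labels = permute_labels,
                       keep_models = keep_models)),
    class = "match_experiment")
}

run_one_trial <- function(split, pair_matrix, truth, target_dict,
                          k_negatives, grid, selection_metric, folds,
                          cutoffs, master_seed, features, baselines,
                          sim_features, permute_labels, keep_models) {
  t <- split$trial_id
  train_sources <- split$train[[1]]
  test_sources <- split$test[[1]]
  pairs <- downsample_negatives(train_sources, truth, target_dict,
                                k = k_negatives,
                                seed = derive_seed(master_seed, t, 1L))
  train_tbl <- training_features(pairs, pair_matrix)
  if (permute_labels) {
    train_tbl$label <- with_local_seed(
      derive_seed(master_seed, t, 3L),
      sample(train_tbl$label))
  }
  model <- tune_and_train(train_tbl, grid, selection_metric, folds,
                          seed = derive_seed(master_seed, t, 2L),
                          features = features)
  test_tbl <- pair_matrix[pair_matrix$source_name %in% test_sources, ]
  ranked <- predict_and_rank(model, test_tbl)
  eval <- evaluate_ranking(ranked, truth, cutoffs)
  rows <- list(eval_metric_rows(t, "ensemble", eval))
  baseline_evals <- list()
  if (baselines) {
    for (f in sim_features) {
      ev <- local({
        rk <- rank_by_source(test_tbl, test_tbl[[f]])
        evaluate_ranking(rk, truth, cutoffs)
      })
      baseline_evals[[f]] <- ev
      rows[[length(rows) + 1L]] <- eval_metric_rows(t, f, ev)
    }
  }
  list(trial_id = t, seed = split$seed,
       train_sources = train_sources, test_sources = test_sources,
       n_train_positive = sum(train_tbl$label == 1L),
       n_train_negative = sum(train_tbl$label == 0L),
       model = if (keep_models) model else NULL,
       params = model$params,
       eval = eval, baseline_evals = baseline_evals,
       predictions = attr(ranked, "probabilities"),
       metric_rows = dplyr::bind_rows(rows))
}

eval_metric_rows <- function(trial_id, model, eval) {
  vals <- c(eval$hr, mrr = eval$mrr)
  tibble::tibble(trial_id = trial_id, model = model,
                 metric = names(vals), value = unname(vals))
}

#' @export
print.match_experiment <- function(x, ...) {
  cat("# Matching experiment:", length(x$trials), "trial(s)\n")
  sm <- x$metrics |>
    dplyr::filter(.data$model == "ensemble") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  print(sm)
  invisible(x)
}
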