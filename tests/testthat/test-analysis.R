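test_that("paired comparisons follow the textbook t formulas", {
  a <- c(0.9, 0.8, 0.85, 0.95)
  cmp <- paired_compare(a, a)
  expect_equal(cmp$mean_diff, 0)
  expect_true(cmp$degenerate)
  expect_true(is.na(cmp$p_value))
  # constant offset: degenerate variance, zero-width interval
  cmp2 <- paired_compare(a + 0.1, a)
  expect_equal(cmp2$mean_diff, 0.1, tolerance = 1e-12)
  expect_equal(cmp2$conf_low, cmp2$conf_high)
  expect_true(cmp2$degenerate)
  # seeded Gaussian samples vs a hand computation
  set.seed(33)
  x <- rnorm(20, 0.8, 0.05); y <- rnorm(20, 0.75, 0.05)
  cmp3 <- paired_compare(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(20))
  p_hand <- 2 * pt(-abs(t_hand), df = 19)
  expect_equal(cmp3$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp3$p_value, p_hand, tolerance = 1e-12)
  half <- qt(0.975, 19) * sd(d) / sqrt(20)
  expect_equal(c(cmp3$conf_low, cmp3$conf_high),
               mean(d) + c(-half, half), tolerance = 1e-12)
  expect_true(cmp3$conf_low <= cmp3$mean_diff &
                cmp3$mean_diff <= cmp3$conf_high)
  expect_error(paired_compare(x, y[1:5]), "length")
})

test_that("permutation importance isolates the feature the model uses", {
  corp <- tiny_corpus()
  pm <- corp$pair_matrix
  pm$planted <- as.numeric(pm$label)
  pm$pure_noise <- with_seed_vec(99, nrow(pm))
  # held-out evaluation: train and permute on disjoint source groups so
  # the forest cannot score by memorizing the noise column
  srcs <- unique(pm$source_name)
  train_tbl <- pm[pm$source_name %in% srcs[1:7], ]
  test_tbl <- pm[!pm$source_name %in% srcs[1:7], ]
  model <- tune_and_train(train_tbl, grid = standard_grid(), seed = 3,
                          features = c("planted", "pure_noise"))
  imp <- permutation_importance(model, test_tbl,
                                metrics = c("hr10", "mrr"),
                                n_repeats = 3, seed = 12)
  sig <- imp[imp$feature == "planted" & imp$metric == "hr10", ]
  noi <- imp[imp$feature == "pure_noise" & imp$metric == "hr10", ]
  expect_gt(sig$importance, 0.3)
  expect_lt(abs(noi$importance), 0.05)
  # constant column: permuting changes nothing at all
  pmc <- pm
  pmc$constant <- 1
  mc <- tune_and_train(pmc, grid = standard_grid(), seed = 3,
                       features = c("planted", "constant"))
  impc <- permutation_importance(mc, pmc, metrics = "hr10", n_repeats = 2,
                                 seed = 5, features = "constant")
  expect_equal(impc$importance, 0)
  # bit-reproducible under a fixed seed
  imp2 <- permutation_importance(model, test_tbl,
                                 metrics = c("hr10", "mrr"),
                                 n_repeats = 3, seed = 12)
  expect_identical(imp, imp2)
  expect_error(
    permutation_importance(model, test_tbl, features = "nope"), "nope")
})

test_that("importance aggregation averages declines and within-trial ranks", {
  per_trial <- tibble::tibble(
    trial_id = c(1, 1, 2, 2),
    feature = c("f1", "f2", "f1", "f2"),
    metric = "hr10",
    importance = c(0.03, 0.01, 0.05, 0.20))
  rep <- aggregate_importance(per_trial)
  f1 <- rep[rep$feature == "f1", ]
  expect_equal(f1$mean_importance, 0.04)   # mean of {0.03, 0.05}
  expect_equal(f1$mean_rank, 1.5)          # ranks {1, 2}
  # single trial: aggregate equals the trial itself
  one <- aggregate_importance(per_trial[per_trial$trial_id == 1, ])
  expect_equal(one$mean_importance,
               c(0.03, 0.01)[match(one$feature, c("f1", "f2"))])
  expect_equal(sort(one$mean_rank), c(1, 2))
})

test_that("feature ablation reruns trials and flags the signal group", {
  corp <- tiny_corpus()
  # plant the signal in the embedding group only: scramble the fuzzy
  # channels into pure noise so removing them is harmless while removing
  # the embedding channels is not
  pm <- corp$pair_matrix
  set.seed(404)
  for (f in similarity_feature_names("fuzzy")) pm[[f]] <- sample(pm[[f]])
  ex <- run_experiment(corp$source, corp$target, corp$truth,
                       pair_matrix = pm, n_trials = 3L,
                       k_negatives = 12L, grid = standard_grid(),
                       master_seed = 5L, baselines = FALSE)
  fc <- feature_cols(pm)
  groups <- default_feature_groups(attr(pm, "methods"))
  expect_equal(lengths(groups), c(llm = 12L, fuzzy = 3L, other = 6L))
  ab <- feature_ablation(ex, groups, metrics = "mrr")
  expect_setequal(unique(ab$group), names(groups))
  llm <- ab[ab$group == "llm", ]
  fuz <- ab[ab$group == "fuzzy", ]
  expect_gt(llm$decline, 0)
  expect_lt(abs(fuz$decline), abs(llm$decline))
  # the noise group's decline interval straddles zero
  expect_true(fuz$degenerate ||
                (fuz$conf_low <= 0 + 0.05 && fuz$conf_high >= 0 - 0.05))
  # groups must partition the features
  expect_error(feature_ablation(ex, list(a = fc[1:3])), "partition")
  expect_error(feature_ablation(ex, list(all = fc)), "every feature")
})

test_that("model comparison extracts aligned per-trial vectors", {
  corp <- tiny_corpus()
  ex <- run_experiment(corp$source, corp$target, corp$truth,
                       pair_matrix = corp$pair_matrix, n_trials = 2L,
                       k_negatives = 12L, grid = standard_grid(),
                       master_seed = 6L)
  cmp <- compare_models(ex, "ensemble", "hash1_on_label",
                        metrics = c("hr30", "mrr"))
  expect_equal(nrow(cmp), 2L)
  expect_identical(cmp$model_a, rep("ensemble", 2))
  expect_equal(cmp$n, rep(2L, 2))
  expect_error(compare_models(ex, "ensemble", "not_a_model"),
               "not_a_model")
})
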