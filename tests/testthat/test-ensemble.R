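test_that("trial splits partition sources 4:1 by source variable", {
  sources <- paste0("S", 1:347)
  sp <- make_trial_splits(sources, n_trials = 3, master_seed = 9)
  for (i in 1:3) {
    tr <- sp$train[[i]]; te <- sp$test[[i]]
    expect_length(tr, 277L)   # floor(0.8 * 347)
    expect_length(te, 70L)
    expect_length(intersect(tr, te), 0L)
    expect_setequal(c(tr, te), sources)
  }
  # determinism under the master seed
  sp2 <- make_trial_splits(sources, n_trials = 3, master_seed = 9)
  expect_identical(sp, sp2)
  sp3 <- make_trial_splits(paste0("S", 1:10), n_trials = 3, master_seed = 1)
  expect_length(sp3$train[[2]], 8L)
  expect_length(sp3$test[[2]], 2L)
  expect_error(make_trial_splits(paste0("S", 1:4)), "at least 5")
})

test_that("negative down-sampling respects truth exclusions and pool caps", {
  tgt <- make_dict(paste0("T", 1:10), paste("Label", 1:10), study = "T")
  truth <- as_match_table(tibble::tibble(source = "A", target = "T1"))
  ds <- downsample_negatives("A", truth, tgt, k = 5, seed = 2)
  expect_equal(sum(ds$label == 0L), 5L)
  expect_false("T1" %in% ds$target_name[ds$label == 0L])
  expect_false(anyDuplicated(ds$target_name) > 0)
  # k = 0: positives only
  ds0 <- downsample_negatives("A", truth, tgt, k = 0, seed = 2)
  expect_identical(ds0$label, 1L)
  # multi-match source: all truth targets excluded, pool cap warning
  truth2 <- as_match_table(tibble::tibble(
    source = c("A", "A"), target = c("T1", "T2")))
  expect_warning(
    ds2 <- downsample_negatives("A", truth2, tgt, k = 5, seed = 2),
    "pool")
  neg2 <- ds2$target_name[ds2$label == 0L]
  expect_length(neg2, 8L)  # pool of 10 - 2 truths, want 2*5
  expect_length(intersect(neg2, c("T1", "T2")), 0L)
  expect_false(anyDuplicated(neg2) > 0)
})

test_that("grid search picks the CV argmax and single-point grids skip CV", {
  corp <- tiny_corpus()
  pairs <- suppressWarnings(
    downsample_negatives(unique(corp$truth$source)[1:10],
                         corp$truth, corp$target, k = 15, seed = 4))
  train <- corp$pair_matrix[
    paste(corp$pair_matrix$source_name, corp$pair_matrix$target_name) %in%
      paste(pairs$source_name, pairs$target_name), ]
  train$label <- pairs$label[match(
    paste(train$source_name, train$target_name),
    paste(pairs$source_name, pairs$target_name))]
  one <- tune_and_train(train, grid = standard_grid(), seed = 5)
  expect_true(all(is.na(one$cv_results$cv_metric)))
  expect_identical(one$params$num_trees, 300L)
  grid2 <- dplyr::bind_rows(standard_grid(),
                            dplyr::mutate(standard_grid(), num_trees = 50L))
  m2 <- tune_and_train(train, grid = grid2, folds = 3, seed = 5)
  cv <- m2$cv_results$cv_metric
  expect_length(cv, 2L)
  expect_false(anyNA(cv))
  expect_identical(m2$params$num_trees,
                   grid2$num_trees[which.max(cv)])
  expect_error(tune_and_train(train, grid = grid2[0, ]), "empty")
})

test_that("prediction ranks by match probability with schema checks", {
  # perfectly separable data (single-match truth): a feature equal to the
  # label must put every truth target at rank 1
  gen <- generate_paired_dictionaries(
    synth_config(n_source = 10, n_target = 30, multi_match_rate = 0,
                 seed = 3))
  pm <- build_pair_matrix(gen$source, gen$target, gen$truth,
                          backends = list(tiny_backend()))
  pm$planted <- as.numeric(pm$label)
  model <- tune_and_train(pm, grid = standard_grid(), seed = 1,
                          features = "planted")
  ranked <- predict_and_rank(model, pm)
  ev <- evaluate_ranking(ranked, gen$truth, cutoffs = c(1, 5))
  expect_equal(unname(ev$hr["hr1"]), 1)  # every truth target at rank 1
  expect_error(predict_and_rank(model, pm[, setdiff(names(pm), "planted")]),
               "planted")
  corp <- tiny_corpus()
  srcs <- unique(corp$truth$source)
  model <- tune_and_train(corp$pair_matrix, grid = standard_grid(),
                          seed = 1,
                          features = c("hash1_on_label", "Label_len_src"))
  pm <- corp$pair_matrix
  # all-identical feature rows: total tie, every rank (N+1)/2
  flat <- pm[pm$source_name == srcs[1], ]
  flat$hash1_on_label <- 0.5
  flat$Label_len_src <- 1
  rk <- predict_and_rank(model, flat)[[1]]
  expect_true(all(rk$rank == (nrow(flat) + 1) / 2))
})

test_that("the experiment loop is reproducible and leak-free", {
  corp <- tiny_corpus()
  args <- list(source_dict = corp$source, target_dict = corp$target,
               truth = corp$truth, pair_matrix = corp$pair_matrix,
               n_trials = 2L, k_negatives = 12L, grid = standard_grid(),
               master_seed = 77L)
  ex1 <- do.call(run_experiment, args)
  ex2 <- do.call(run_experiment, args)
  expect_identical(ex1$metrics, ex2$metrics)
  expect_identical(ex1$trials[[1]]$predictions, ex2$trials[[1]]$predictions)
  for (tr in ex1$trials) {
    expect_length(intersect(tr$train_sources, tr$test_sources), 0L)
    # test predictions never involve training sources
    expect_false(any(tr$predictions$source_name %in% tr$train_sources))
    # one full ranked list per test source
    expect_equal(nrow(tr$predictions),
                 length(tr$test_sources) * nrow(corp$target))
  }
  # per-trial metrics cover the ensemble and all 15 baselines
  expect_setequal(unique(ex1$metrics$model),
                  c("ensemble",
                    similarity_feature_names(c(paste0("hash", 1:4),
                                               "fuzzy"))))
  empty <- corp$truth[0, ]
  expect_error(
    run_experiment(corp$source, corp$target, empty,
                   pair_matrix = corp$pair_matrix), "no matched sources")
})
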