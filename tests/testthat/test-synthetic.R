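test_that("the generator is fully determined by its seed", {
  cfg <- synth_config(n_source = 20, n_target = 60, seed = 7)
  g1 <- generate_paired_dictionaries(cfg)
  g2 <- generate_paired_dictionaries(cfg)
  expect_identical(g1, g2)
  g3 <- generate_paired_dictionaries(
    synth_config(n_source = 20, n_target = 60, seed = 8))
  expect_false(identical(g1$source$variable_label,
                         g3$source$variable_label))
})

test_that("ground truth is consistent and multi-match counts are exact", {
  g <- generate_paired_dictionaries(
    synth_config(n_source = 50, n_target = 160, multi_match_rate = 0.2,
                 seed = 13))
  expect_true(all(g$truth$source %in% g$source$variable_name))
  expect_true(all(g$truth$target %in% g$target$variable_name))
  cnt <- match_counts(g$truth)
  expect_equal(cnt$n_sources, 50L)       # match_rate = 1
  expect_equal(cnt$n_multi, 10L)         # round(0.2 * 50)
  expect_equal(nrow(g$target), 160L)
  # no truth pair links two distractors: every truth target's concept is
  # a source concept, and distractor names never appear in the truth
  expect_lt(cnt$n_pairs, nrow(g$target))
})

test_that("label lengths calibrate to the configured means", {
  g <- generate_paired_dictionaries(synth_config(seed = 7))
  m_src <- mean(count_words(g$source$variable_label))
  m_tgt <- mean(count_words(g$target$variable_label))
  expect_lt(abs(m_src - 11.3) / 11.3, 0.2)
  expect_lt(abs(m_tgt - 8.5) / 8.5, 0.2)
  # rule missingness near the configured rates
  expect_lt(abs(mean(!nzchar(g$source$derivation_rule)) - 0.726), 0.15)
  expect_lt(abs(mean(!nzchar(g$target$derivation_rule)) - 0.115), 0.15)
})

test_that("zero noise with equal label lengths gives identical labels", {
  cfg <- synth_config(
    n_source = 15, n_target = 40, match_rate = 1, multi_match_rate = 0,
    label_noise = list(synonym = 0, drop = 0, shuffle = 0, abbrev = 0),
    label_words = list(src = 6, tgt = 6), seed = 21)
  g <- generate_paired_dictionaries(cfg)
  src_lab <- g$source$variable_label[
    match(g$truth$source, g$source$variable_name)]
  tgt_lab <- g$target$variable_label[
    match(g$truth$target, g$target$variable_name)]
  expect_identical(src_lab, tgt_lab)
  # fuzzy-only ranking on labels recovers every match at rank 1
  pm <- build_pair_matrix(g$source, g$target, g$truth,
                          backends = list(tiny_backend()))
  rk <- lapply(split(pm, pm$source_name), function(d) {
    rank_candidates(stats::setNames(d$fuzzy_on_label, d$target_name))
  })
  expect_equal(hit_ratio(rk, g$truth, 1), 1)
})

test_that("heavier label noise degrades fuzzy-only matching on average", {
  hr10_at <- function(noise, seed) {
    cfg <- synth_config(n_source = 15, n_target = 50,
                        label_noise = noise, seed = seed)
    g <- generate_paired_dictionaries(cfg)
    pm <- build_pair_matrix(g$source, g$target, g$truth,
                            backends = list(tiny_backend()))
    rk <- lapply(split(pm, pm$source_name), function(d) {
      rank_candidates(stats::setNames(d$fuzzy_on_label, d$target_name))
    })
    hit_ratio(rk, g$truth, 10)
  }
  low <- list(synonym = 0.02, drop = 0.02, shuffle = 0.02, abbrev = 0.05)
  high <- list(synonym = 0.6, drop = 0.4, shuffle = 0.6, abbrev = 0.8)
  seeds <- 1:10
  hr_low <- vapply(seeds, function(s) hr10_at(low, s), numeric(1))
  hr_high <- vapply(seeds, function(s) hr10_at(high, s), numeric(1))
  expect_gt(mean(hr_low), mean(hr_high))
})

test_that("the long-format sheet round-trips through the wide transform", {
  cfg <- synth_config(seed = 5)
  lf <- generate_long_format_sheet(cfg, n_questions = 11)
  wide <- long_to_wide(lf$source, lf$data_rows, lf$spec)
  expect_equal(nrow(wide), 11L)  # 2 records out, 11 in
  expect_setequal(wide$variable_name, lf$truth$source)
  truth <- as_match_table(lf$truth, wide, lf$target)
  pm <- build_pair_matrix(wide, lf$target, truth,
                          backends = list(tiny_backend()))
  rk <- lapply(split(pm, pm$source_name), function(d) {
    rank_candidates(stats::setNames(d$fuzzy_on_label, d$target_name))
  })
  expect_equal(hit_ratio(rk, truth, 1), 1)
  one <- generate_long_format_sheet(cfg, n_questions = 1)
  expect_equal(nrow(long_to_wide(one$source, one$data_rows, one$spec)), 1L)
})
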