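write_dict_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, na = "")
  path
}

base_rows <- function() {
  tibble::tibble(
    study_id = "studyA",
    sheet_name = c("DM", "DM", "VS", "VS", "QS", "QS"),
    sheet_description = c(rep("Demographics", 2), rep("Vitals", 2),
                          rep("Questionnaire items", 2)),
    variable_name = c("SEX", "AGE", "BMI", "SBP", "Q1", "Q2"),
    variable_label = c("Sex", "Age in years", "Body mass index",
                       "Systolic blood pressure", "Question one score",
                       "Question two score"),
    derivation_rule = c("coded 1 male 2 female", "", "weight over height",
                        "", "item score 0 to 3", ""))
}

test_that("a well-formed dictionary file loads with empty rules preserved", {
  path <- write_dict_csv(base_rows())
  d <- read_dictionary(path)
  expect_s3_class(d, "study_dictionary")
  expect_equal(nrow(d), 6L)
  expect_identical(d$variable_name, base_rows()$variable_name)  # file order
  expect_identical(d$derivation_rule[2], "")
  b <- add_text_bundles(d)
  expect_true(b$rule_absent[2])
  expect_false(b$rule_absent[1])
})

test_that("schema and validation errors name the offending columns/variables", {
  rows <- base_rows()
  expect_error(read_dictionary(write_dict_csv(rows[-4])),
               "variable_name")
  dup <- rows
  dup$variable_name[2] <- "SEX"
  expect_error(read_dictionary(write_dict_csv(dup)), "SEX")
  blank <- rows
  blank$variable_label[3] <- ""
  expect_error(read_dictionary(write_dict_csv(blank)), "BMI")
})

test_that("write/read round-trip is field-identical", {
  d <- read_dictionary(write_dict_csv(base_rows()))
  path2 <- tempfile(fileext = ".csv")
  write_dictionary(d, path2)
  d2 <- read_dictionary(path2)
  expect_identical(as.data.frame(d), as.data.frame(d2))
})

test_that("match tables count pairs, unique sources and multi-matches", {
  src <- make_dict(c("A", "B"), c("Label a", "Label b"))
  tgt <- make_dict(c("X", "Y", "Z"), c("Label x", "Label y", "Label z"))
  mt <- as_match_table(
    tibble::tibble(source = c("A", "A", "B"), target = c("X", "Y", "Z")),
    src, tgt)
  cnt <- match_counts(mt)
  expect_equal(cnt$n_pairs, 3L)
  expect_equal(cnt$n_sources, 2L)
  expect_equal(cnt$n_multi, 1L)
  expect_error(
    as_match_table(tibble::tibble(source = "A", target = "Q99"), src, tgt),
    "Q99")
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(source = c("A", "B"),
                                  target = c("X", "Z")), path)
  expect_equal(nrow(read_match_table(path, src, tgt)), 2L)
})

test_that("long-to-wide replaces the key/value pair with per-question records", {
  d <- make_dict(c("MMSEQSNUM", "MMSERN", "AGE"),
                 c("MMSE question number", "MMSE item result numeric",
                   "Age in years"),
                 sheet = "QS")
  spec <- long_format_spec("QS", "MMSEQSNUM", "MMSERN",
                           "MMSE item result numeric question {key}")
  rows <- tibble::tibble(MMSEQSNUM = c(1, 2, 1, 2), MMSERN = c(3, 2, 1, 0))
  w <- long_to_wide(d, rows, spec)
  expect_identical(w$variable_name, c("MMSERN_1", "MMSERN_2", "AGE"))
  expect_identical(w$variable_label[1],
                   "MMSE item result numeric question 1")
  # count bookkeeping: |records| - 2 + |distinct keys|
  rows3 <- tibble::tibble(MMSEQSNUM = c(7, 8, 9), MMSERN = 0)
  w3 <- long_to_wide(d, rows3, spec)
  expect_equal(nrow(w3), nrow(d) - 2L + 3L)
  # untouched records keep their fields
  expect_identical(w3[w3$variable_name == "AGE", ],
                   d[d$variable_name == "AGE", ])
})

test_that("long-to-wide handles empty sheets, reapplication and odd keys", {
  d <- make_dict(c("QSNUM", "RN", "AGE"),
                 c("Question number", "Item result", "Age in years"),
                 sheet = "QS")
  spec <- long_format_spec("QS", "QSNUM", "RN", "Item result {key}")
  empty <- tibble::tibble(QSNUM = numeric(0), RN = numeric(0))
  expect_warning(w0 <- long_to_wide(d, empty, spec), "unchanged")
  expect_identical(as.data.frame(w0), as.data.frame(d))
  w <- long_to_wide(d, tibble::tibble(QSNUM = 1:2, RN = 0), spec)
  # idempotent once the pair is gone
  expect_warning(w2 <- long_to_wide(w, tibble::tibble(QSNUM = 1, RN = 0),
                                    spec), "not found")
  expect_identical(as.data.frame(w2), as.data.frame(w))
  # separator characters in keys are sanitized
  odd <- tibble::tibble(QSNUM = c("a_1", "b"), RN = 0)
  expect_warning(wo <- long_to_wide(d, odd, spec), "sanitized")
  expect_true("RN_a-1" %in% wo$variable_name)
})
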