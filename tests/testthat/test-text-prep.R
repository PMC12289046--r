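test_that("the stemmer reproduces canonical Porter behaviour", {
  pairs <- c(
    caresses = "caress", ponies = "poni", ties = "ti", cats = "cat",
    feed = "feed", agreed = "agre", plastered = "plaster",
    motoring = "motor", sing = "sing", conflated = "conflat",
    troubled = "troubl", sized = "size", hopping = "hop",
    falling = "fall", hissing = "hiss", filing = "file",
    happy = "happi", sky = "sky", relational = "relat",
    conditional = "condit", rational = "ration", valenci = "valenc",
    hesitanci = "hesit", digitizer = "digit", conformabli = "conform",
    radicalli = "radic", differentli = "differ", vileli = "vile",
    analogousli = "analog", vietnamization = "vietnam",
    predication = "predic", operator = "oper", feudalism = "feudal",
    decisiveness = "decis", hopefulness = "hope",
    callousness = "callous", formaliti = "formal",
    sensitiviti = "sensit", sensibiliti = "sensibl",
    triplicate = "triplic", formative = "form", formalize = "formal",
    electriciti = "electr", electrical = "electr", hopeful = "hope",
    goodness = "good", revival = "reviv", allowance = "allow",
    inference = "infer", airliner = "airlin", gyroscopic = "gyroscop",
    adjustable = "adjust", defensible = "defens", irritant = "irrit",
    replacement = "replac", adjustment = "adjust", dependent = "depend",
    adoption = "adopt", communism = "commun", activate = "activ",
    angulariti = "angular", homologous = "homolog",
    effective = "effect", bowdlerize = "bowdler", probate = "probat",
    rate = "rate", cease = "ceas", controll = "control", roll = "roll",
    body = "bodi", baseline = "baselin")
  expect_identical(porter_stem(names(pairs)), unname(pairs))
})

test_that("fuzzy normalization lowercases, strips, de-stops and stems", {
  expect_identical(normalize_for_fuzzy("Body Mass Index (BMI) at Baseline"),
                   "bodi mass index bmi baselin")
  expect_identical(normalize_for_fuzzy(""), "")
  expect_identical(normalize_for_fuzzy("The of and"), "")
  # idempotence on a spread of generated labels
  gen <- generate_paired_dictionaries(
    synth_config(n_source = 10, n_target = 25, seed = 3))
  labs <- c(gen$source$variable_label, gen$target$variable_label)
  once <- normalize_for_fuzzy(labs)
  expect_identical(normalize_for_fuzzy(once), once)
})

test_that("word counting follows whitespace tokens", {
  expect_equal(count_words(c("", "one", "two words", " padded   out ")),
               c(0L, 1L, 2L, 2L))
})

test_that("keyword extraction keeps short rules verbatim and budgets long ones", {
  bk <- tiny_backend()
  rule20 <- paste(rep(c("alpha", "beta", "gamma", "delta"), 5),
                  collapse = " ")
  expect_equal(count_words(rule20), 20L)
  expect_identical(extract_keywords(rule20, bk), rule20)  # boundary: <= 20
  rule5 <- "systolic blood pressure at baseline"
  expect_identical(extract_keywords(rule5, bk), rule5)
  set.seed(9)
  vocab <- c("pressure", "systolic", "diastolic", "visit", "derived",
             "score", "sum", "item", "response", "clinical", "record",
             "form", "baseline", "the", "of", "and")
  rule40 <- paste(sample(vocab, 40, replace = TRUE), collapse = " ")
  kw <- extract_keywords(rule40, bk, max_keywords = 15)
  expect_lte(count_words(kw), 15L)
  kw_words <- strsplit(kw, " ")[[1]]
  expect_true(all(tolower(kw_words) %in%
                    tolower(strsplit(rule40, " ")[[1]])))
  # no duplicated words in the output
  expect_false(anyDuplicated(tolower(kw_words)) > 0)
})

test_that("text bundles assemble the three channels and metadata", {
  rule30 <- paste(rep(c("derived", "from", "clinical", "diagnosis",
                        "record", "date"), 5), collapse = " ")
  d <- make_dict(c("DIAGDT", "SEX", "BMI"),
                 c("Disease diagnosis date", "Sex", "Body mass index"),
                 rules = c(rule30, "", "weight divided by height squared"))
  b <- add_text_bundles(d, tiny_backend())
  expect_equal(b$label_word_count, c(3L, 1L, 3L))
  expect_equal(b$rule_word_count, c(30L, 0L, 5L))
  expect_identical(b$rule_absent, c(FALSE, TRUE, FALSE))
  # absent rule: channel falls back to the label
  expect_identical(b$label_key_text[2], b$label_text[2])
  # short rule (<= 20 words): concatenated verbatim
  expect_identical(b$label_key_text[3],
                   "Body mass index weight divided by height squared")
  # long rule: keywords, all drawn from the rule
  kw <- sub("^Disease diagnosis date ", "", b$label_key_text[1])
  expect_lte(count_words(kw), 15L)
  # deterministic given a deterministic embedder
  b2 <- add_text_bundles(d, tiny_backend())
  expect_identical(b, b2)
  # backend required only when a rule exceeds the limit
  expect_error(add_text_bundles(d), "backend")
  expect_silent(add_text_bundles(d[2:3, ]))
})
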