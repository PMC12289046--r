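#' Configuration for the synthetic paired-dictionary generator
#'
#' The generator emulates a pair of cohort-study data dictionaries with
#' divergent naming conventions and known ground truth, so the whole
#' matching pipeline can be exercised offline.  Defaults mirror the
#' characteristics of real harmonization corpora: verbose source labels
#' (mean ~11.3 words) vs terser target labels (~8.5), short source sheet
#' descriptions (~3.2 words) vs longer target ones (~5.5), heavy
#' derivation-rule missingness on the source side (72.6%) vs light on the
#' target side (11.5%), longer rules on the target side (mean ~26.4 vs
#' ~14.9 words), and roughly a fifth of matched sources with 2-3 true
#' target alignments.
#'
#' @param n_source,n_target Number of source/target variables
#'   (`n_target >= n_source`).
#' @param match_rate Fraction of source variables with at least one true
#'   target.
#' @param multi_match_rate Fraction of matched sources with 2-3 true
#'   targets.
#' @param label_noise Named list of per-label corruption probabilities:
#'   `synonym` (per-word synonym swap), `drop` (per-word deletion),
#'   `shuffle` (whole-label word shuffle), `abbrev` (known-phrase
#'   abbreviation).
#' @param rule_missing_src,rule_missing_tgt Probability that a variable
#'   has no derivation rule.
#' @param rule_length Named list `list(src = , tgt = )` of mean rule
#'   lengths in words.
#' @param label_words Named list `list(src = , tgt = )` of mean label
#'   lengths in words.
#' @param n_sheets Number of data sheets per study (2-6; concept
#'   categories are grouped into sheets).
#' @param seed Integer seed; fully determines the output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_source = 60L, n_target = 240L,
                         match_rate = 1, multi_match_rate = 0.2,
                         label_noise = list(synonym = 0.15, drop = 0.08,
                                            shuffle = 0.10, abbrev = 0.3),
                         rule_missing_src = 0.726,
                         rule_missing_tgt = 0.115,
                         rule_length = list(src = 14.9, tgt = 26.4),
                         label_words = list(src = 11.3, tgt = 8.5),
                         n_sheets = 6L, seed = 7L) {
  probs <- c(match_rate, multi_match_rate, rule_missing_src,
             rule_missing_tgt, unlist(label_noise))
  stopifnot(all(probs >= 0 & probs <= 1), n_target >= n_source,
            n_source >= 1L, n_sheets >= 2L, n_sheets <= 6L)
  structure(
    list(n_source = as.integer(n_source), n_target = as.integer(n_target),
         match_rate = match_rate, multi_match_rate = multi_match_rate,
         label_noise = label_noise, rule_missing_src = rule_missing_src,
         rule_missing_tgt = rule_missing_tgt, rule_length = rule_length,
         label_words = label_words, n_sheets = as.integer(n_sheets),
         seed = as.integer(seed)),
    class = "synth_config")
}

# ---- static vocabulary (bundled so no network or model is needed) ------

synth_synonyms <- c(
  examination = "test", survey = "questionnaire", item = "question",
  score = "result", baseline = "initial", cost = "expenditure",
  death = "mortality", weight = "mass", education = "schooling",
  employment = "occupation", marital = "marriage", smoking = "tobacco",
  alcohol = "drinking", caregiver = "carer", patient = "subject",
  visit = "assessment", hospitalization = "admission",
  discontinuation = "withdrawal", indicator = "flag",
  orientation = "awareness", area = "region", monthly = "permonth",
  total = "overall", diagnosis = "disease", height = "stature")

synth_abbreviations <- c(
  "body mass index" = "BMI",
  "blood pressure" = "BP",
  "mini mental state examination" = "MMSE",
  "quality of life" = "QoL",
  "activities of daily living" = "ADL",
  "time to death" = "TTD",
  "heart rate" = "pulse")

synth_fillers <- c("value", "result", "numeric", "recorded", "score",
                   "assessment", "measure", "observed", "analysis",
                   "derived", "standardised", "reported")

# rule wording is study-specific: each side synthesizes its derivation
# rules from its own clause vocabulary, so matched pairs share the core
# concept words but not the surrounding rule text (as in real
# dictionaries, where studies word their definitions independently)
synth_rule_clauses_src <- c(
  "derived from the source field recorded at each scheduled visit",
  "value equals the measurement captured on the case report form",
  "coded 1 equals yes and 0 equals no",
  "missing entries are set to not available when the participant withdrew",
  "records flagged by the data management team were excluded",
  "computed after central review and validation of the raw entries",
  "question numbers follow the original instrument ordering",
  "summed across all completed items of the instrument")

synth_rule_clauses_tgt <- c(
  "taken directly from the electronic data capture system per protocol",
  "categories are one for present and zero for absent",
  "range spans zero through thirty where larger numbers mean better function",
  "blank cells denote participants lost to follow up",
  "entries failing the automated plausibility screen were discarded",
  "averaged over duplicate determinations five minutes apart",
  "ordering of the questions mirrors the printed booklet",
  "aggregated as the arithmetic total of the answered questions",
  "negative numbers flag events preceding enrolment")

synth_topics <- c(
  "orientation to time", "orientation to place",
  "registration of three words", "attention and calculation",
  "delayed recall of words", "naming common objects",
  "repeating a phrase", "following a three stage command",
  "reading and obeying", "writing a sentence", "copying a design",
  "counting backwards", "spelling a word backwards",
  "recall of address", "recognition of pictures",
  "verbal fluency for animals", "clock drawing", "walking ability",
  "dressing", "feeding", "toileting", "shopping", "managing money",
  "using the telephone", "preparing meals")

# concept pool: one row per harmonizable construct; built combinatorially
# per category, mirroring the data-element families of cohort studies on
# dementia (demographics, vitals, questionnaire items, costs,
# time-to-event, comorbidities)
synth_concepts <- function() {
  demo <- c("sex", "age in years", "years of education", "marital status",
            "living area", "employment status", "smoking status",
            "alcohol use", "household size", "ethnic group",
            "primary language", "handedness", "insurance type",
            "retirement age", "number of children")
  vit_measures <- c("body mass index", "body weight", "body height",
                    "systolic blood pressure", "diastolic blood pressure",
                    "heart rate", "respiratory rate",
                    "waist circumference", "hip circumference",
                    "body temperature", "oxygen saturation",
                    "grip strength")
  vit_times <- c("baseline", "visit 2", "visit 3", "final visit")
  instruments <- c("mini mental state examination",
                   "cognitive assessment scale",
                   "daily living inventory",
                   "quality of life survey",
                   "caregiver burden interview")
  payers <- c("patient", "caregiver")
  cost_types <- c("direct medical", "direct nonmedical", "indirect")
  periods <- c("per month", "up to visit", "total study period",
               "per year")
  events <- c("death", "institutionalization", "study discontinuation",
              "first hospitalization", "dementia progression",
              "loss of independence", "first fall", "treatment change")
  conditions <- c("hypertension", "type 2 diabetes", "stroke",
                  "depression", "anxiety disorder",
                  "coronary artery disease", "atrial fibrillation",
                  "chronic kidney disease", "osteoarthritis",
                  "osteoporosis", "cancer history", "thyroid disease",
                  "parkinsonism", "hearing loss", "visual impairment")
  rows <- list(
    tibble::tibble(category = "demographic", core = demo),
    tibble::tibble(
      category = "vitals",
      core = as.vector(outer(vit_measures, vit_times, paste, sep = " at "))),
    tibble::tibble(
      category = "questionnaire",
      core = as.vector(outer(
        instruments, paste("item", seq_along(synth_topics), synth_topics),
        paste, sep = " "))),
    tibble::tibble(
      category = "cost",
      core = as.vector(outer(
        as.vector(outer(payers, cost_types, paste)),
        paste("cost", periods), paste))),
    tibble::tibble(category = "time_to_event",
                   core = paste("time to", rep(events, each = 2),
                                c("in months", "in days"))),
    tibble::tibble(category = "diagnosis",
                   core = paste(rep(conditions, each = 2),
                                c("diagnosis indicator",
                                  "treatment indicator"))))
  dplyr::bind_rows(rows)
}

# sheet catalog: per category, study-specific sheet names/descriptions;
# categories are grouped into n_sheets sheets
synth_sheets <- function(n_sheets) {
  cats <- c("demographic", "vitals", "questionnaire", "cost",
            "time_to_event", "diagnosis")
  src_names <- c("DM", "VS", "QS", "CO", "TTE", "MH")
  src_desc <- c("Demographics and Relationship", "Vital Signs Baseline",
                "Questionnaire Item Result Values",
                "Cost Primary Analysis", "Time to Event Data",
                "Medical History Comorbidities")
  tgt_names <- c("SLADS_DM", "VSV", "QRV", "TCV", "TTESL", "CMV")
  tgt_desc <- c("Subject Level Demographics Analysis Dataset",
                "Vital Signs per Visit Dataset",
                "Questionnaire Responses per Visit Dataset",
                "Total Cost up to the Visit",
                "Time to Event Subject Level Dataset",
                "Caregiver and Subject Comorbidities per Visit")
  grp <- rep_len(seq_len(n_sheets), length(cats))
  tibble::tibble(category = cats,
                 src_sheet = src_names[grp], src_desc = src_desc[grp],
                 tgt_sheet = tgt_names[grp], tgt_desc = tgt_desc[grp])
}

# ---- label machinery ---------------------------------------------------

# decorate a core phrase up to a drawn target length with filler words;
# the draw is keyed by (concept, mean length) so that the canonical
# (pre-noise) label of a concept is identical wherever it appears — under
# zero noise and equal length settings, matched labels coincide exactly
synth_pad_label <- function(core_tokens, mean_len) {
  cseed <- (sum(utf8ToInt(paste(core_tokens, collapse = " "))) * 131 +
              round(mean_len * 100)) %% 2147483000 + 1
  with_local_seed(cseed, {
    want <- max(length(core_tokens),
                round(stats::rnorm(1, mean_len, 0.3 * mean_len)))
    extra <- want - length(core_tokens)
    if (extra <= 0) {
      core_tokens
    } else {
      pad <- sample(synth_fillers, extra, replace = TRUE)
      front <- extra %/% 2
      c(pad[seq_len(front)], core_tokens,
        pad[seq_len(extra - front) + front])
    }
  })
}

# per-label noise: abbreviation, per-word synonym swap, per-word drop,
# whole-label shuffle
synth_noise_label <- function(label, noise) {
  for (phrase in names(synth_abbreviations)) {
    if (grepl(phrase, label, fixed = TRUE) &&
        stats::runif(1) < noise$abbrev) {
      label <- sub(phrase, synth_abbreviations[[phrase]], label,
                   fixed = TRUE)
    }
  }
  tok <- strsplit(label, " ", fixed = TRUE)[[1]]
  swap <- names(synth_synonyms)
  for (i in seq_along(tok)) {
    if (tok[i] %in% swap && stats::runif(1) < noise$synonym) {
      tok[i] <- synth_synonyms[[tok[i]]]
    }
  }
  if (length(tok) > 2L) {
    keep <- stats::runif(length(tok)) >= noise$drop
    if (sum(keep) >= 2L) tok <- tok[keep]
  }
  if (stats::runif(1) < noise$shuffle) tok <- sample(tok)
  paste(tok, collapse = " ")
}

synth_rule <- function(core, mean_len, side) {
  clauses <- if (side == "src") synth_rule_clauses_src else
    synth_rule_clauses_tgt
  want <- max(3L, round(stats::rgamma(1, shape = 2, scale = mean_len / 2)))
  words <- strsplit(paste("defined as the", core,
                          paste(sample(clauses, length(clauses)),
                                collapse = " ")),
                    " ", fixed = TRUE)[[1]]
  paste(words[seq_len(min(want, length(words)))], collapse = " ")
}

# study-specific variable-name conventions: source uses sheet-prefixed
# initialisms, target uses truncated concept codes
synth_src_name <- function(core, sheet, i) {
  ini <- toupper(substr(strsplit(core, " ", fixed = TRUE)[[1]], 1, 1))
  paste0(sheet, "_", paste(ini[seq_len(min(6, length(ini)))],
                           collapse = ""), i)
}

synth_tgt_name <- function(core, i) {
  code <- toupper(gsub("[^a-z]", "", substr(gsub(" ", "", core), 1, 8)))
  paste0(code, "_", i)
}

#' Generate a paired pair of study dictionaries with known truth
#'
#' Builds two study dictionaries ("studyA" as source, "studyB" as target)
#' from a shared concept pool.  Matched variables derive from the same
#' concept on both sides through independent decoration and noise
#' channels (synonym swaps, word drops, shuffles, abbreviations), so
#' matched pairs share lexical and semantic signal while distractor
#' targets come from held-out concepts and never participate in the
#' ground truth.  Derivation rules are synthesized from template clauses
#' with the configured length and missingness; sheets group the concept
#' categories with study-specific descriptions.
#'
#' @param config A [synth_config()].
#' @return List with elements `source` and `target`
#'   (`study_dictionary`), and `truth` (`match_table`).  Output is fully
#'   determined by `config$seed`.
#' @export
generate_paired_dictionaries <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, generate_paired_impl(config))
}

generate_paired_impl <- function(cfg) {
  concepts <- synth_concepts()
  sheets <- synth_sheets(cfg$n_sheets)
  n_matched <- round(cfg$match_rate * cfg$n_source)
  n_multi <- round(cfg$multi_match_rate * n_matched)
  multi_extra <- if (n_multi > 0) {
    sample(1:2, n_multi, replace = TRUE)  # 2-3 targets per multi source
  } else integer(0)
  n_matched_tgt <- n_matched + sum(multi_extra)
  n_distract <- cfg$n_target - n_matched_tgt
  if (n_distract < 0) {
    stop("infeasible counts: ", cfg$n_target, " targets cannot hold ",
         n_matched_tgt, " matched records", call. = FALSE)
  }
  need <- cfg$n_source + n_distract
  if (need > nrow(concepts)) {
    stop("infeasible counts: need ", need, " concepts but the pool has ",
         nrow(concepts), call. = FALSE)
  }
  picked <- concepts[sample.int(nrow(concepts), need), ]
  src_concepts <- picked[seq_len(cfg$n_source), ]
  distractors <- picked[-seq_len(cfg$n_source), , drop = FALSE]
  matched_idx <- sort(sample.int(cfg$n_source, n_matched))
  multi_idx <- if (n_multi > 0) sort(sample(matched_idx, n_multi)) else
    integer(0)

  # -- record builder shared by both sides
  make_record <- function(core, category, side, idx) {
    sh <- sheets[sheets$category == category, ]
    mean_label <- if (side == "src") cfg$label_words$src else
      cfg$label_words$tgt
    miss <- if (side == "src") cfg$rule_missing_src else
      cfg$rule_missing_tgt
    mean_rule <- if (side == "src") cfg$rule_length$src else
      cfg$rule_length$tgt
    tokens <- synth_pad_label(strsplit(core, " ", fixed = TRUE)[[1]],
                              mean_label)
    label <- synth_noise_label(paste(tokens, collapse = " "),
                               cfg$label_noise)
    rule <- if (stats::runif(1) < miss) "" else
      synth_rule(core, mean_rule, side)
    name <- if (side == "src") {
      synth_src_name(core, sh$src_sheet, idx)
    } else {
      synth_tgt_name(core, idx)
    }
    tibble::tibble(
      study_id = if (side == "src") "studyA" else "studyB",
      sheet_name = if (side == "src") sh$src_sheet else sh$tgt_sheet,
      sheet_description = if (side == "src") sh$src_desc else sh$tgt_desc,
      variable_name = name, variable_label = label,
      derivation_rule = rule)
  }

  src_tbl <- dplyr::bind_rows(lapply(seq_len(cfg$n_source), function(i) {
    make_record(src_concepts$core[i], src_concepts$category[i], "src", i)
  }))

  tgt_parts <- list()
  truth_parts <- list()
  tgt_counter <- 0L
  extra_of <- stats::setNames(rep(0L, length(multi_idx)), multi_idx)
  if (length(multi_idx)) extra_of[] <- multi_extra
  for (i in matched_idx) {
    n_rec <- 1L + if (as.character(i) %in% names(extra_of))
      extra_of[[as.character(i)]] else 0L
    for (r in seq_len(n_rec)) {
      tgt_counter <- tgt_counter + 1L
      rec <- make_record(src_concepts$core[i], src_concepts$category[i],
                         "tgt", tgt_counter)
      # extra alignments of a multi-match source live in a different
      # sheet (the same construct recorded twice in the target study)
      if (r > 1L) {
        rec$sheet_name <- "SLADS"
        rec$sheet_description <- "Subject Level Analysis Dataset"
      }
      tgt_parts[[length(tgt_parts) + 1L]] <- rec
      truth_parts[[length(truth_parts) + 1L]] <- tibble::tibble(
        source = src_tbl$variable_name[i], target = rec$variable_name)
    }
  }
  if (n_distract > 0) {
    for (j in seq_len(n_distract)) {
      tgt_counter <- tgt_counter + 1L
      tgt_parts[[length(tgt_parts) + 1L]] <-
        make_record(distractors$core[j], distractors$category[j], "tgt",
                    tgt_counter)
    }
  }
  tgt_tbl <- dplyr::bind_rows(tgt_parts)
  perm <- sample.int(nrow(tgt_tbl))
  tgt_tbl <- tgt_tbl[perm, ]
  source <- as_study_dictionary(src_tbl)
  target <- as_study_dictionary(tgt_tbl)
  truth <- as_match_table(dplyr::bind_rows(truth_parts), source, target)
  list(source = source, target = target, truth = truth)
}

#' Generate a long-format questionnaire sheet with its wide counterpart
#'
#' Emulates a questionnaire stored in long format on the source side (one
#' variable holding the question number, one holding the score) whose
#' target-study counterpart is wide (one variable per question).  The
#' returned pieces make the long-to-wide transform testable end to end:
#' apply [long_to_wide()] to `source` with `data_rows` and `spec`, then
#' match against `target`; under zero noise every widened variable aligns
#' with its wide target at rank 1.
#'
#' @param config A [synth_config()] (only the seed is used).
#' @param n_questions Number of questionnaire items (>= 1).
#' @return List with `source` (a 2-record `study_dictionary`),
#'   `data_rows` (the long sheet's rows), `spec` (a [long_format_spec()]),
#'   `target` (the wide `study_dictionary` with `n_questions` records)
#'   and `truth` (a plain tibble mapping post-transform source names to
#'   target names; validate it after the transform).
#' @export
generate_long_format_sheet <- function(config = synth_config(),
                                       n_questions = 11L) {
  stopifnot(n_questions >= 1L)
  with_local_seed(config$seed + 1L, {
    keys <- seq_len(n_questions)
    src <- as_study_dictionary(tibble::tibble(
      study_id = "studyA", sheet_name = "QS",
      sheet_description = "Questionnaire Item Result Values",
      variable_name = c("MEMQSNUM", "MEMRN"),
      variable_label = c("Memory Screening Question Number",
                         "Memory Screening Item Result Numeric"),
      derivation_rule = c("", "score of the memory screening item")))
    data_rows <- tibble::tibble(
      MEMQSNUM = rep(keys, each = 2L),
      MEMRN = sample(0:3, 2L * n_questions, replace = TRUE))
    spec <- long_format_spec(
      sheet_name = "QS", key_variable = "MEMQSNUM",
      value_variable = "MEMRN",
      label_template = "Memory Screening Item Result Numeric Question {key}")
    tgt <- as_study_dictionary(tibble::tibble(
      study_id = "studyB", sheet_name = "QRV",
      sheet_description = "Questionnaire Responses per Visit Dataset",
      variable_name = paste0("MEMQ", keys),
      variable_label = paste("Memory Screening Question", keys,
                             "Result Numeric"),
      derivation_rule = ""))
    truth <- tibble::tibble(source = paste0("MEMRN_", keys),
                            target = paste0("MEMQ", keys))
    list(source = src, data_rows = data_rows, spec = spec, target = tgt,
         truth = truth)
  })
}
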