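.varmatchr_env <- new.env(parent = emptyenv())

#' English stop-word list used by fuzzy-matching normalization
#'
#' The list is frozen as a plain-text fixture shipped with the package so
#' that normalized strings are stable across library versions.
#'
#' @return Character vector of lowercase stop words.
#' @export
stopwords_en <- function() {
  if (is.null(.varmatchr_env$stopwords)) {
    path <- system.file("extdata", "stopwords_en.txt",
                        package = "varmatchr", mustWork = TRUE)
    .varmatchr_env$stopwords <- readLines(path, encoding = "UTF-8")
  }
  .varmatchr_env$stopwords
}

#' Count whitespace-delimited words
#' @param x Character vector.
#' @return Integer vector of token counts (`""` counts 0).
#' @export
count_words <- function(x) {
  x <- stringr::str_squish(ifelse(is.na(x), "", x))
  ifelse(nzchar(x), stringr::str_count(x, "\\S+"), 0L)
}

#' Normalize text for fuzzy matching
#'
#' Applies the lexical-matching preprocessing pipeline: lowercase, strip
#' punctuation, drop English stop words, and Porter-stem the remaining
#' tokens, re-joined by single spaces.  Embedding channels use raw text;
#' this normalization applies only to fuzzy matching.  The function is
#' idempotent.
#'
#' @param text Character vector.
#' @return Character vector of normalized strings; an all-stop-word input
#'   yields `""` (its fuzzy score is defined as 0 downstream).
#' @examples
#' normalize_for_fuzzy("Body Mass Index (BMI) at Baseline")
#' @export
normalize_for_fuzzy <- function(text) {
  text <- ifelse(is.na(text), "", text)
  x <- tolower(text)
  x <- gsub("[[:punct:]]", " ", x)
  sw <- stopwords_en()
  vapply(strsplit(stringr::str_squish(x), " ", fixed = TRUE), function(tok) {
    tok <- tok[nzchar(tok) & !tok %in% sw]
    if (!length(tok)) return("")
    # stem to a fixpoint: single-pass Porter is not idempotent for every
    # word ("circumference" -> "circumfer" -> "circumf"), and downstream
    # code relies on normalize_for_fuzzy(x) being stable under re-application
    repeat {
      stemmed <- porter_stem(tok)
      if (identical(stemmed, tok)) break
      tok <- stemmed
    }
    paste(tok, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract keywords from a long derivation rule
#'
#' Derivation rules vary widely in length; rules longer than `word_limit`
#' words are compressed to at most `max_keywords` words before entering the
#' label+keywords text channel.  Candidate n-grams (1 to `ngram_max` words,
#' stop-word candidates excluded) are scored by cosine similarity between
#' their embedding and the embedding of the full rule, then selected
#' greedily by descending score; a candidate containing an already-selected
#' word is skipped (duplicate-word removal), as is one that would push the
#' total beyond `max_keywords` words.  Output preserves selection order.
#'
#' @param rule Non-empty derivation-rule text.
#' @param backend Embedding backend (see [hash_embedder()]).
#' @param max_keywords Word budget for the extracted keywords (default 15).
#' @param word_limit Rules of at most this many words are returned verbatim
#'   (default 20, boundary inclusive).
#' @param ngram_max Longest candidate phrase in words (default 2).
#' @return A single string of keywords (or the rule itself when short).
#' @export
extract_keywords <- function(rule, backend, max_keywords = 15L,
                             word_limit = 20L, ngram_max = 2L) {
  stopifnot(length(rule) == 1L, is.character(rule), nzchar(rule))
  n <- count_words(rule)
  if (n <= word_limit) return(stringr::str_squish(rule))
  tokens <- strsplit(stringr::str_squish(rule), " ", fixed = TRUE)[[1]]
  sw <- stopwords_en()
  cands <- character(0)
  for (k in seq_len(ngram_max)) {
    if (length(tokens) < k) break
    starts <- seq_len(length(tokens) - k + 1L)
    grams <- vapply(starts, function(i) {
      paste(tokens[i:(i + k - 1L)], collapse = " ")
    }, character(1))
    keep <- vapply(starts, function(i) {
      !all(tolower(tokens[i:(i + k - 1L)]) %in% sw)
    }, logical(1))
    cands <- c(cands, grams[keep])
  }
  cands <- cands[!duplicated(tolower(cands))]
  if (!length(cands)) {
    return(paste(utils::head(tokens, max_keywords), collapse = " "))
  }
  emb <- row_normalize(embed_texts(c(rule, cands), backend))
  scores <- as.numeric(emb[-1, , drop = FALSE] %*% emb[1, ])
  ord <- order(-scores)  # stable: ties keep first-occurrence order
  selected <- character(0)
  used_words <- character(0)
  total <- 0L
  for (i in ord) {
    words <- strsplit(cands[i], " ", fixed = TRUE)[[1]]
    if (any(tolower(words) %in% used_words)) next
    if (total + length(words) > max_keywords) next
    selected <- c(selected, cands[i])
    used_words <- c(used_words, tolower(words))
    total <- total + length(words)
    if (total >= max_keywords) break
  }
  if (!length(selected)) {
    return(paste(utils::head(tokens, max_keywords), collapse = " "))
  }
  paste(selected, collapse = " ")
}

#' Build the text channels used by every similarity method
#'
#' Adds, for each dictionary record, the three text channels and the
#' metadata descriptors consumed downstream:
#' `label_text` (the variable label), `sheet_text` (the data sheet
#' description), and `label_key_text` (label concatenated with the
#' derivation rule, or with keywords extracted from it when the rule
#' exceeds `word_limit` words; just the label when the rule is absent, so
#' the channel is always non-empty).  Also adds `label_word_count`,
#' `rule_word_count` and `rule_absent`.
#'
#' @param dictionary A `study_dictionary`.
#' @param backend Embedding backend used for keyword extraction; required
#'   only when some rule exceeds `word_limit` words.
#' @param max_keywords,word_limit,ngram_max Passed to [extract_keywords()].
#' @return The dictionary tibble with the six new columns.
#' @export
add_text_bundles <- function(dictionary, backend = NULL, max_keywords = 15L,
                             word_limit = 20L, ngram_max = 2L) {
  d <- dictionary
  d$label_text <- d$variable_label
  d$sheet_text <- d$sheet_description
  d$label_word_count <- count_words(d$variable_label)
  d$rule_word_count <- count_words(d$derivation_rule)
  d$rule_absent <- !nzchar(d$derivation_rule)
  key_part <- d$derivation_rule
  long <- which(!d$rule_absent & d$rule_word_count > word_limit)
  if (length(long)) {
    if (is.null(backend)) {
      stop("an embedding backend is required to extract keywords from ",
           length(long), " derivation rule(s) longer than ", word_limit,
           " words", call. = FALSE)
    }
    key_part[long] <- vapply(long, function(i) {
      tryCatch(
        extract_keywords(d$derivation_rule[i], backend, max_keywords,
                         word_limit, ngram_max),
        error = function(e) {
          stop("keyword extraction failed for variable '",
               d$variable_name[i], "': ", conditionMessage(e),
               call. = FALSE)
        })
    }, character(1))
  }
  d$label_key_text <- ifelse(d$rule_absent, d$label_text,
                             paste(d$label_text, key_part))
  d
}
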