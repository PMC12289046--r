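#' Porter stemmer
#'
#' Reduces English words to their stems with the classic Porter (1980)
#' suffix-stripping algorithm.  Used by [normalize_for_fuzzy()] so that
#' lexically similar variable labels ("baseline" vs "baselines") compare
#' equal under fuzzy matching.
#'
#' @param words Character vector of single lowercase words.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("body", "baselines", "relational", "hopping"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_one, character(1), USE.NAMES = FALSE)
}

# consonant map for a whole word; 'y' is a consonant at position 1 or
# after a vowel
.p_cons_map <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (j in seq_len(n)) {
    c <- chars[j]
    cons[j] <- if (c %in% c("a", "e", "i", "o", "u")) {
      FALSE
    } else if (c == "y") {
      if (j == 1L) TRUE else !cons[j - 1L]
    } else TRUE
  }
  cons
}

# measure m of a stem: number of VC sequences
.p_measure <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cons <- .p_cons_map(strsplit(stem, "")[[1]])
  # collapse runs of consonants/vowels, count V->C transitions
  r <- rle(cons)$values
  if (length(r) >= 2L) sum(!r[-length(r)] & r[-1]) else 0L
}

.p_has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  any(!.p_cons_map(strsplit(stem, "")[[1]]))
}

.p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  cons <- .p_cons_map(strsplit(word, "")[[1]])
  cons[n]
}

# *o: stem ends cvc where the final c is not w, x or y
.p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cons <- .p_cons_map(strsplit(word, "")[[1]])
  last <- substr(word, n, n)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(last %in% c("w", "x", "y"))
}

.p_ends <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n > k && substr(word, n - k + 1L, n) == suffix
}

.p_stem_of <- function(word, suffix) {
  substr(word, 1L, nchar(word) - nchar(suffix))
}

porter_stem_one <- function(word) {
  w <- word
  if (nchar(w) <= 2L) return(w)

  # step 1a
  if (.p_ends(w, "sses")) {
    w <- paste0(.p_stem_of(w, "sses"), "ss")
  } else if (.p_ends(w, "ies")) {
    w <- paste0(.p_stem_of(w, "ies"), "i")
  } else if (!.p_ends(w, "ss") && .p_ends(w, "s")) {
    w <- .p_stem_of(w, "s")
  }

  # step 1b
  did_1b2 <- FALSE
  if (.p_ends(w, "eed")) {
    if (.p_measure(.p_stem_of(w, "eed")) > 0L) {
      w <- paste0(.p_stem_of(w, "eed"), "ee")
    }
  } else if (.p_ends(w, "ed") && .p_has_vowel(.p_stem_of(w, "ed"))) {
    w <- .p_stem_of(w, "ed"); did_1b2 <- TRUE
  } else if (.p_ends(w, "ing") && .p_has_vowel(.p_stem_of(w, "ing"))) {
    w <- .p_stem_of(w, "ing"); did_1b2 <- TRUE
  }
  if (did_1b2) {
    if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.p_measure(w) == 1L && .p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (.p_ends(w, "y") && .p_has_vowel(.p_stem_of(w, "y"))) {
    w <- paste0(.p_stem_of(w, "y"), "i")
  }

  # step 2 (condition m > 0 on the stem)
  step2 <- c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  )
  for (sfx in names(step2)) {
    if (.p_ends(w, sfx)) {
      stem <- .p_stem_of(w, sfx)
      if (.p_measure(stem) > 0L) w <- paste0(stem, step2[[sfx]])
      break
    }
  }

  # step 3
  step3 <- c(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  )
  for (sfx in names(step3)) {
    if (.p_ends(w, sfx)) {
      stem <- .p_stem_of(w, sfx)
      if (.p_measure(stem) > 0L) w <- paste0(stem, step3[[sfx]])
      break
    }
  }

  # step 4 (condition m > 1)
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  # longest-match first
  step4 <- step4[order(-nchar(step4))]
  for (sfx in step4) {
    if (.p_ends(w, sfx)) {
      stem <- .p_stem_of(w, sfx)
      ok <- .p_measure(stem) > 1L
      if (sfx == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (.p_ends(w, "e")) {
    stem <- .p_stem_of(w, "e")
    m <- .p_measure(stem)
    if (m > 1L || (m == 1L && !.p_cvc(stem))) w <- stem
  }

  # step 5b
  if (.p_measure(w) > 1L && .p_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- substr(w, 1L, nchar(w) - 1L)
  }
  w
}
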