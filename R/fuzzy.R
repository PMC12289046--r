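#' Token-set-ratio fuzzy similarity
#'
#' Lexical similarity on a 0-100 scale, computed the way the classic
#' fuzzy-matching token-set scorer does: each string is tokenized on
#' whitespace, tokens are deduplicated and sorted alphabetically; with
#' `I` the sorted token intersection and `D1`, `D2` the sorted set
#' differences, three strings are formed — `s0 = join(I)`,
#' `s1 = join(I, D1)`, `s2 = join(I, D2)` (space-joined) — and the result
#' is the maximum normalized indel similarity over the pairs
#' `(s0, s1)`, `(s0, s2)`, `(s1, s2)`, times 100.  Normalized indel
#' similarity of strings `x`, `y` is
#' `1 - indel_distance(x, y) / (nchar(x) + nchar(y))`, where the indel
#' distance allows insertions and deletions only.
#'
#' Inputs are expected to be pre-normalized with [normalize_for_fuzzy()].
#' If either token set is empty the score is 0 by convention.  Whenever one
#' token set is a subset of the other the score is 100.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Numeric vector of scores in `[0, 100]`.
#' @examples
#' token_set_ratio("bodi mass index", "index mass bodi")   # 100
#' token_set_ratio("vital sign bmi baselin", "bmi baselin")
#' @export
token_set_ratio <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(ifelse(is.na(a), "", as.character(a)), n)
  b <- rep_len(ifelse(is.na(b), "", as.character(b)), n)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  res <- vapply(which(first), function(i) tsr_one(a[i], b[i]), numeric(1))
  res[match(key, key[first])]
}

tsr_one <- function(x, y) {
  tx <- unique(strsplit(stringr::str_squish(x), " ", fixed = TRUE)[[1]])
  ty <- unique(strsplit(stringr::str_squish(y), " ", fixed = TRUE)[[1]])
  tx <- tx[nzchar(tx)]; ty <- ty[nzchar(ty)]
  if (!length(tx) || !length(ty)) return(0)
  I <- sort(intersect(tx, ty))
  D1 <- sort(setdiff(tx, ty))
  D2 <- sort(setdiff(ty, tx))
  s0 <- paste(I, collapse = " ")
  s1 <- paste(c(I, D1), collapse = " ")
  s2 <- paste(c(I, D2), collapse = " ")
  # s0 is a prefix of s1 and of s2, so those indel distances are the
  # length differences
  sim_prefix <- function(p, w) {
    lp <- nchar(p); lw <- nchar(w)
    if (lp + lw == 0) 1 else 1 - (lw - lp) / (lp + lw)
  }
  sims <- c(sim_prefix(s0, s1), sim_prefix(s0, s2), indel_similarity(s1, s2))
  100 * max(sims)
}

# normalized indel similarity via generalized edit distance with
# substitution cost 2 (a substitution = one deletion + one insertion)
indel_similarity <- function(x, y) {
  if (identical(x, y)) return(1)
  lx <- nchar(x); ly <- nchar(y)
  if (lx + ly == 0) return(1)
  d <- utils::adist(x, y,
                    costs = list(insertions = 1, deletions = 1,
                                 substitutions = 2))[1, 1]
  1 - d / (lx + ly)
}
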