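# Independent oracles used to cross-check the implementation.

# O(nm) indel (insert/delete only) edit distance, classic DP
oracle_indel <- function(x, y) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  if (n && m) {
    for (i in 1:n) {
      for (j in 1:m) {
        best <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L)
        if (a[i] == b[j]) best <- min(best, d[i, j])
        d[i + 1L, j + 1L] <- best
      }
    }
  }
  d[n + 1L, m + 1L]
}

# independent token-set-ratio: same string construction, all three
# similarities computed with the DP above (no closed-form shortcuts)
oracle_tsr <- function(x, y) {
  toks <- function(s) {
    t <- strsplit(trimws(s), "\\s+")[[1]]
    unique(t[nzchar(t)])
  }
  tx <- toks(x); ty <- toks(y)
  if (!length(tx) || !length(ty)) return(0)
  I <- sort(intersect(tx, ty))
  s0 <- paste(I, collapse = " ")
  s1 <- paste(c(I, sort(setdiff(tx, ty))), collapse = " ")
  s2 <- paste(c(I, sort(setdiff(ty, tx))), collapse = " ")
  sim <- function(p, q) {
    tot <- nchar(p) + nchar(q)
    if (tot == 0) 1 else 1 - oracle_indel(p, q) / tot
  }
  100 * max(sim(s0, s1), sim(s0, s2), sim(s1, s2))
}

# brute-force "sort then assign median positions" rank oracle
oracle_median_ranks <- function(scores) {
  ord <- order(-scores)
  pos <- integer(length(scores))
  pos[ord] <- seq_along(scores)
  vapply(seq_along(scores), function(i) {
    stats::median(pos[scores == scores[i]])
  }, numeric(1))
}

# small in-code dictionary fixture
make_dict <- function(names, labels, study = "S", sheet = "SH",
                      desc = "Fixture data sheet", rules = "") {
  as_study_dictionary(tibble::tibble(
    study_id = study, sheet_name = sheet, sheet_description = desc,
    variable_name = names, variable_label = labels,
    derivation_rule = rep_len(rules, length(names))))
}

# seeded uniform noise vector
with_seed_vec <- function(seed, n) {
  set.seed(seed)
  stats::runif(n)
}

tiny_backend <- function(seed = 5L, dim = 32L) {
  hash_embedder(paste0("tb", seed), dim = dim, seed = seed)
}
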