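#' Rank candidate targets with median-rank tie resolution
#'
#' Orders candidates by descending score and assigns each candidate its
#' rank, resolving ties by the median of the list positions the tie block
#' occupies: a block of `k` equal scores at sorted positions
#' `p .. p+k-1` receives rank `(2p + k - 1) / 2` for every member (so
#' three candidates tied at positions 4-6 all get rank 5).  Equal scores
#' always receive equal ranks and a strictly higher score a strictly
#' smaller rank; ranks sum to `N(N+1)/2`.
#'
#' @param scores Named numeric vector (names are candidate identifiers) or
#'   a data frame whose first two columns are candidate and score.
#' @return Tibble with columns `target`, `score`, `rank`, ordered by
#'   descending score (ties keep input order).
#' @export
rank_candidates <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(ncol(scores) >= 2L)
    target <- as.character(scores[[1]])
    score <- as.numeric(scores[[2]])
  } else {
    stopifnot(is.numeric(scores), !is.null(names(scores)))
    target <- names(scores)
    score <- as.numeric(scores)
  }
  if (!length(score)) stop("empty score set", call. = FALSE)
  bad <- target[is.na(score) | is.nan(score)]
  if (length(bad)) {
    stop("non-finite score for candidate(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rk <- rank(-score, ties.method = "average")
  ord <- order(-score)
  tibble::tibble(target = target[ord], score = score[ord], rank = rk[ord])
}

# smallest median-resolved rank among a source's truth targets
first_hit_rank <- function(ranked, targets) {
  hit <- ranked$rank[ranked$target %in% targets]
  if (!length(hit)) {
    stop("no truth target among ranked candidates (targets: ",
         paste(targets, collapse = ", "), ")", call. = FALSE)
  }
  min(hit)
}

#' First-hit ranks for a set of ranked lists
#'
#' For each source, the smallest (best) median-resolved rank among that
#' source's truth targets.  For multi-match sources a hit only requires
#' any one truth target, so the minimum rank is used.
#'
#' @param results Named list of [rank_candidates()] tibbles, keyed by
#'   source variable name.
#' @param truth A `match_table`.
#' @return Tibble with columns `source`, `rhit` (possibly fractional).
#' @export
first_hit_ranks <- function(results, truth) {
  srcs <- names(results)
  missing <- setdiff(srcs, unique(truth$source))
  if (length(missing)) {
    stop("source(s) missing from the match table: ",
         paste(missing, collapse = ", "),
         " (evaluation only runs on matched sources)", call. = FALSE)
  }
  rhit <- vapply(srcs, function(s) {
    first_hit_rank(results[[s]], truth_targets(truth, s))
  }, numeric(1))
  tibble::tibble(source = srcs, rhit = unname(rhit))
}

#' Top-n hit ratio
#'
#' Fraction of evaluated source variables whose best-ranked truth target
#' has (median-resolved) rank at most `n` (strict `<= n`, so a tie-block
#' rank of 30.5 is not a hit at `n = 30`).
#'
#' @inheritParams first_hit_ranks
#' @param n Cutoff.
#' @return Numeric in `[0, 1]`.
#' @export
hit_ratio <- function(results, truth, n) {
  rhit <- first_hit_ranks(results, truth)$rhit
  mean(rhit <= n)
}

#' Mean reciprocal rank
#'
#' Mean over evaluated sources of `1 / Rhit`, where `Rhit` is the smallest
#' median-resolved rank among the source's truth targets (fractional ranks
#' from tie resolution are used as-is).
#'
#' @inheritParams first_hit_ranks
#' @return Numeric in `(0, 1]`.
#' @export
mean_reciprocal_rank <- function(results, truth) {
  rhit <- first_hit_ranks(results, truth)$rhit
  mean(1 / rhit)
}

#' Evaluate a set of ranked candidate lists
#'
#' Computes the hit ratio at each cutoff and the mean reciprocal rank in
#' one pass.
#'
#' @inheritParams first_hit_ranks
#' @param cutoffs Hit-ratio cutoffs (default `c(5, 10, 15, 20, 30)`).
#' @return A `match_eval` object: list with `hr` (named vector, names
#'   `"hr<cutoff>"`), `mrr`, `rhit` (per-source tibble) and `n_sources`.
#' @export
evaluate_ranking <- function(results, truth,
                             cutoffs = c(5, 10, 15, 20, 30)) {
  fh <- first_hit_ranks(results, truth)
  hr <- vapply(cutoffs, function(n) mean(fh$rhit <= n), numeric(1))
  names(hr) <- paste0("hr", cutoffs)
  structure(list(hr = hr, mrr = mean(1 / fh$rhit), rhit = fh,
                 n_sources = nrow(fh)),
            class = "match_eval")
}

# single metric value from a match_eval ("hr30", "mrr", ...)
metric_value <- function(eval, metric) {
  if (metric == "mrr") return(eval$mrr)
  if (metric %in% names(eval$hr)) return(unname(eval$hr[metric]))
  stop("unknown metric: ", metric, call. = FALSE)
}

#' @export
print.match_eval <- function(x, ...) {
  cat("# Ranking evaluation over", x$n_sources, "source variables\n")
  vals <- c(x$hr, mrr = x$mrr)
  print(round(vals, 4))
  invisible(x)
}
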