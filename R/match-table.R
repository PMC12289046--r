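#' Coerce a data frame to a ground-truth match table
#'
#' A match table records the manually curated alignments between a source
#' study and a target study, one row per (source variable, target variable)
#' pair.  A source variable may map to several targets (multi-match), e.g.
#' when the same construct is recorded in several target sheets.
#'
#' @param pairs Data frame whose first two columns are the source and
#'   target variable names (columns named `source`/`target` are used when
#'   present).
#' @param source_dict,target_dict Optional dictionaries; when supplied,
#'   every named variable must exist in its dictionary and unknown names
#'   raise an error citing the row number.
#' @return A `match_table` tibble with columns `source` and `target`.
#'   Printing reports the pair count, the number of unique sources, and the
#'   number of sources with more than one target.
#' @export
as_match_table <- function(pairs, source_dict = NULL, target_dict = NULL) {
  pairs <- tibble::as_tibble(pairs)
  if (all(c("source", "target") %in% names(pairs))) {
    pairs <- pairs[c("source", "target")]
  } else {
    if (ncol(pairs) < 2L) {
      stop("match table needs two columns (source, target)", call. = FALSE)
    }
    pairs <- pairs[1:2]
    names(pairs) <- c("source", "target")
  }
  pairs$source <- as.character(pairs$source)
  pairs$target <- as.character(pairs$target)
  if (anyNA(pairs) || any(!nzchar(pairs$source)) ||
      any(!nzchar(pairs$target))) {
    stop("match table contains missing variable names", call. = FALSE)
  }
  if (!is.null(source_dict)) {
    bad <- which(!pairs$source %in% source_dict$variable_name)
    if (length(bad)) {
      stop("unknown source variable(s) in match table: ",
           paste0("row ", bad, ": '", pairs$source[bad], "'",
                  collapse = "; "), call. = FALSE)
    }
  }
  if (!is.null(target_dict)) {
    bad <- which(!pairs$target %in% target_dict$variable_name)
    if (length(bad)) {
      stop("unknown target variable(s) in match table: ",
           paste0("row ", bad, ": '", pairs$target[bad], "'",
                  collapse = "; "), call. = FALSE)
    }
  }
  dup <- duplicated(paste(pairs$source, pairs$target, sep = "\r"))
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicated pair(s) in match table")
    pairs <- pairs[!dup, ]
  }
  tibble::new_tibble(pairs, class = "match_table")
}

#' Read a ground-truth match table
#'
#' Reads a two-column delimited file of manually matched (source, target)
#' variable pairs and validates every name against the two dictionaries.
#'
#' @param path Path to a 2-column CSV/TSV (`source`, `target`).
#' @param source_dict,target_dict The two study dictionaries.
#' @param delim Field delimiter; inferred from the extension by default.
#' @return A `match_table`; see [as_match_table()].
#' @export
read_match_table <- function(path, source_dict = NULL, target_dict = NULL,
                             delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  as_match_table(raw, source_dict, target_dict)
}

#' Summary counts of a match table
#' @param truth A `match_table`.
#' @return Named list: `n_pairs`, `n_sources`, `n_multi` (sources with more
#'   than one target).
#' @export
match_counts <- function(truth) {
  tab <- table(truth$source)
  list(n_pairs = nrow(truth), n_sources = length(tab),
       n_multi = sum(tab > 1L))
}

#' @export
print.match_table <- function(x, ...) {
  cnt <- match_counts(x)
  cat("# Match table: ", cnt$n_pairs, " pairs, ", cnt$n_sources,
      " unique sources (", cnt$n_multi, " with multiple targets)\n",
      sep = "")
  NextMethod()
}

# targets matched to one source variable
truth_targets <- function(truth, source) {
  truth$target[truth$source == source]
}

# source -> list of targets, in source first-appearance order
truth_index <- function(truth) {
  split(truth$target, factor(truth$source, levels = unique(truth$source)))
}
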