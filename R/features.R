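#' Canonical feature names
#'
#' The pair feature vector has 15 similarity features — three text channels
#' (`on_label`, `on_sheet`, `on_label_key`) for each of the four embedding
#' backends plus fuzzy matching — and 6 metadata features: word counts of
#' the two labels, word counts of the two derivation rules, and the two
#' rule-absence flags.
#'
#' @param methods Character vector of similarity method identifiers
#'   (backend ids plus `"fuzzy"`).
#' @return Character vector of feature names, method-major.
#' @export
similarity_feature_names <- function(methods) {
  as.vector(t(outer(methods, c("_on_label", "_on_sheet", "_on_label_key"),
                    paste0)))
}

#' @rdname similarity_feature_names
#' @export
metadata_feature_names <- function() {
  c("Label_len_src", "Label_len_tgt",
    "Derive_info_len_src", "Derive_info_len_tgt",
    "Derive_info_null_src", "Derive_info_null_tgt")
}

#' Enumerate labeled source-target candidate pairs
#'
#' For each listed source variable, one row per target-dictionary variable
#' (the full candidate set), labeled 1 when the pair is in the ground
#' truth and 0 otherwise.
#'
#' @param source_dict,target_dict The two study dictionaries.
#' @param sources Source variable names to enumerate; defaults to the
#'   matched sources when `truth` is given, else all source variables.
#' @param truth Optional `match_table`; when `NULL` all labels are 0 and
#'   the result carries `attr(, "labeled") = FALSE` (prediction mode).
#' @return Tibble with columns `source_name`, `target_name`, `label`;
#'   `length(sources) * nrow(target_dict)` rows.
#' @export
enumerate_pairs <- function(source_dict, target_dict, sources = NULL,
                            truth = NULL) {
  if (is.null(sources)) {
    sources <- if (!is.null(truth)) {
      unique(truth$source)
    } else {
      source_dict$variable_name
    }
  }
  unknown <- setdiff(sources, source_dict$variable_name)
  if (length(unknown)) {
    stop("unknown source variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tg <- target_dict$variable_name
  out <- tibble::tibble(
    source_name = rep(sources, each = length(tg)),
    target_name = rep(tg, times = length(sources)))
  if (is.null(truth)) {
    out$label <- 0L
  } else {
    out$label <- as.integer(
      paste(out$source_name, out$target_name, sep = "\r") %in%
        paste(truth$source, truth$target, sep = "\r"))
  }
  attr(out, "labeled") <- !is.null(truth)
  out
}

#' Build the pair feature matrix
#'
#' Assembles the full feature table used by the ensemble: for every
#' (source, target) candidate pair, the 15 similarity features (each
#' embedding backend and fuzzy matching applied to the three text
#' channels) and the 6 dictionary metadata features, plus the binary match
#' label.  Embedding channels score cosine similarity on raw channel text;
#' fuzzy channels score token-set ratio on [normalize_for_fuzzy()] text.
#' Embeddings are computed once per distinct string and cached in the
#' backend.
#'
#' @param source_dict,target_dict The two study dictionaries.
#' @param truth Optional `match_table` providing labels.
#' @param sources Source variables to include (see [enumerate_pairs()]).
#' @param backends Named list of embedding backends
#'   (default [default_backends()]).
#' @param include_fuzzy Include the fuzzy-matching channels (default TRUE).
#' @param max_keywords,word_limit Keyword-extraction settings, see
#'   [extract_keywords()].
#' @return A `pair_features` tibble with `source_name`, `target_name`, the
#'   21 feature columns in canonical order, and `label`; attributes
#'   `methods` and `feature_cols` record the layout.  Boolean features are
#'   encoded 0/1 and no value is missing.
#' @export
build_pair_matrix <- function(source_dict, target_dict, truth = NULL,
                              sources = NULL,
                              backends = default_backends(),
                              include_fuzzy = TRUE,
                              max_keywords = 15L, word_limit = 20L) {
  pairs <- enumerate_pairs(source_dict, target_dict, sources, truth)
  src_names <- unique(pairs$source_name)
  kw_backend <- if (length(backends)) backends[[1]] else NULL
  src_b <- add_text_bundles(
    source_dict[match(src_names, source_dict$variable_name), ],
    kw_backend, max_keywords, word_limit)
  tgt_b <- add_text_bundles(target_dict, kw_backend, max_keywords,
                            word_limit)
  si <- match(pairs$source_name, src_b$variable_name)
  ti <- match(pairs$target_name, tgt_b$variable_name)
  channels <- c(on_label = "label_text", on_sheet = "sheet_text",
                on_label_key = "label_key_text")
  out <- pairs[c("source_name", "target_name")]
  methods <- character(0)
  for (bk in backends) {
    methods <- c(methods, bk$id)
    for (ch in names(channels)) {
      S <- row_normalize(embed_texts(src_b[[channels[[ch]]]], bk))
      Tm <- row_normalize(embed_texts(tgt_b[[channels[[ch]]]], bk))
      M <- S %*% t(Tm)
      out[[paste0(bk$id, "_", ch)]] <- M[cbind(si, ti)]
    }
  }
  if (include_fuzzy) {
    methods <- c(methods, "fuzzy")
    for (ch in names(channels)) {
      sn <- normalize_for_fuzzy(src_b[[channels[[ch]]]])
      tn <- normalize_for_fuzzy(tgt_b[[channels[[ch]]]])
      out[[paste0("fuzzy_", ch)]] <- token_set_ratio(sn[si], tn[ti])
    }
  }
  out$Label_len_src <- src_b$label_word_count[si]
  out$Label_len_tgt <- tgt_b$label_word_count[ti]
  out$Derive_info_len_src <- src_b$rule_word_count[si]
  out$Derive_info_len_tgt <- tgt_b$rule_word_count[ti]
  out$Derive_info_null_src <- as.integer(src_b$rule_absent[si])
  out$Derive_info_null_tgt <- as.integer(tgt_b$rule_absent[ti])
  out$label <- pairs$label
  feature_cols <- c(similarity_feature_names(methods),
                    metadata_feature_names())
  stopifnot(!anyNA(out[feature_cols]))
  tibble::new_tibble(out, methods = methods, feature_cols = feature_cols,
                     labeled = attr(pairs, "labeled"),
                     class = "pair_features")
}

#' Feature columns of a pair feature table
#' @param x A `pair_features` tibble (or any feature table).
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(x) {
  fc <- attr(x, "feature_cols")
  if (!is.null(fc)) return(fc)
  setdiff(names(x), c("source_name", "target_name", "label"))
}

#' Similarity channel scores for one variable pair
#'
#' Convenience wrapper scoring a single source-target pair with every
#' method; mostly useful for inspecting why two variables were (not)
#' matched.
#'
#' @param src,tgt One-row study dictionaries (or single records).
#' @param backends,include_fuzzy See [build_pair_matrix()].
#' @return Tibble with one row per method and columns `method`,
#'   `on_label`, `on_sheet`, `on_label_key`.
#' @export
score_pair <- function(src, tgt, backends = default_backends(),
                       include_fuzzy = TRUE) {
  stopifnot(nrow(src) == 1L, nrow(tgt) == 1L)
  pm <- build_pair_matrix(src, tgt, backends = backends,
                          include_fuzzy = include_fuzzy)
  methods <- attr(pm, "methods")
  tibble::tibble(
    method = methods,
    on_label = vapply(methods, function(m) pm[[paste0(m, "_on_label")]],
                      numeric(1), USE.NAMES = FALSE),
    on_sheet = vapply(methods, function(m) pm[[paste0(m, "_on_sheet")]],
                      numeric(1), USE.NAMES = FALSE),
    on_label_key = vapply(methods,
                          function(m) pm[[paste0(m, "_on_label_key")]],
                          numeric(1), USE.NAMES = FALSE))
}

#' Default feature groups for ablation
#'
#' Partitions the 21 features into the three groups used by the ablation
#' analysis: embedding-derived similarity features (12), fuzzy-matching
#' features (3), and the other (metadata) features (6).
#'
#' @param methods Method identifiers as stored in
#'   `attr(pair_matrix, "methods")`.
#' @return Named list of three character vectors.
#' @export
default_feature_groups <- function(methods) {
  emb <- setdiff(methods, "fuzzy")
  list(
    llm = similarity_feature_names(emb),
    fuzzy = similarity_feature_names("fuzzy"),
    other = metadata_feature_names())
}
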