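#' Default data-dictionary column mapping
#'
#' Study data dictionaries name their columns differently; `read_dictionary()`
#' maps file columns onto the canonical fields through this named vector.
#' Names are the canonical field names, values are the column names expected
#' in the file.
#'
#' @param study_id,sheet_name,sheet_description,variable_name,variable_label,derivation_rule
#'   Column names used in the dictionary file for each canonical field.
#' @return Named character vector of length 6.
#' @export
dictionary_columns <- function(study_id = "study_id",
                               sheet_name = "sheet_name",
                               sheet_description = "sheet_description",
                               variable_name = "variable_name",
                               variable_label = "variable_label",
                               derivation_rule = "derivation_rule") {
  c(study_id = study_id,
    sheet_name = sheet_name,
    sheet_description = sheet_description,
    variable_name = variable_name,
    variable_label = variable_label,
    derivation_rule = derivation_rule)
}

.dict_fields <- c("study_id", "sheet_name", "sheet_description",
                  "variable_name", "variable_label", "derivation_rule")

#' Coerce a data frame to a validated study dictionary
#'
#' A study dictionary is a tibble with one row per variable and the six
#' canonical columns (`study_id`, `sheet_name`, `sheet_description`,
#' `variable_name`, `variable_label`, `derivation_rule`).  Text is trimmed
#' and Unicode-normalized to NFC so that tokenization is stable; a missing
#' derivation rule is stored as the empty string and never coerced to a
#' placeholder.  Row order is preserved.
#'
#' @param x Data frame with the canonical columns (missing `study_id` is
#'   filled from the `study_id` argument).
#' @param study_id Optional study identifier overriding/filling the
#'   `study_id` column.
#' @return A `study_dictionary` tibble.
#' @details Validation fails if `variable_name` is empty or duplicated, or
#'   if any `variable_label` is empty; offending variables are listed in the
#'   error.
#' @export
as_study_dictionary <- function(x, study_id = NULL) {
  x <- tibble::as_tibble(x)
  if (!is.null(study_id)) x$study_id <- study_id
  missing_cols <- setdiff(.dict_fields, names(x))
  if ("derivation_rule" %in% missing_cols) {
    x$derivation_rule <- ""
    missing_cols <- setdiff(missing_cols, "derivation_rule")
  }
  if (length(missing_cols)) {
    stop("dictionary is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[.dict_fields]
  for (f in .dict_fields) {
    v <- as.character(x[[f]])
    v[is.na(v)] <- ""
    x[[f]] <- stringi::stri_trans_nfc(stringr::str_squish(v))
  }
  validate_study_dictionary(x)
  sid <- unique(x$study_id)
  tibble::new_tibble(x, study_id = sid[1], class = "study_dictionary")
}

validate_study_dictionary <- function(x) {
  if (any(!nzchar(x$variable_name))) {
    stop("dictionary contains rows with empty variable_name (rows ",
         paste(which(!nzchar(x$variable_name)), collapse = ", "), ")",
         call. = FALSE)
  }
  dup <- unique(x$variable_name[duplicated(x$variable_name)])
  if (length(dup)) {
    stop("duplicate variable_name in dictionary: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  empty <- x$variable_name[!nzchar(x$variable_label)]
  if (length(empty)) {
    stop("variables with empty variable_label: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Read a study data dictionary
#'
#' Reads a delimited (CSV/TSV, UTF-8, header row) data dictionary into a
#' validated [as_study_dictionary()] tibble.  Missing derivation rules load
#' as empty strings; all fields are whitespace-trimmed and NFC-normalized.
#'
#' @param path Path to the dictionary file.
#' @param col_map Mapping from canonical field names to file column names,
#'   see [dictionary_columns()].
#' @param delim Field delimiter; default infers `"\t"` for `.tsv` files and
#'   `","` otherwise.
#' @param study_id Optional study identifier when the file has no study
#'   column.
#' @return A `study_dictionary` tibble in file order.
#' @export
read_dictionary <- function(path, col_map = dictionary_columns(),
                            delim = NULL, study_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  # study_id may come from the argument, derivation_rule may be absent
  optional <- "derivation_rule"
  if (!is.null(study_id)) optional <- c(optional, "study_id")
  need <- col_map[!names(col_map) %in% optional]
  missing <- need[!need %in% names(raw)]
  if (length(missing)) {
    stop("dictionary file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- col_map[col_map %in% names(raw)]
  out <- raw[unname(keep)]
  names(out) <- names(keep)
  as_study_dictionary(out, study_id = study_id)
}

#' Write a study dictionary to a delimited file
#'
#' Inverse of [read_dictionary()]: writing and re-reading a dictionary is
#' field-identical (text is already normalized at load).
#'
#' @param dictionary A `study_dictionary`.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path, delim = ",") {
  readr::write_delim(as.data.frame(dictionary)[.dict_fields], path,
                     delim = delim, na = "")
  invisible(path)
}

#' Study identifier of a dictionary
#' @param dictionary A `study_dictionary`.
#' @return Character scalar.
#' @export
study_id <- function(dictionary) {
  attr(dictionary, "study_id") %||% unique(dictionary$study_id)[1]
}

#' @export
print.study_dictionary <- function(x, ...) {
  cat("# Study dictionary '", study_id(x), "': ", nrow(x),
      " variables, ", length(unique(x$sheet_name)), " sheet(s)\n", sep = "")
  NextMethod()
}

#' Describe a long-format questionnaire sheet
#'
#' Some studies store questionnaire scores in long format: one variable
#' holds the question number and a second holds the score, with one data row
#' per question.  [long_to_wide()] uses this specification to replace the
#' pair with one synthetic wide variable per question.
#'
#' @param sheet_name Data sheet holding the two variables.
#' @param key_variable Name of the question-number variable.
#' @param value_variable Name of the score variable.
#' @param label_template Label for the synthetic wide variables; the literal
#'   token `"{key}"` is replaced by each question number.
#' @return A `long_format_spec` object.
#' @export
long_format_spec <- function(sheet_name, key_variable, value_variable,
                             label_template) {
  stopifnot(is.character(sheet_name), is.character(key_variable),
            is.character(value_variable), is.character(label_template))
  if (identical(key_variable, value_variable)) {
    stop("key_variable and value_variable must differ", call. = FALSE)
  }
  if (!grepl("{key}", label_template, fixed = TRUE)) {
    stop("label_template must contain the placeholder '{key}'",
         call. = FALSE)
  }
  structure(list(sheet_name = sheet_name, key_variable = key_variable,
                 value_variable = value_variable,
                 label_template = label_template),
            class = "long_format_spec")
}

#' Widen a long-format questionnaire sheet in a dictionary
#'
#' Replaces the (question-number, score) variable pair described by `spec`
#' with one synthetic variable per distinct question number observed in
#' `data_rows`.  Synthetic names are `value_variable` + `sep` + key;
#' synthetic labels instantiate `label_template`.  All other records are
#' untouched and the new records take the position of the removed pair.
#' Longitudinal visit-indexed variables should not be widened when visit
#' numbers align across studies; simply omit them from the spec.
#'
#' @param dictionary A `study_dictionary`.
#' @param data_rows Data frame with the sheet's rows; must contain the
#'   key-variable column.
#' @param spec A [long_format_spec()].
#' @param sep Separator used to build synthetic names (default `"_"`).
#' @return The transformed `study_dictionary`.  If the sheet is empty or
#'   the variable pair is absent the dictionary is returned unchanged with a
#'   warning (which makes the operation idempotent).
#' @export
long_to_wide <- function(dictionary, data_rows, spec, sep = "_") {
  stopifnot(inherits(spec, "long_format_spec"))
  idx_key <- which(dictionary$variable_name == spec$key_variable &
                     dictionary$sheet_name == spec$sheet_name)
  idx_val <- which(dictionary$variable_name == spec$value_variable &
                     dictionary$sheet_name == spec$sheet_name)
  if (length(idx_key) != 1L || length(idx_val) != 1L) {
    warning("long-format variable pair ('", spec$key_variable, "', '",
            spec$value_variable, "') not found in sheet '", spec$sheet_name,
            "'; dictionary unchanged")
    return(dictionary)
  }
  if (!spec$key_variable %in% names(data_rows)) {
    stop("data_rows is missing the key column '", spec$key_variable, "'",
         call. = FALSE)
  }
  keys <- as.character(data_rows[[spec$key_variable]])
  keys <- unique(keys[!is.na(keys) & nzchar(keys)])
  if (!length(keys)) {
    warning("empty long-format sheet for '", spec$value_variable,
            "'; dictionary unchanged")
    return(dictionary)
  }
  num <- suppressWarnings(as.numeric(keys))
  keys <- if (!anyNA(num)) keys[order(num)] else sort(keys)
  safe <- gsub(sep, "-", keys, fixed = TRUE)
  if (any(safe != keys)) {
    warning("key value(s) containing the name separator '", sep,
            "' were sanitized: ",
            paste(keys[safe != keys], collapse = ", "))
  }
  template <- dictionary[idx_val, ]
  wide <- template[rep(1L, length(keys)), ]
  wide$variable_name <- paste0(spec$value_variable, sep, safe)
  wide$variable_label <- vapply(
    keys,
    function(k) gsub("{key}", k, spec$label_template, fixed = TRUE),
    character(1), USE.NAMES = FALSE)
  pos <- min(idx_key, idx_val)
  rest <- dictionary[-c(idx_key, idx_val), ]
  before <- rest[seq_len(pos - 1L), ]
  after <- if (pos <= nrow(rest)) rest[pos:nrow(rest), ] else rest[0, ]
  as_study_dictionary(dplyr::bind_rows(before, wide, after))
}
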