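#' Seeded character-trigram hashing embedder
#'
#' A deterministic, dependency-free sentence embedder: the text is
#' lowercased and padded, its character trigrams are hashed into `dim`
#' signed buckets, and the resulting count vector is L2-normalized.  Texts
#' sharing character n-grams (shared words, morphological variants,
#' abbreviations with common letters) receive high cosine similarity, so
#' the embedder behaves as a lexical-overlap similarity channel.  Distinct
#' seeds give distinct (weakly correlated) embedders, which stands in for a
#' set of heterogeneous pretrained sentence-embedding models when running
#' fully offline.  Pretrained transformer backends can be plugged in
#' through [embedding_backend()] instead.
#'
#' @param id Backend identifier (used in feature names, e.g.
#'   `"<id>_on_label"`).
#' @param dim Embedding dimension (default 256).
#' @param seed Small positive integer controlling the hash mixing.
#' @return An `embedding_backend` object.
#' @export
hash_embedder <- function(id = "hash", dim = 256L, seed = 1L) {
  stopifnot(dim >= 2L, seed >= 0L, seed < 1e6)
  structure(
    list(id = id, dim = as.integer(dim), seed = as.integer(seed),
         cache = new.env(parent = emptyenv())),
    class = c("hash_embedder", "embedding_backend"))
}

#' Wrap an arbitrary embedding function as a backend
#'
#' Adapter for user-supplied embedders (e.g. a function calling a local
#' sentence-transformer service).  Results are cached per distinct string
#' so each text is embedded once.
#'
#' @param id Backend identifier.
#' @param fn Function taking a character vector and returning a numeric
#'   matrix with one row per input text.
#' @param dim Embedding dimension returned by `fn`.
#' @return An `embedding_backend` object.
#' @export
embedding_backend <- function(id, fn, dim) {
  stopifnot(is.function(fn), dim >= 1L)
  structure(
    list(id = id, dim = as.integer(dim), fn = fn,
         cache = new.env(parent = emptyenv())),
    class = c("function_embedder", "embedding_backend"))
}

#' Default offline backend set
#'
#' Four independently seeded [hash_embedder()] backends, mirroring the
#' four-embedding-model + fuzzy-matching channel layout of the matching
#' pipeline without requiring any model download.
#'
#' @param dim Embedding dimension for every backend.
#' @return Named list of four `embedding_backend` objects.
#' @export
default_backends <- function(dim = 256L) {
  ids <- c("hash1", "hash2", "hash3", "hash4")
  seeds <- c(101L, 211L, 307L, 401L)
  out <- Map(function(i, s) hash_embedder(i, dim = dim, seed = s), ids, seeds)
  names(out) <- ids
  out
}

#' Embed texts with a backend
#'
#' One vector per input text, deterministic for a fixed backend, with
#' results cached by (backend, text) so each distinct string is embedded
#' once.  Empty strings map to the zero vector with a warning.
#'
#' @param texts Character vector.
#' @param backend An `embedding_backend`.
#' @return Numeric matrix, one row per text, `backend$dim` columns.
#' @export
embed_texts <- function(texts, backend) {
  if (!inherits(backend, "embedding_backend")) {
    stop("unknown backend; registered constructors: hash_embedder(), ",
         "embedding_backend()", call. = FALSE)
  }
  texts <- as.character(texts)
  texts[is.na(texts)] <- ""
  if (any(!nzchar(texts))) {
    warning("embedding empty text as the zero vector")
  }
  uniq <- unique(texts[nzchar(texts)])
  todo <- uniq[!vapply(uniq, exists, logical(1),
                       envir = backend$cache, inherits = FALSE)]
  if (length(todo)) {
    m <- compute_embeddings(backend, todo)
    for (i in seq_along(todo)) {
      assign(todo[i], m[i, ], envir = backend$cache)
    }
  }
  out <- matrix(0, length(texts), backend$dim)
  for (i in seq_along(texts)) {
    if (nzchar(texts[i])) {
      out[i, ] <- get(texts[i], envir = backend$cache, inherits = FALSE)
    }
  }
  out
}

compute_embeddings <- function(backend, texts) UseMethod("compute_embeddings")

#' @export
compute_embeddings.hash_embedder <- function(backend, texts) {
  m <- matrix(0, length(texts), backend$dim)
  for (i in seq_along(texts)) {
    m[i, ] <- hash_embed_one(texts[i], backend$dim, backend$seed)
  }
  m
}

#' @export
compute_embeddings.function_embedder <- function(backend, texts) {
  m <- backend$fn(texts)
  m <- as.matrix(m)
  if (nrow(m) != length(texts) || ncol(m) != backend$dim) {
    stop("backend '", backend$id, "' returned a ", nrow(m), "x", ncol(m),
         " matrix; expected ", length(texts), "x", backend$dim,
         call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("backend '", backend$id, "' returned non-finite values",
         call. = FALSE)
  }
  m
}

# signed trigram hashing; pure double arithmetic (< 2^53) so results are
# identical across platforms
hash_embed_one <- function(text, dim, seed) {
  s <- tolower(text)
  codes <- utf8ToInt(paste0(" ", s, " "))
  n <- length(codes)
  if (!nzchar(s) || n < 3L) return(numeric(dim))
  h <- 961 * codes[1:(n - 2L)] + 31 * codes[2:(n - 1L)] + codes[3:n]
  h <- (h * (2 * seed + 17) + 97003) %% 2147483647
  idx <- h %% dim + 1
  sgn <- ((h * 7919 + 13) %% 2147483647) %% 2
  v <- tabulate(idx[sgn == 1], dim) - tabulate(idx[sgn == 0], dim)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) numeric(dim) else v / nrm
}

row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Cosine similarity between two embedding vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return `dot(a, b) / (||a|| ||b||)`; 0 when either norm is 0.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("embedding dimension mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
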