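#' Construct an embedding space
#'
#' An `embedding_space` holds a fixed-dimension static word-vector table: an
#' ordered vocabulary and one real row vector per token. Lookups of tokens
#' absent from the vocabulary return a zero vector flagged as out-of-vocabulary
#' (OOV); this convention is what lets text vectors keep OOV tokens in the
#' averaging denominator.
#'
#' @param vectors Numeric matrix, one row per token; rownames are the
#'   vocabulary. Alternatively a matrix plus a `vocabulary` character vector.
#' @param vocabulary Character vector of unique tokens; defaults to
#'   `rownames(vectors)`.
#' @param source_tag Free-text label for the corpus or period the vectors were
#'   trained on.
#' @return An object of class `embedding_space` with fields `vocabulary`,
#'   `vectors`, `dimension` and `source_tag`.
#' @export
#' @examples
#' m <- rbind(run = c(1, 0), gym = c(0, 1))
#' sp <- embedding_space(m, source_tag = "toy")
#' sp$dimension
embedding_space <- function(vectors, vocabulary = rownames(vectors),
                            source_tag = "") {
  vectors <- as.matrix(vectors)
  if (is.null(vocabulary)) {
    stop("`vocabulary` must be supplied (or set as rownames of `vectors`)")
  }
  vocabulary <- as.character(vocabulary)
  if (length(vocabulary) != nrow(vectors)) {
    stop("vocabulary length (", length(vocabulary),
         ") does not match number of vector rows (", nrow(vectors), ")")
  }
  if (anyDuplicated(vocabulary)) {
    dup <- vocabulary[duplicated(vocabulary)][1L]
    stop("duplicate token in vocabulary: ", dup)
  }
  if (ncol(vectors) < 2L) stop("embedding dimension must be at least 2")
  if (!all(is.finite(vectors))) stop("embedding vectors must be finite")
  storage.mode(vectors) <- "double"
  rownames(vectors) <- vocabulary
  structure(
    list(vocabulary = vocabulary, vectors = vectors,
         dimension = ncol(vectors), source_tag = source_tag),
    class = "embedding_space"
  )
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("<embedding_space> ", length(x$vocabulary), " tokens, d = ",
      x$dimension,
      if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Read a word2vec-format text embedding file
#'
#' Reads the plain-text word2vec dialect: a header line `"<count> <dim>"`
#' followed by one `token v1 ... vd` line per word, space-separated, UTF-8.
#' Tokens may not contain whitespace. Vectors are used exactly as stored;
#' no re-normalisation is applied at load time.
#'
#' @param path Path to the embedding file.
#' @param source_tag Optional label recorded on the returned space; defaults
#'   to the file name.
#' @return An [embedding_space()].
#' @export
read_word2vec <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) stop("malformed header: file is empty")
  header <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    stop("malformed header: expected \"<count> <dim>\", got \"",
         lines[[1L]], "\"")
  }
  n <- as.integer(header[[1L]])
  d <- as.integer(header[[2L]])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop("header declares ", n, " tokens but file contains ", length(body))
  }
  parts <- strsplit(body, " +")
  arity <- lengths(parts)
  bad <- which(arity != d + 1L)
  if (length(bad)) {
    stop("row arity error at line ", bad[[1L]] + 1L, ": expected ", d,
         " values for token \"", parts[[bad[[1L]]]][1L], "\", found ",
         arity[[bad[[1L]]]] - 1L)
  }
  vocab <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(vocab)) {
    stop("duplicate token in embedding file: ",
         vocab[duplicated(vocab)][1L])
  }
  vec <- matrix(
    as.numeric(unlist(lapply(parts, `[`, -1L), use.names = FALSE)),
    nrow = n, ncol = d, byrow = TRUE
  )
  if (anyNA(vec)) stop("non-numeric vector entry in embedding file")
  embedding_space(vec, vocab, source_tag = source_tag)
}

#' Write an embedding space in word2vec text format
#'
#' Inverse of [read_word2vec()]: writes the `"<count> <dim>"` header and one
#' space-separated row per token. A written-then-reloaded space reproduces
#' vocabulary order and (to the printed precision) the vectors.
#'
#' @param space An [embedding_space()].
#' @param path Output file path.
#' @param digits Significant digits used when printing vector entries.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(space, path, digits = 8) {
  stopifnot(inherits(space, "embedding_space"))
  rows <- apply(space$vectors, 1L, function(v) {
    paste(format(v, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste(length(space$vocabulary), space$dimension),
               paste(space$vocabulary, rows)), con)
  invisible(path)
}

#' Look up token vectors with an explicit OOV flag
#'
#' Total lookup function: every token maps to a length-d vector. Tokens in the
#' vocabulary return their stored row; any other string (including `""`)
#' returns the zero vector and is flagged out-of-vocabulary.
#'
#' @param space An [embedding_space()].
#' @param tokens Character vector of tokens.
#' @return A list with `vectors` (matrix, one row per input token) and
#'   `in_vocab` (logical vector).
#' @export
embed_tokens <- function(space, tokens) {
  stopifnot(inherits(space, "embedding_space"))
  tokens <- as.character(tokens)
  idx <- match(tokens, space$vocabulary)
  out <- matrix(0, nrow = length(tokens), ncol = space$dimension)
  hit <- !is.na(idx)
  if (any(hit)) out[hit, ] <- space$vectors[idx[hit], , drop = FALSE]
  rownames(out) <- tokens
  list(vectors = out, in_vocab = hit)
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length; both must have nonzero norm.
#' @return Cosine similarity in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1)) # sqrt(2)/2
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for a zero-norm vector")
  }
  s <- sum(u * v) / (nu * nv)
  # guard rounding just past +/-1
  max(-1, min(1, s))
}

#' Nearest neighbours of a token by cosine similarity
#'
#' Ranks every other vocabulary token by descending cosine similarity to the
#' query token's vector. Ties are broken by vocabulary order so the ranking is
#' deterministic.
#'
#' @param space An [embedding_space()].
#' @param token Query token; must be in the vocabulary.
#' @param k Number of neighbours requested; capped at `|vocab| - 1`.
#' @return A tibble with columns `token`, `similarity`, `rank`.
#' @export
nearest_neighbors <- function(space, token, k = 10) {
  stopifnot(inherits(space, "embedding_space"))
  idx <- match(token, space$vocabulary)
  if (is.na(idx)) stop("query token not in vocabulary: ", token)
  q <- space$vectors[idx, ]
  qn <- sqrt(sum(q^2))
  if (qn == 0) stop("query token has a zero vector: ", token)
  norms <- sqrt(rowSums(space$vectors^2))
  sims <- as.numeric(space$vectors %*% q) / (norms * qn)
  sims[norms == 0] <- -Inf
  sims[idx] <- -Inf # exclude the query itself
  ord <- order(-sims, seq_along(sims))
  keep <- ord[seq_len(min(k, length(sims) - 1L))]
  tibble::tibble(
    token = space$vocabulary[keep],
    similarity = sims[keep],
    rank = seq_along(keep)
  )
}
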