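#' Generate synthetic word embeddings
#'
#' Draws one unit vector per word: an isotropic random direction, optionally
#' blended with a shared component so that the expected pairwise cosine
#' similarity equals `similarity`. Vectors are unit-norm. These stand in for
#' distributional (Skip-gram-style) embeddings so the decoding pipeline can
#' run without any download; real vectors in word2vec text format can be
#' loaded with [load_embeddings()].
#'
#' @param words Character vector of unique word tokens.
#' @param d Embedding dimension (default 300).
#' @param seed Integer seed; tables are deterministic given the seed.
#' @param similarity Target mean pairwise cosine similarity in `[0, 1)`
#'   (default 0, isotropic).
#' @return An object of class `embedding_table`: a list with `words`, `d`,
#'   and `vectors` (a `length(words) x d` matrix with words as row names).
#' @examples
#' emb <- make_embeddings(c("bag", "bell", "red"), d = 50, seed = 1)
#' rowSums(emb$vectors^2)  # all 1
#' @export
make_embeddings <- function(words, d = 300L, seed, similarity = 0) {
  words <- as.character(words)
  if (length(words) == 0L || anyDuplicated(words) || any(!nzchar(words))) {
    stop("`words` must be non-empty, non-blank, and unique", call. = FALSE)
  }
  stopifnot_scalar_number(d, "d", lower = 2)
  stopifnot_scalar_number(similarity, "similarity", lower = 0, upper = 1 - 1e-9)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  d <- as.integer(d)
  with_seed(seed, {
    shared <- stats::rnorm(d)
    shared <- shared / sqrt(sum(shared^2))
    a <- sqrt(similarity)
    vec <- t(vapply(words, function(w) {
      z <- stats::rnorm(d)
      # remove the shared component so the blend weights are exact
      z <- z - sum(z * shared) * shared
      z <- z / sqrt(sum(z^2))
      v <- a * shared + sqrt(1 - a^2) * z
      v / sqrt(sum(v^2))
    }, numeric(d)))
    rownames(vec) <- words
    structure(list(words = words, d = d, vectors = vec),
              class = "embedding_table")
  })
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d words, d = %d>\n", length(x$words), x$d))
  cat("  words:", paste(utils::head(x$words, 10L), collapse = ", "),
      if (length(x$words) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Load word embeddings from a word2vec text file
#'
#' Reads the plain-text word2vec format: a header line `"<count> <dim>"`
#' followed by one line per word, `"<word> <v1> ... <vd>"`.
#'
#' @param path File path.
#' @param words Optional character vector restricting (and ordering) the
#'   vocabulary; an error is raised if any requested word is absent.
#' @return An `embedding_table`.
#' @seealso [write_embeddings()] for the inverse.
#' @export
load_embeddings <- function(path, words = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("not a word2vec text file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(header) != 2L) stop("malformed word2vec header line", call. = FALSE)
  d <- as.integer(header[[2L]])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "\\s+")
  vocab <- vapply(toks, `[[`, character(1L), 1L)
  if (anyDuplicated(vocab)) {
    stop("duplicate word in embedding file: ",
         vocab[duplicated(vocab)][1L], call. = FALSE)
  }
  bad <- which(lengths(toks) != d + 1L)
  if (length(bad)) {
    stop(sprintf("malformed vector line %d: expected %d values", bad[1L] + 1L, d),
         call. = FALSE)
  }
  vec <- t(vapply(toks, function(tk) {
    v <- suppressWarnings(as.numeric(tk[-1L]))
    if (anyNA(v)) stop("malformed vector line (non-numeric value)", call. = FALSE)
    v
  }, numeric(d)))
  rownames(vec) <- vocab
  if (!is.null(words)) {
    missing_w <- setdiff(words, vocab)
    if (length(missing_w)) {
      stop("vocabulary word(s) missing from file: ",
           paste(missing_w, collapse = ", "), call. = FALSE)
    }
    vec <- vec[words, , drop = FALSE]
    vocab <- words
  }
  if (!all(is.finite(vec))) stop("non-finite embedding values", call. = FALSE)
  structure(list(words = vocab, d = d, vectors = vec), class = "embedding_table")
}

#' Write an embedding table in word2vec text format
#'
#' @param emb An `embedding_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(emb$words), emb$d), con)
  for (i in seq_along(emb$words)) {
    writeLines(paste(c(emb$words[[i]],
                       format(emb$vectors[i, ], digits = 17L, scientific = TRUE,
                              trim = TRUE)), collapse = " "), con)
  }
  invisible(path)
}

#' Cosine distance between two vectors
#'
#' `1 - cos(u, v)`; the 2-vs-2 test's default distance. Errors on zero-norm
#' input, for which cosine distance is undefined.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single number in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for zero-norm vector",
                               call. = FALSE)
  1 - sum(u * v) / (nu * nv)
}
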