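# Word-vector models: plain-text format I/O, cosine similarity and exact
# nearest-neighbour queries.

#' Construct a word-vector model
#'
#' @param vectors numeric matrix, one row per token, with row names giving
#'   the vocabulary.
#' @return object of class `medlex_vectors` with fields `dim`, `vocab` and
#'   the row-normalized matrix used for cosine queries.
#' @export
vector_model <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  if (is.null(rownames(vectors)) || anyDuplicated(rownames(vectors)))
    stop("vectors must have unique row names (the vocabulary)")
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0))
    stop("zero vector for token(s): ",
         paste(rownames(vectors)[norms == 0], collapse = ", "))
  structure(list(dim = ncol(vectors), vocab = rownames(vectors),
                 vectors = vectors, unit = vectors / norms),
            class = "medlex_vectors")
}

#' @export
print.medlex_vectors <- function(x, ...) {
  cat(sprintf("<medlex_vectors> %d tokens, dim %d\n",
              length(x$vocab), x$dim))
  invisible(x)
}

#' Read word vectors in the plain-text format
#'
#' The standard textual format: a header line `vocab_size dim`, then one line
#' per token with the token followed by `dim` floats, space-separated.
#'
#' @param path file path.
#' @return a `medlex_vectors` model.
#' @export
read_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty vector file: ", path)
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(header) != 2L || anyNA(header))
    stop("malformed vector-file header: '", lines[1], "'")
  n <- header[1]; d <- header[2]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop("vector file declares ", n, " tokens but has ", length(body))
  parts <- strsplit(trimws(body), " ", fixed = TRUE)
  tokens <- vapply(parts, `[`, character(1), 1)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(mat) <- nfc(tokens)
  vector_model(mat)
}

#' Write word vectors in the plain-text format
#'
#' Deterministic: tokens are written in the model's stored order with a fixed
#' number of decimals, so identical models produce byte-identical files.
#'
#' @param model a `medlex_vectors`.
#' @param path output path.
#' @param digits decimals per component.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(model, path, digits = 6L) {
  mat <- model$vectors
  vals <- apply(mat, 1, function(r)
    paste(formatC(r, digits = digits, format = "f"), collapse = " "))
  lines <- c(paste(nrow(mat), ncol(mat)),
             paste(rownames(mat), vals))
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Cosine similarity between two vectors
#'
#' `dot(s, w) / (||s|| * ||w||)`: 1 means the directions (and hence the
#' distributional meanings) coincide, 0 means the vectors are orthogonal.
#'
#' @param s,w numeric vectors of equal length, both non-zero.
#' @return similarity in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0))  # 0.7071
cosine_similarity <- function(s, w) {
  if (length(s) != length(w))
    stop("vectors have different lengths (", length(s), " vs ", length(w), ")")
  ns <- sqrt(sum(s^2)); nw <- sqrt(sum(w^2))
  if (ns == 0 || nw == 0)
    stop("undefined similarity: zero vector")
  sum(s * w) / (ns * nw)
}

#' Exact nearest neighbours of a term by cosine similarity
#'
#' Scores the whole vocabulary against the query vector and returns the
#' `k` highest-similarity tokens, the query itself excluded.  Ties are broken
#' by codepoint order of the token.
#'
#' @param model a `medlex_vectors`.
#' @param term query token (must be in the vocabulary).
#' @param k retrieval depth (default 50); at most `vocab - 1` hits exist.
#' @return data.frame with columns `token`, `similarity`, sorted descending.
#' @export
nearest_neighbors <- function(model, term, k = 50L) {
  stopifnot(k >= 1)
  term <- nfc(term)
  if (!term %in% model$vocab)
    stop("out-of-vocabulary query term: '", term, "'")
  sims <- drop(model$unit %*% model$unit[term, ])
  sims <- sims[names(sims) != term]
  ord <- order(-sims, names(sims), method = "radix")
  top <- ord[seq_len(min(k, length(sims)))]
  data.frame(token = names(sims)[top], similarity = unname(sims[top]),
             stringsAsFactors = FALSE)
}
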