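PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"

#' Build a vocabulary from training documents
#'
#' Tokens are included when they occur in at least `min_df` training
#' documents (document frequency, not raw count). Indices 1 and 2 are
#' reserved for the padding and unknown-word tokens.
#'
#' @param docs List of `clean_document`s — the training split only.
#' @param min_df Minimum document frequency for inclusion (default 2).
#' @return An object of class `rob_vocab`: list with `index` (token ->
#'   integer map as a named integer vector), `tokens` (index -> token),
#'   `df` (document frequencies of retained tokens) and `n_docs`.
#' @export
build_vocabulary <- function(docs, min_df = 2L) {
  stopifnot(length(docs) > 0)
  df <- new.env(hash = TRUE, parent = emptyenv())
  for (d in docs) {
    for (tok in unique(doc_tokens(d))) {
      df[[tok]] <- (if (is.null(df[[tok]])) 0L else df[[tok]]) + 1L
    }
  }
  toks <- ls(df)
  counts <- vapply(toks, function(t) df[[t]], 1L)
  keep <- counts >= min_df
  toks <- sort(toks[keep])
  counts <- vapply(toks, function(t) df[[t]], 1L)
  tokens <- c(PAD_TOKEN, UNK_TOKEN, toks)
  structure(
    list(index = setNames(seq_along(tokens), tokens), tokens = tokens,
         df = setNames(counts, toks), n_docs = length(docs)),
    class = "rob_vocab"
  )
}

#' @exportS3Method base::print
print.rob_vocab <- function(x, ...) {
  cat(sprintf("<rob_vocab: %d tokens (+pad/unk), built from %d documents>\n",
              length(x$tokens) - 2L, x$n_docs))
  invisible(x)
}

vocab_lookup <- function(vocab, tokens) {
  idx <- vocab$index[tokens]
  idx[is.na(idx)] <- vocab$index[[UNK_TOKEN]]
  unname(idx)
}

#' Random embedding table for a vocabulary
#'
#' Rows are Gaussian with standard deviation `1/sqrt(dim)`, giving
#' approximately unit-norm vectors (the typical scale of pretrained word
#' vectors); the padding row is all zeros and the unknown-word row is a
#' single shared zero vector.
#'
#' @param vocab A `rob_vocab`.
#' @param dim Embedding dimension (default 200).
#' @param seed Integer seed.
#' @return A `|V| x dim` numeric matrix with tokens as row names.
#' @export
random_embedding_table <- function(vocab, dim = 200L, seed = 1L) {
  stopifnot(dim >= 1)
  set.seed(as.integer(seed))
  n <- length(vocab$tokens)
  mat <- matrix(rnorm(n * dim, 0, 1 / sqrt(dim)), nrow = n)
  rownames(mat) <- vocab$tokens
  mat[PAD_TOKEN, ] <- 0
  mat[UNK_TOKEN, ] <- 0
  mat
}

#' Read a word2vec text-format embedding file
#'
#' Format: a header line `"V d"`, then one line per token: the token
#' followed by `d` floats. Padding/unknown rows are prepended if absent.
#'
#' @param path File path.
#' @return Numeric matrix with tokens as row names (including `<pad>` and
#'   `<unk>`).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  stopifnot(length(hdr) == 2)
  v <- hdr[1]; d <- hdr[2]
  body <- lines[1 + seq_len(v)]
  parts <- strsplit(trimws(body), "\\s+")
  toks <- vapply(parts, `[[`, "", 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(mat) <- toks
  for (special in c(UNK_TOKEN, PAD_TOKEN)) {
    if (!special %in% toks) {
      mat <- rbind(matrix(0, 1, d, dimnames = list(special)), mat)
    }
  }
  mat[PAD_TOKEN, ] <- 0
  mat
}

#' Write an embedding table in word2vec text format
#' @param mat Numeric matrix with tokens as row names.
#' @param path Output path.
#' @export
write_word2vec <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(rownames(mat)[i],
                     paste(formatC(mat[i, ], format = "g", digits = 8),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Align an embedding table to a vocabulary
#'
#' Returns a matrix with one row per vocabulary entry, in vocabulary order;
#' vocabulary tokens missing from the table get the shared unknown-word row.
#'
#' @param mat Embedding matrix with token row names.
#' @param vocab A `rob_vocab`.
#' @return `|V| x d` matrix in vocabulary order.
#' @export
align_embeddings <- function(mat, vocab) {
  d <- ncol(mat)
  out <- matrix(0, length(vocab$tokens), d)
  rownames(out) <- vocab$tokens
  hit <- vocab$tokens %in% rownames(mat)
  out[hit, ] <- mat[vocab$tokens[hit], , drop = FALSE]
  if (any(!hit) && UNK_TOKEN %in% rownames(mat)) {
    out[!hit, ] <- matrix(mat[UNK_TOKEN, ], sum(!hit), d, byrow = TRUE)
  }
  out[PAD_TOKEN, ] <- 0
  out
}
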