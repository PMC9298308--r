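#' Fit TF-IDF statistics on the training split
#'
#' Computes document frequencies over the training documents only. Terms
#' must occur in at least `min_df` training documents to enter the feature
#' space.
#'
#' @param train_docs List of `clean_document`s (training split only).
#' @param min_df Minimum document frequency (default 2).
#' @return List with `terms`, `df` (named integer vector) and `n_docs`.
#' @export
tfidf_fit <- function(train_docs, min_df = 2L) {
  if (length(train_docs) == 0) stop("empty training set (N = 0)")
  vocab <- build_vocabulary(train_docs, min_df = min_df)
  list(terms = names(vocab$df), df = vocab$df, n_docs = vocab$n_docs)
}

#' TF-IDF vector for one document
#'
#' `weight(t, d) = tf(t, d) * ln(N / df(t))`, where `tf` is the raw count of
#' term `t` in the document, `N` the number of training documents and `df`
#' the number of training documents containing `t`. Terms absent from the
#' training vocabulary are dropped. No smoothing is applied (a term present
#' in every training document gets weight 0); optional l2 normalisation.
#'
#' @param doc A `clean_document`.
#' @param stats Output of [tfidf_fit()].
#' @param normalize `"none"` (default) or `"l2"`.
#' @return A sparse numeric vector ([Matrix::sparseVector]) of length
#'   `length(stats$terms)`, in `stats$terms` order.
#' @export
tfidf_vectorize <- function(doc, stats, normalize = c("none", "l2")) {
  normalize <- match.arg(normalize)
  if (stats$n_docs == 0) stop("empty training set (N = 0)")
  toks <- doc_tokens(doc)
  tab <- table(toks[toks %in% stats$terms])
  idx <- match(names(tab), stats$terms)
  w <- as.numeric(tab) * log(stats$n_docs / stats$df[names(tab)])
  nz <- w != 0
  v <- Matrix::sparseVector(w[nz], i = idx[nz], length = length(stats$terms))
  if (normalize == "l2") {
    nrm <- sqrt(sum(v@x^2))
    if (nrm > 0) v@x <- v@x / nrm
  }
  v
}

#' TF-IDF document-term matrix
#'
#' @param docs List of `clean_document`s.
#' @param stats Output of [tfidf_fit()].
#' @param normalize Passed to [tfidf_vectorize()].
#' @return Sparse `length(docs) x n_terms` matrix (dgCMatrix), rows named by
#'   doc_id.
#' @export
tfidf_matrix <- function(docs, stats, normalize = "none") {
  vecs <- lapply(docs, tfidf_vectorize, stats = stats, normalize = normalize)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (r in seq_along(vecs)) {
    v <- vecs[[r]]
    i <- c(i, rep.int(r, length(v@i)))
    j <- c(j, as.integer(v@i))
    x <- c(x, as.numeric(v@x))
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(docs), length(stats$terms)))
  rownames(m) <- vapply(docs, function(d) d$doc_id, "")
  colnames(m) <- stats$terms
  m
}

#' Map a document to a fixed-size embedding matrix
#'
#' The first `min(s, s_max)` rows are embedding-table lookups of the
#' document's tokens in order (out-of-vocabulary tokens use the shared
#' unknown-word row); remaining rows are zero padding; tokens beyond
#' `s_max` are truncated.
#'
#' @param doc A `clean_document`.
#' @param table Embedding matrix with token row names (`<pad>` row zero).
#' @param s_max Maximum document length in tokens (default 5000, roughly
#'   the corpus-average full-text length).
#' @return `s_max x d` numeric matrix with attribute `n_tokens` = number of
#'   non-padding rows.
#' @export
embed_document <- function(doc, table, s_max = 5000L) {
  stopifnot(s_max >= 1)
  d <- ncol(table)
  toks <- doc_tokens(doc)
  s <- min(length(toks), s_max)
  out <- matrix(0, s_max, d)
  if (s > 0) {
    toks <- toks[seq_len(s)]
    hit <- toks %in% rownames(table)
    toks[!hit] <- UNK_TOKEN
    out[seq_len(s), ] <- table[toks, , drop = FALSE]
  }
  attr(out, "n_tokens") <- s
  out
}

embed_tokens <- function(tokens, table) {
  if (length(tokens) == 0) return(matrix(0, 0, ncol(table)))
  hit <- tokens %in% rownames(table)
  tokens[!hit] <- UNK_TOKEN
  table[tokens, , drop = FALSE]
}

#' Train paragraph vectors (distributed-memory + distributed bag-of-words)
#'
#' Learns a dense vector per document as the concatenation of two
#' paragraph-vector variants: distributed memory (the document vector plus
#' the mean of a sliding context window predicts the centre word) and
#' distributed bag-of-words (the document vector alone predicts each of the
#' document's words). Both use negative sampling against frozen, seeded
#' random word projections, which makes the per-document objective convex:
#' inference is deterministic and identical documents receive identical
#' vectors. The same inference routine embeds unseen documents
#' ([infer_doc_vector()]).
#'
#' @param corpus List of `clean_document`s.
#' @param dim_dm Distributed-memory dimension (default 100).
#' @param dim_dbow Distributed bag-of-words dimension (default 100).
#' @param seed Integer seed.
#' @param epochs Gradient passes per document (default 20).
#' @param lr Learning rate (default 0.05).
#' @param window Context window for the distributed-memory variant.
#' @param n_neg Negative samples per positive word.
#' @param min_df Vocabulary minimum document frequency.
#' @return List with `vectors` (named doc_id -> numeric vector of length
#'   `dim_dm + dim_dbow`) and `model` (frozen projections, reusable via
#'   [infer_doc_vector()]).
#' @export
train_doc_vectors <- function(corpus, dim_dm = 100L, dim_dbow = 100L,
                              seed = 1L, epochs = 20L, lr = 0.05,
                              window = 4L, n_neg = 5L, min_df = 2L) {
  if (length(corpus) == 0) stop("empty corpus")
  if (dim_dm <= 0 || dim_dbow <= 0) stop("dimensions must be positive")
  vocab <- build_vocabulary(corpus, min_df = min_df)
  nv <- length(vocab$tokens)
  set.seed(as.integer(seed))
  model <- list(
    vocab = vocab, dim_dm = dim_dm, dim_dbow = dim_dbow,
    epochs = epochs, lr = lr, window = window, n_neg = n_neg,
    seed = as.integer(seed),
    word_in = matrix(rnorm(nv * dim_dm, 0, 1 / sqrt(dim_dm)), nv),
    out_dm = matrix(rnorm(nv * dim_dm, 0, 1 / sqrt(dim_dm)), nv),
    out_dbow = matrix(rnorm(nv * dim_dbow, 0, 1 / sqrt(dim_dbow)), nv)
  )
  vecs <- lapply(corpus, function(d) infer_doc_vector(d, model))
  names(vecs) <- vapply(corpus, function(d) d$doc_id, "")
  list(vectors = vecs, model = model)
}

#' Infer the paragraph vector of a (possibly unseen) document
#'
#' @param doc A `clean_document`.
#' @param model The `model` component returned by [train_doc_vectors()].
#' @return Numeric vector of length `dim_dm + dim_dbow`.
#' @export
infer_doc_vector <- function(doc, model) {
  ids <- vocab_lookup(model$vocab, doc_tokens(doc))
  ids <- ids[ids > 2L]  # drop pad/unk from the objective
  nv <- length(model$vocab$tokens)
  sgd <- function(dim, out, use_ctx) {
    v <- numeric(dim)
    if (length(ids) == 0) return(v)
    # deterministic negatives: seeded from content so duplicates agree
    set.seed((sum(ids) + length(ids)) %% .Machine$integer.max)
    negs <- matrix(sample.int(nv - 2L, length(ids) * model$n_neg *
                                model$epochs, replace = TRUE) + 2L,
                   ncol = model$n_neg)
    row <- 0L
    for (ep in seq_len(model$epochs)) {
      for (t in seq_along(ids)) {
        row <- row + 1L
        ctx <- if (use_ctx) {
          lo <- max(1L, t - model$window); hi <- min(length(ids), t + model$window)
          win <- setdiff(lo:hi, t)
          if (length(win) > 0)
            colMeans(model$word_in[ids[win], , drop = FALSE]) else numeric(dim)
        } else numeric(dim)
        h <- v + ctx
        tgt <- c(ids[t], negs[row, ])
        lab <- c(1, numeric(model$n_neg))
        u <- out[tgt, , drop = FALSE]
        g <- (plogis(drop(u %*% h)) - lab)  # d loss / d score
        v <- v - model$lr * drop(crossprod(u, g))
      }
    }
    v
  }
  c(sgd(model$dim_dm, model$out_dm, use_ctx = TRUE),
    sgd(model$dim_dbow, model$out_dbow, use_ctx = FALSE))
}

#' Write document vectors as TSV (doc_id + floats)
#' @param vectors Named list of numeric vectors.
#' @param path Output path.
#' @export
write_doc_vectors <- function(vectors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(vectors)) {
    writeLines(paste(c(id, formatC(vectors[[id]], format = "g", digits = 8)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
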