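#' Rank a document's sentences by HAN sentence attention
#'
#' Runs the trained hierarchical attention network and returns the
#' sentences sorted by their sentence-level attention score, descending —
#' the model's own evidence ranking for human verification.
#'
#' @param doc A `clean_document`.
#' @param model A trained `neural_model` of type `"han"`.
#' @return Data frame with `index`, `text`, `score` (attention weights,
#'   summing to 1 over the scored sentences), sorted by score.
#' @export
rank_sentences <- function(doc, model) {
  stopifnot(inherits(model, "neural_model"), model$type == "han")
  if (is.null(model$history)) stop("model has not been trained")
  rep <- doc_representation(model, doc)
  fw <- han_forward(rep, model$spec, model$weights)
  scores <- fw$sentence_attention
  n <- length(scores)
  ord <- order(-scores, seq_len(n))
  data.frame(
    index = ord,
    text = vapply(doc$sentences[ord], paste, "", collapse = " "),
    score = scores[ord],
    stringsAsFactors = FALSE
  )
}

#' Corpus-level word importance from attention
#'
#' Averages per-token attention weights of the recurrent attention model
#' over positive-labelled documents. Each document's attention profile is
#' already normalised (weights sum to 1), so long documents do not
#' dominate. A token's per-document score is the total attention mass it
#' receives in that document; its importance is the mean of this score over
#' the positive documents that contain it (documents without the token
#' contribute nothing to its average).
#'
#' @param positive_docs List of `clean_document`s labelled 1 for the item.
#' @param model A trained `neural_model` of type `"rnn"`.
#' @param top_n Number of rows in the returned ranking (default 50; use
#'   `Inf` for all).
#' @param drop_stopwords Filter a small English stop-word list from the
#'   displayed ranking (the underlying weights are untouched).
#' @return A `word_importance` object: data frame with `token`,
#'   `mean_weight`, `rank`.
#' @export
word_importance <- function(positive_docs, model, top_n = 50L,
                            drop_stopwords = FALSE) {
  stopifnot(inherits(model, "neural_model"), model$type == "rnn")
  if (length(positive_docs) == 0) {
    stop("word importance needs at least one positive document")
  }
  sums <- new.env(hash = TRUE, parent = emptyenv())
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (doc in positive_docs) {
    rep <- doc_representation(model, doc)
    fw <- rnn_attention_forward(rep, model$spec, model$weights)
    toks <- head(doc_tokens(doc), length(fw$attention))
    if (length(toks) == 0) next
    mass <- tapply(fw$attention[seq_along(toks)], toks, sum)
    for (tok in names(mass)) {
      sums[[tok]] <- (if (is.null(sums[[tok]])) 0 else sums[[tok]]) +
        mass[[tok]]
      counts[[tok]] <- (if (is.null(counts[[tok]])) 0L else counts[[tok]]) + 1L
    }
  }
  toks <- ls(sums, all.names = TRUE)  # all.names: "." is a real token
  w <- vapply(toks, function(t) sums[[t]] / counts[[t]], 0)
  if (drop_stopwords) {
    stop_list <- c("the", "a", "an", "and", "or", "of", "in", "on", "to",
                   "was", "were", "is", "are", "for", "with", "by", "at",
                   "from", "that", "this", "it", ".", ",")
    keep <- !(toks %in% stop_list)
    toks <- toks[keep]; w <- w[keep]
  }
  ord <- order(-w, toks)
  out <- data.frame(token = toks[ord], mean_weight = unname(w[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  out <- head(out, top_n)
  class(out) <- c("word_importance", class(out))
  out
}

#' Write word importance as TSV (token, mean_weight, rank)
#' @param wi A `word_importance` data frame.
#' @param path Output path.
#' @export
write_word_importance <- function(wi, path) {
  utils::write.table(wi, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write evidence records (prediction + top sentences) as JSONL
#'
#' One object per document:
#' `{"doc_id","item","probability","top_sentences":[...]}`.
#'
#' @param records List of lists with `doc_id`, `item`, `probability`,
#'   `top_sentences` (data frame from [rank_sentences()]).
#' @param path Output path.
#' @export
write_evidence_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, dataframe = "rows",
                                digits = NA), con)
  }
  invisible(path)
}
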