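#' Clean raw article text
#'
#' Applies, in order, the cleaning rules used to prepare full texts for
#' classification:
#' 1. drop all text preceding the first heading line consisting of optional
#'    numbering plus "introduction" (case-insensitive); if no such heading
#'    exists the document is kept whole (front matter is never guessed away,
#'    since e.g. conflict-of-interest statements can live there);
#' 2. truncate at the last heading line matching "references" /
#'    "bibliography" (the heading itself and everything after it is removed);
#' 3. remove URLs (`http(s)://...`, `www....`, up to the next whitespace);
#' 4. remove in-text citation markers: bracketed numeric runs like `[3]`,
#'    `[1, 4-6]`, and parenthesised author-year groups like `(Smith, 2010)`;
#' 5. remove digits;
#' 6. remove non-ASCII characters;
#' 7. lower-case and collapse all whitespace runs to single spaces.
#'
#' The exact regular expressions are this package's own declared
#' approximations. The function is idempotent: applying it twice gives the
#' same result as applying it once.
#'
#' @param raw A character scalar (possibly empty).
#' @return A cleaned character scalar.
#' @examples
#' clean_text("Title page\nIntroduction\nWe studied 12 rats.")
#' @export
clean_text <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1)
  if (is.na(raw) || !nzchar(raw)) return("")

  lines <- strsplit(raw, "\r?\n", perl = TRUE)[[1]]
  heading <- function(pat) {
    grep(sprintf("^\\s*(?:[0-9]+[.)]?\\s*)?%s\\s*:?\\s*$", pat),
         lines, ignore.case = TRUE, perl = TRUE)
  }
  intro <- heading("introduction")
  if (length(intro) > 0) lines <- lines[intro[1]:length(lines)]
  refs <- heading("(?:references|bibliography)")
  if (length(refs) > 0) {
    last <- refs[length(refs)]
    lines <- if (last == 1) character(0) else lines[1:(last - 1)]
  }
  x <- paste(lines, collapse = " ")

  x <- gsub("(?i)\\b(?:https?://|www\\.)\\S*", " ", x, perl = TRUE)
  # bracketed numeric citations: [3], [1, 4-6], [2;7]
  x <- gsub("\\[[0-9][0-9,;\\s–-]*\\]", " ", x, perl = TRUE)
  # parenthesised author-year citations: (Smith, 2010; Jones et al., 2011b)
  x <- gsub("\\((?:[^()0-9]*\\b(?:1[789]|20)[0-9]{2}[a-z]?\\b[^()]*)\\)",
            " ", x, perl = TRUE)
  x <- gsub("[0-9]+", " ", x)
  x <- gsub("[^\\x01-\\x7F]", " ", x, perl = TRUE)
  x <- tolower(x)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Tokenize cleaned text into sentences of word tokens
#'
#' Deterministic rule-based segmentation: sentences are split after
#' `.`, `!` or `?` followed by whitespace; within a sentence, punctuation
#' characters are separated into their own tokens and tokens are split on
#' whitespace. Concatenating the per-sentence token lists reproduces the
#' document's token stream.
#'
#' @param cleaned A character scalar, normally the output of [clean_text()].
#' @return A list of character vectors, one per sentence (empty list for
#'   empty input).
#' @examples
#' tokenize("the rat ran. it stopped.")
#' @export
tokenize <- function(cleaned) {
  stopifnot(is.character(cleaned), length(cleaned) == 1)
  if (is.na(cleaned) || !nzchar(trimws(cleaned))) return(list())
  sents <- strsplit(cleaned, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  sents <- sents[nzchar(trimws(sents))]
  out <- lapply(sents, function(s) {
    s <- gsub("([[:punct:]])", " \\1 ", s)
    toks <- strsplit(trimws(s), "\\s+", perl = TRUE)[[1]]
    toks[nzchar(toks)]
  })
  out[vapply(out, length, 1L) > 0]
}

#' Construct a cleaned, tokenized document
#'
#' @param doc_id Unique document identifier.
#' @param sentences List of character vectors (lower-case tokens), as from
#'   [tokenize()].
#' @param labels Named integer vector (0/1/NA) keyed by risk-of-bias item.
#' @return An object of class `clean_document` with fields `doc_id`,
#'   `sentences`, `n_tokens` and `labels`.
#' @export
clean_document <- function(doc_id, sentences, labels = integer(0)) {
  stopifnot(is.character(doc_id), length(doc_id) == 1, nzchar(doc_id))
  stopifnot(is.list(sentences))
  toks <- unlist(sentences, use.names = FALSE)
  if (length(toks) > 0) {
    if (any(grepl("[0-9]", toks))) stop("tokens must not contain digits")
    if (any(grepl("[^\\x01-\\x7F]", toks, perl = TRUE)))
      stop("tokens must be ASCII")
  }
  structure(
    list(doc_id = doc_id, sentences = sentences,
         n_tokens = length(toks), labels = labels),
    class = "clean_document"
  )
}

#' @exportS3Method base::print
print.clean_document <- function(x, ...) {
  cat(sprintf("<clean_document %s: %d sentences, %d tokens>\n",
              x$doc_id, length(x$sentences), x$n_tokens))
  invisible(x)
}

#' Clean and tokenize a raw document
#'
#' @param doc_id Document identifier.
#' @param text Raw article text.
#' @param labels Named 0/1/NA labels.
#' @return A `clean_document`.
#' @export
preprocess_document <- function(doc_id, text, labels = integer(0)) {
  clean_document(doc_id, tokenize(clean_text(text)), labels)
}

doc_tokens <- function(doc) unlist(doc$sentences, use.names = FALSE)

#' Randomly split documents into train/validation/test sets
#'
#' Sizes are exact: the training set gets `floor(ratios[1] * n)` documents,
#' validation `floor(ratios[2] * n)`, and the test set the remainder (so for
#' 7089 documents with the default ratios the sizes are 5671/708/710, and
#' for 7840 they are 6272/784/784).
#'
#' @param docs List of `clean_document` objects.
#' @param ratios Numeric length-3 vector summing to 1 (train, valid, test).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return An object of class `rob_corpus`: a list with `documents` (named
#'   by doc_id) and `split` (named character vector, values in
#'   `c("train","valid","test")`).
#' @export
split_corpus <- function(docs, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  n <- length(docs)
  if (n < 3) stop("degenerate corpus: need at least 3 documents to split")
  ids <- vapply(docs, function(d) d$doc_id, "")
  if (anyDuplicated(ids)) stop("duplicate doc_ids in corpus")
  n_train <- floor(ratios[1] * n + 1e-9)
  n_valid <- floor(ratios[2] * n + 1e-9)
  n_test <- n - n_train - n_valid
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_valid)]] <- "valid"
  split[perm[n_train + n_valid + seq_len(n_test)]] <- "test"
  names(split) <- ids
  structure(list(documents = setNames(docs, ids), split = split),
            class = "rob_corpus")
}

#' @exportS3Method base::print
print.rob_corpus <- function(x, ...) {
  tab <- table(factor(x$split, levels = c("train", "valid", "test")))
  cat(sprintf("<rob_corpus: %d documents (train %d / valid %d / test %d)>\n",
              length(x$documents), tab[["train"]], tab[["valid"]],
              tab[["test"]]))
  invisible(x)
}

#' Subset a corpus to one split
#' @param corpus A `rob_corpus`.
#' @param which One of "train", "valid", "test".
#' @return List of `clean_document`s.
#' @export
corpus_split <- function(corpus, which = c("train", "valid", "test")) {
  which <- match.arg(which)
  corpus$documents[names(corpus$split)[corpus$split == which]]
}

#' Extract one item's labels from a list of documents
#' @param docs List of `clean_document`s.
#' @param item Item key.
#' @return Named integer vector (may contain NA).
#' @export
corpus_labels <- function(docs, item) {
  vapply(docs, function(d) {
    v <- d$labels[[item]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }, 1L)
}

document_text <- function(doc) {
  paste(vapply(doc$sentences, paste, "", collapse = " "), collapse = " ")
}

#' Write documents to a JSONL corpus file
#'
#' One JSON object per line: `{"doc_id", "text", "labels": {item: 0|1|null}}`.
#' For cleaned documents the text is the space-joined token stream, which
#' round-trips through [read_corpus_jsonl()] exactly.
#'
#' @param docs List of `clean_document`s (or a `rob_corpus`).
#' @param path Output file path.
#' @export
write_corpus_jsonl <- function(docs, path) {
  if (inherits(docs, "rob_corpus")) docs <- docs$documents
  con <- file(path, "w")
  on.exit(close(con))
  for (d in docs) {
    labels <- as.list(d$labels)
    rec <- list(doc_id = d$doc_id, text = document_text(d),
                labels = labels)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                na = "null"), con)
  }
  invisible(path)
}

#' Read a JSONL corpus file
#'
#' @param path Path to a JSONL file written by [write_corpus_jsonl()] or
#'   following the same schema with raw text.
#' @param preprocess If `TRUE` (default) run [clean_text()] before
#'   tokenization; already-clean text passes through unchanged
#'   (cleaning is idempotent).
#' @return List of `clean_document`s.
#' @export
read_corpus_jsonl <- function(path, preprocess = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    labels <- rec$labels
    lab <- if (length(labels) == 0) integer(0) else {
      vapply(labels, function(v) if (is.null(v)) NA_integer_
             else as.integer(v), 1L)
    }
    txt <- if (preprocess) clean_text(rec$text) else rec$text
    clean_document(rec$doc_id, tokenize(txt), lab)
  })
}
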