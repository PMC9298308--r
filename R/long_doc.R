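# Two strategies for classifying ~5000-token documents with a 512-token
# contextual encoder: document chunk pooling (DCP; frozen encoder, layer
# averaging, token pooling, a small trainable head) and sentence extraction
# (SE; unsupervised cosine ranking against the item description, then a
# fine-tunable compact encoder + head on the extracted passage). Encoders
# are injected adapters so the module is testable with deterministic stubs.

#' Split a token-id sequence into encoder-sized chunks
#'
#' `m = ceiling(s / chunk_size)` chunks of `chunk_size` payload tokens
#' (except possibly the last), each wrapped with the classification and
#' separation special tokens. The ceiling guarantees no token is discarded:
#' concatenating the chunk payloads reproduces the input exactly.
#'
#' @param token_ids Integer vector of length `s >= 1`.
#' @param chunk_size Payload tokens per chunk (default 510, i.e. 512 minus
#'   the two specials).
#' @param cls_id,sep_id Special token ids (defaults 101/102).
#' @return A `chunk_set`: list with `m`, `chunks` (list of id vectors
#'   including specials), `chunk_size`, `cls_id`, `sep_id`.
#' @export
chunk_document <- function(token_ids, chunk_size = 510L, cls_id = 101L,
                           sep_id = 102L) {
  s <- length(token_ids)
  if (s == 0) stop("cannot chunk an empty document")
  m <- ceiling(s / chunk_size)
  chunks <- lapply(seq_len(m), function(i) {
    lo <- (i - 1L) * chunk_size + 1L
    hi <- min(i * chunk_size, s)
    c(cls_id, token_ids[lo:hi], sep_id)
  })
  structure(list(m = m, chunks = chunks, chunk_size = as.integer(chunk_size),
                 cls_id = as.integer(cls_id), sep_id = as.integer(sep_id)),
            class = "chunk_set")
}

#' Recover the original token ids from a chunk set
#' @param cs A `chunk_set`.
#' @return Integer vector: concatenated chunk payloads (specials removed).
#' @export
chunk_payload <- function(cs) {
  unlist(lapply(cs$chunks, function(ch) ch[-c(1L, length(ch))]),
         use.names = FALSE)
}

#' Deterministic stub contextual encoder
#'
#' A frozen random-projection encoder for tests and examples: layer `l`
#' maps token ids through a seeded embedding followed by a seeded linear
#' map and `tanh`. Same interface as a real frozen transformer adapter:
#' `encode(ids)` returns a list of `n_layers` matrices of shape
#' `length(ids) x hidden_size`. Synthetic — carries no pretrained knowledge.
#'
#' @param n_layers Number of encoder layers (default 4).
#' @param hidden_size Hidden width (default 16).
#' @param vocab_size Id space size (default 30000).
#' @param seed Seed for the frozen projections.
#' @return An encoder adapter list with `n_layers`, `hidden_size`,
#'   `encode`.
#' @export
stub_chunk_encoder <- function(n_layers = 4L, hidden_size = 16L,
                               vocab_size = 30000L, seed = 1L) {
  set.seed(as.integer(seed))
  E <- matrix(rnorm(vocab_size * hidden_size, 0, 0.5), vocab_size)
  R <- lapply(seq_len(n_layers), function(l) {
    matrix(rnorm(hidden_size * hidden_size, 0, 1 / sqrt(hidden_size)),
           hidden_size)
  })
  list(
    n_layers = n_layers, hidden_size = hidden_size,
    encode = function(ids) {
      ids <- ((as.integer(ids) - 1L) %% vocab_size) + 1L
      base <- E[ids, , drop = FALSE]
      lapply(R, function(r) tanh(base %*% r))
    }
  )
}

#' Configuration for document chunk pooling
#'
#' @param layers Indices of encoder layers to average (default `"last4"`,
#'   the last four).
#' @param token_pool How to collapse tokens within a chunk: `"max"`,
#'   `"avg"`, `"concat_max_avg"`, `"first_token"`, `"all_tokens"`.
#' @param head Classification head over the chunk sequence: `"linear"`,
#'   `"conv"`, `"lstm"`.
#' @param head_pool Extra pool across chunks for the linear head (same
#'   options minus `"all_tokens"`, which has no fixed dimension and is
#'   rejected).
#' @return A `dcp_config` list.
#' @export
dcp_config <- function(layers = "last4",
                       token_pool = c("max", "avg", "concat_max_avg",
                                      "first_token", "all_tokens"),
                       head = c("linear", "conv", "lstm"),
                       head_pool = c("avg", "max", "concat_max_avg",
                                     "first_token")) {
  token_pool <- match.arg(token_pool)
  head <- match.arg(head)
  head_pool <- match.arg(head_pool)
  if (token_pool == "all_tokens" && head == "linear") {
    stop("token_pool 'all_tokens' cannot feed the linear head ",
         "(no fixed dimension)")
  }
  structure(list(layers = layers, token_pool = token_pool, head = head,
                 head_pool = head_pool),
            class = "dcp_config")
}

dcp_layer_idx <- function(cfg, n_layers) {
  if (identical(cfg$layers, "last4")) {
    seq.int(max(1L, n_layers - 3L), n_layers)
  } else {
    idx <- as.integer(cfg$layers)
    stopifnot(all(idx >= 1), all(idx <= n_layers))
    idx
  }
}

pool_rows <- function(M, how) {
  switch(how,
         max = apply(M, 2, max),
         avg = colMeans(M),
         concat_max_avg = c(apply(M, 2, max), colMeans(M)),
         first_token = M[1, ],
         stop("unknown pooling option: ", how))
}

dcp_feature_dim <- function(cfg, h) {
  if (cfg$token_pool == "concat_max_avg") 2L * h else h
}

#' Initialise head weights for document chunk pooling
#' @param cfg A [dcp_config()].
#' @param encoder Encoder adapter (for `hidden_size`).
#' @param conv_filters,conv_sizes Convolution head shape (defaults 8
#'   filters of sizes 1 and 2).
#' @param lstm_hidden LSTM head width (default 16).
#' @param seed Seed.
#' @return Weight list for [dcp_encode_pool()].
#' @export
dcp_init_head <- function(cfg, encoder, conv_filters = 8L,
                          conv_sizes = c(1L, 2L), lstm_hidden = 16L,
                          seed = 1L) {
  set.seed(as.integer(seed))
  p <- dcp_feature_dim(cfg, encoder$hidden_size)
  if (cfg$head == "linear") {
    q <- if (cfg$head_pool == "concat_max_avg") 2L * p else p
    list(kind = "linear", W = nn_mat(q, 2L), b = numeric(2L))
  } else if (cfg$head == "conv") {
    spec <- conv_spec(conv_sizes, conv_filters, dropout = 0)
    list(kind = "conv", spec = spec, w = cnn_init(spec, p))
  } else {
    list(kind = "lstm", p = rnn_init("lstm", p, lstm_hidden),
         W = nn_mat(lstm_hidden, 2L), b = numeric(2L))
  }
}

#' Encode a chunked document with a frozen encoder and pool to logits
#'
#' Per chunk, hidden states are averaged over the configured encoder-layer
#' subset, then collapsed across tokens by the chosen pooling option; the
#' resulting chunk-sequence representation feeds the head (the linear head
#' first applies its extra pool across chunks). The encoder is used purely
#' as a function: its parameters are never updated here.
#'
#' @param chunks A `chunk_set`.
#' @param encoder Encoder adapter (see [stub_chunk_encoder()] for the
#'   interface).
#' @param cfg A [dcp_config()].
#' @param weights Head weights from [dcp_init_head()].
#' @return List with `logits` (length 2), `probs`, and `chunk_features`
#'   (the pooled per-chunk matrix fed to the head).
#' @export
dcp_encode_pool <- function(chunks, encoder, cfg, weights) {
  if (cfg$token_pool == "all_tokens" && cfg$head == "linear") {
    stop("token_pool 'all_tokens' cannot feed the linear head")
  }
  idx <- dcp_layer_idx(cfg, encoder$n_layers)
  feats <- lapply(chunks$chunks, function(ch) {
    layers <- encoder$encode(ch)
    avg <- Reduce(`+`, layers[idx]) / length(idx)
    if (cfg$token_pool == "all_tokens") avg else
      matrix(pool_rows(avg, cfg$token_pool), nrow = 1)
  })
  M <- do.call(rbind, feats)
  logits <- if (weights$kind == "linear") {
    v <- pool_rows(M, cfg$head_pool)
    drop(crossprod(weights$W, v)) + weights$b
  } else if (weights$kind == "conv") {
    x <- M
    need <- max(weights$spec$filter_sizes)
    if (nrow(x) < need) x <- rbind(x, matrix(0, need - nrow(x), ncol(x)))
    attr(x, "n_tokens") <- nrow(M)
    cnn_forward(x, weights$spec, weights$w, train = FALSE)$logits
  } else {
    X <- lapply(seq_len(nrow(M)), function(i) M[i, , drop = FALSE])
    enc <- rnn_forward(X, weights$p, "lstm", matrix(1, 1, nrow(M)))
    drop(crossprod(weights$W, drop(enc$H[[nrow(M)]]))) + weights$b
  }
  p <- exp(logits - max(logits)); p <- p / sum(p)
  list(logits = logits, probs = p, chunk_features = M)
}

## ---- sentence extraction ---------------------------------------------

#' Deterministic bag-of-words stub sentence encoder
#'
#' Maps a sentence (token vector) to token-count features over a hashed
#' id space; identical sentences map to identical vectors, so a sentence
#' equal to the query scores cosine 1. Synthetic stand-in for a pretrained
#' sentence embedder, suitable for tests and fully offline use.
#'
#' @param dim Feature dimension (default 512).
#' @return Sentence-encoder adapter: list with `dim` and
#'   `embed(tokens) -> numeric(dim)`.
#' @export
bow_sentence_encoder <- function(dim = 512L) {
  hash_token <- function(tok) {
    codes <- utf8ToInt(tok)
    (sum(codes * seq_along(codes) * 31L) %% dim) + 1L
  }
  list(
    dim = dim,
    embed = function(tokens) {
      v <- numeric(dim)
      if (length(tokens) == 0) return(v)
      for (tok in tokens) {
        i <- hash_token(tok)
        v[i] <- v[i] + 1
      }
      v
    }
  )
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Extract the sentences most similar to an item's description
#'
#' Unsupervised and independent of any training: every sentence is embedded
#' with the given sentence encoder, scored by cosine similarity against the
#' embedded one-sentence item description, and the top `k` are returned
#' (all sentences if the document has fewer than `k`). Zero-norm sentence
#' vectors score 0; equal scores break ties toward the lower original
#' index.
#'
#' @param doc A `clean_document`.
#' @param item Item key (its [rob_item_description()] is the query) or a
#'   list with `key` and `description`.
#' @param encoder Sentence-encoder adapter (see [bow_sentence_encoder()]).
#' @param k Number of sentences to keep (default 5).
#' @return A `rob_passage`: list with `doc_id`, `item`, `sentences` (data
#'   frame of `index`, `text`, `score`, sorted by non-increasing score).
#' @export
extract_relevant_sentences <- function(doc, item, encoder, k = 5L) {
  stopifnot(k >= 1)
  if (is.character(item)) {
    item <- list(key = item, description = rob_item_description(item))
  }
  query_toks <- unlist(tokenize(item$description), use.names = FALSE)
  q <- encoder$embed(query_toks)
  scores <- vapply(doc$sentences, function(s) cosine(encoder$embed(s), q), 0)
  k_eff <- min(k, length(scores))
  ord <- order(-scores, seq_along(scores))[seq_len(k_eff)]
  sentences <- data.frame(
    index = ord,
    text = vapply(doc$sentences[ord], paste, "", collapse = " "),
    score = scores[ord],
    stringsAsFactors = FALSE
  )
  structure(list(doc_id = doc$doc_id, item = item$key,
                 sentences = sentences),
            class = "rob_passage")
}

#' @exportS3Method base::print
print.rob_passage <- function(x, ...) {
  cat(sprintf("<rob_passage %s/%s: %d sentences, top score %.3f>\n",
              x$doc_id, x$item, nrow(x$sentences),
              if (nrow(x$sentences) > 0) x$sentences$score[1] else NA))
  invisible(x)
}

#' Write passages as JSONL evidence records
#'
#' One object per passage:
#' `{"doc_id","item","sentences":[{"index","text","score"}]}`.
#'
#' @param passages List of `rob_passage`s.
#' @param path Output path.
#' @export
write_passages_jsonl <- function(passages, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in passages) {
    rec <- list(doc_id = p$doc_id, item = p$item,
                sentences = p$sentences)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows",
                                digits = NA), con)
  }
  invisible(path)
}

## ---- sentence-extraction classifier ----------------------------------

#' Construct a fine-tunable passage classifier
#'
#' A compact trainable encoder (a linear projection plus `tanh` over
#' sentence features from the injected adapter) followed by a linear,
#' convolution or LSTM head. Unlike the chunk-pooling strategy the encoder
#' projection is updated during training.
#'
#' @param encoder Sentence-feature adapter (see [bow_sentence_encoder()]).
#' @param head `"linear"`, `"conv"` or `"lstm"`.
#' @param hidden Projection width (default 32).
#' @param keep_order `"document"` (default; ranked sentences re-sorted into
#'   original order, preserving discourse flow) or `"rank"`.
#' @param seed Seed for weight initialisation.
#' @return An `se_model`.
#' @export
se_model <- function(encoder, head = c("linear", "conv", "lstm"),
                     hidden = 32L, keep_order = c("document", "rank"),
                     seed = 1L) {
  head <- match.arg(head)
  keep_order <- match.arg(keep_order)
  set.seed(as.integer(seed))
  w <- list(proj = list(W = nn_mat(encoder$dim, hidden),
                        b = numeric(hidden)))
  if (head == "linear") {
    w$out <- list(W = nn_mat(hidden, 2L), b = numeric(2L))
  } else if (head == "conv") {
    spec <- conv_spec(c(1L, 2L), 8L, dropout = 0)
    w$head_spec <- spec
    w$conv <- cnn_init(spec, hidden)
  } else {
    w$lstm <- rnn_init("lstm", hidden, hidden)
    w$out <- list(W = nn_mat(hidden, 2L), b = numeric(2L))
  }
  structure(list(encoder = encoder, head = head, hidden = as.integer(hidden),
                 keep_order = keep_order, weights = w,
                 seed = as.integer(seed)),
            class = "se_model")
}

se_passage_features <- function(model, passage) {
  if (nrow(passage$sentences) == 0) stop("empty passage")
  sents <- passage$sentences
  if (model$keep_order == "document") sents <- sents[order(sents$index), ]
  F_ <- t(vapply(strsplit(sents$text, "\\s+"),
                 function(toks) model$encoder$embed(toks),
                 numeric(model$encoder$dim)))
  F_
}

se_forward <- function(model, F_) {
  w <- model$weights
  A <- addb(F_ %*% w$proj$W, w$proj$b)
  Hp <- tanh(A)
  if (model$head == "linear") {
    v <- colMeans(Hp)
    logits <- drop(crossprod(w$out$W, v)) + w$out$b
    cache <- list(kind = "linear", F_ = F_, Hp = Hp, v = v)
  } else if (model$head == "conv") {
    x <- Hp
    need <- max(w$head_spec$filter_sizes)
    if (nrow(x) < need) x <- rbind(x, matrix(0, need - nrow(x), ncol(x)))
    attr(x, "n_tokens") <- nrow(Hp)
    fw <- cnn_forward(x, w$head_spec, w$conv, train = FALSE)
    logits <- fw$logits
    cache <- list(kind = "conv", F_ = F_, Hp = Hp, x = x, fw = fw)
  } else {
    X <- lapply(seq_len(nrow(Hp)), function(i) Hp[i, , drop = FALSE])
    enc <- rnn_forward(X, w$lstm, "lstm", matrix(1, 1, nrow(Hp)))
    hT <- drop(enc$H[[length(X)]])
    logits <- drop(crossprod(w$out$W, hT)) + w$out$b
    cache <- list(kind = "lstm", F_ = F_, Hp = Hp, enc = enc, hT = hT)
  }
  p <- exp(logits - max(logits)); p <- p / sum(p)
  list(logits = logits, probs = p, cache = cache)
}

se_backward <- function(model, dlogits, cache) {
  w <- model$weights
  g <- list()
  if (cache$kind == "linear") {
    g$out <- list(W = outer(cache$v, dlogits), b = dlogits)
    dv <- drop(w$out$W %*% dlogits)
    dHp <- matrix(dv, nrow(cache$Hp), length(dv), byrow = TRUE) /
      nrow(cache$Hp)
  } else if (cache$kind == "conv") {
    cg <- cnn_backward(dlogits, cache$fw$cache, want_dx = TRUE,
                       x_dim = dim(cache$x))
    g$conv <- cg
    dHp <- attr(cg, "dx")[seq_len(nrow(cache$Hp)), , drop = FALSE]
    attr(g$conv, "dx") <- NULL
  } else {
    g$out <- list(W = outer(cache$hT, dlogits), b = dlogits)
    T_ <- nrow(cache$Hp)
    dH <- lapply(seq_len(T_), function(t) {
      if (t == T_) matrix(w$out$W %*% dlogits, nrow = 1)
      else matrix(0, 1, model$hidden)
    })
    rb <- rnn_backward(dH, cache$enc$cache)
    g$lstm <- rb$grads
    dHp <- do.call(rbind, rb$dX)
  }
  dA <- dHp * (1 - cache$Hp^2)
  g$proj <- list(W = crossprod(cache$F_, dA), b = colSums(dA))
  g
}

#' Train the passage classifier on extracted passages
#'
#' @param model An `se_model`.
#' @param passages List of `rob_passage`s.
#' @param labels 0/1 vector, one per passage.
#' @param config List: `epochs` (20), `lr` (1e-2), `seed` (1).
#' @return The trained `se_model`.
#' @export
se_train <- function(model, passages, labels, config = list()) {
  cfg <- utils::modifyList(list(epochs = 20L, lr = 1e-2, seed = 1L), config)
  stopifnot(length(passages) == length(labels), length(passages) > 0)
  feats <- lapply(passages, se_passage_features, model = model)
  set.seed(cfg$seed)
  opt <- adam_init(model$weights)
  for (ep in seq_len(cfg$epochs)) {
    for (i in sample(seq_along(feats))) {
      fw <- se_forward(model, feats[[i]])
      ls <- softmax_xent(fw$logits, labels[i])
      g <- se_backward(model, ls$dlogits, fw$cache)
      st <- adam_step(model$weights, g, opt, lr = cfg$lr)
      model$weights <- st$params
      opt <- st$state
    }
  }
  model
}

#' Probability that a passage reports the item
#'
#' @param passage A non-empty `rob_passage`.
#' @param model An `se_model` (trained or not).
#' @return Probability of "reported".
#' @export
se_classify <- function(passage, model) {
  if (nrow(passage$sentences) == 0) stop("empty passage")
  se_forward(model, se_passage_features(model, passage))$probs[2]
}
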