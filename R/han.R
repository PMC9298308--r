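#' Specification of the hierarchical attention network
#'
#' Two levels of attention. Word level: a bidirectional recurrent encoder
#' runs over each sentence's tokens and a word context vector scores every
#' hidden state; each sentence becomes the attention-weighted sum of its
#' word states. Sentence level: sentence vectors are encoded (by default a
#' position-independent `tanh` projection, so that sentence scores depend
#' on content rather than position and permuting sentences permutes the
#' scores; optionally a second bidirectional GRU), scored against a sentence
#' context vector, and the attention-weighted sum is mapped to two logits.
#' Sentence attention weights double as evidence-ranking scores.
#'
#' @param word_hidden Word-level hidden units per direction (default 24).
#' @param sent_hidden Sentence-level representation size (default 24).
#' @param cell Word-level recurrent cell, `"gru"` or `"lstm"`.
#' @param sentence_encoder `"projection"` (default; permutation-equivariant
#'   sentence scores) or `"gru"`.
#' @return A `han_spec` list.
#' @export
han_spec <- function(word_hidden = 24L, sent_hidden = 24L,
                     cell = c("gru", "lstm"),
                     sentence_encoder = c("projection", "gru")) {
  cell <- match.arg(cell)
  sentence_encoder <- match.arg(sentence_encoder)
  stopifnot(word_hidden >= 1, sent_hidden >= 1)
  structure(list(word_hidden = as.integer(word_hidden),
                 sent_hidden = as.integer(sent_hidden), cell = cell,
                 sentence_encoder = sentence_encoder),
            class = "han_spec")
}

han_init <- function(spec, d, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  Kw <- 2L * spec$word_hidden
  w <- list(
    word_rnn = bi_rnn_init(spec$cell, d, spec$word_hidden),
    word_attn = attn_init(Kw, spec$word_hidden)
  )
  if (spec$sentence_encoder == "projection") {
    Ks <- spec$sent_hidden
    w$sent_proj <- list(W = nn_mat(Kw, Ks), b = numeric(Ks))
  } else {
    Ks <- 2L * spec$sent_hidden
    w$sent_rnn <- bi_rnn_init("gru", Kw, spec$sent_hidden)
  }
  w$sent_attn <- attn_init(Ks, spec$sent_hidden)
  w$out <- list(W = nn_mat(Ks, 2L), b = numeric(2L))
  w
}

han_batch_sentences <- function(sent_mats) {
  # pad sentences to a common length; returns X (list over t of B x d)
  # and mask (B x T)
  B <- length(sent_mats)
  lens <- vapply(sent_mats, nrow, 1L)
  T_ <- max(lens, 1L)
  d <- ncol(sent_mats[[1]])
  mask <- matrix(0, B, T_)
  X <- lapply(seq_len(T_), function(t) matrix(0, B, d))
  for (b in seq_len(B)) {
    if (lens[b] > 0) {
      mask[b, seq_len(lens[b])] <- 1
      for (t in seq_len(lens[b])) X[[t]][b, ] <- sent_mats[[b]][t, ]
    }
  }
  list(X = X, mask = mask, lens = lens)
}

#' Forward pass of the hierarchical attention network
#'
#' @param sent_mats List of per-sentence embedding matrices (`len x d`),
#'   one entry per sentence, in document order.
#' @param spec A [han_spec()].
#' @param weights Model weights.
#' @return List with `logits`, `probs`, `word_attention` (list of
#'   per-sentence weight vectors, each summing to 1), `sentence_attention`
#'   (vector summing to 1) and `cache`.
#' @export
han_forward <- function(sent_mats, spec, weights) {
  stopifnot(length(sent_mats) >= 1)
  batch <- han_batch_sentences(sent_mats)
  enc <- bi_rnn_forward(batch$X, weights$word_rnn, spec$cell, batch$mask)
  watt <- attn_forward(enc$H, weights$word_attn, batch$mask)
  S <- watt$ctx  # n_sent x 2Hw
  B <- nrow(S)
  if (spec$sentence_encoder == "projection") {
    Z <- tanh(addb(S %*% weights$sent_proj$W, weights$sent_proj$b))
    senc_cache <- list(S = S, Z = Z)
  } else {
    Slist <- lapply(seq_len(B), function(j) S[j, , drop = FALSE])
    smask <- matrix(1, 1, B)
    srnn <- bi_rnn_forward(Slist, weights$sent_rnn, "gru", smask)
    Z <- do.call(rbind, srnn$H)
    senc_cache <- list(S = S, Z = Z, srnn = srnn, smask = smask)
  }
  Zlist <- lapply(seq_len(B), function(j) Z[j, , drop = FALSE])
  satt <- attn_forward(Zlist, weights$sent_attn, matrix(1, 1, B))
  docv <- drop(satt$ctx)
  logits <- drop(crossprod(weights$out$W, docv)) + weights$out$b
  p <- exp(logits - max(logits)); p <- p / sum(p)
  word_attention <- lapply(seq_len(B), function(b) {
    a <- watt$alpha[b, seq_len(max(batch$lens[b], 1L))]
    a
  })
  list(logits = logits, probs = p,
       word_attention = word_attention,
       sentence_attention = drop(satt$alpha),
       cache = list(batch = batch, enc = enc, watt = watt,
                    senc = senc_cache, satt = satt, docv = docv,
                    spec = spec, weights = weights))
}

han_backward <- function(dlogits, cache) {
  w <- cache$weights
  spec <- cache$spec
  g <- list(out = list(W = outer(cache$docv, dlogits), b = dlogits))
  ddoc <- matrix(w$out$W %*% dlogits, nrow = 1)
  sab <- attn_backward(ddoc, cache$satt$cache)
  g$sent_attn <- sab$grads
  dZ <- do.call(rbind, sab$dH)  # n_sent x Ks
  if (spec$sentence_encoder == "projection") {
    Z <- cache$senc$Z
    da <- dZ * (1 - Z^2)
    g$sent_proj <- list(W = crossprod(cache$senc$S, da), b = colSums(da))
    dS <- da %*% t(w$sent_proj$W)
  } else {
    B <- nrow(cache$senc$S)
    dHs <- lapply(seq_len(B), function(j) dZ[j, , drop = FALSE])
    sb <- bi_rnn_backward(dHs, cache$senc$srnn$cache)
    g$sent_rnn <- sb$grads
    dS <- do.call(rbind, sb$dX)
  }
  wab <- attn_backward(dS, cache$watt$cache)
  g$word_attn <- wab$grads
  g$word_rnn <- bi_rnn_backward(wab$dH, cache$enc$cache)$grads
  g
}
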