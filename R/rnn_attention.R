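#' Specification of the recurrent classifier with attention
#'
#' A bidirectional recurrent encoder (GRU or LSTM) produces one hidden
#' state per token; an additive attention module scores each hidden state
#' against a learned context vector, softmax-normalises the scores over the
#' real (non-padding) tokens, and the attention-weighted sum of hidden
#' states is mapped linearly to two logits. The per-token attention weights
#' are returned so word contributions can be inspected.
#'
#' @param cell `"gru"` (default) or `"lstm"`.
#' @param hidden_size Hidden units per direction (default 32).
#' @param attn_size Size of the attention projection (default
#'   `hidden_size`).
#' @param bidirectional Logical (default `TRUE`).
#' @return An `attn_rnn_spec` list.
#' @export
attn_rnn_spec <- function(cell = c("gru", "lstm"), hidden_size = 32L,
                          attn_size = hidden_size, bidirectional = TRUE) {
  cell <- match.arg(cell)
  stopifnot(hidden_size >= 1)
  structure(list(cell = cell, hidden_size = as.integer(hidden_size),
                 attn_size = as.integer(attn_size),
                 bidirectional = isTRUE(bidirectional)),
            class = "attn_rnn_spec")
}

rnn_attn_init <- function(spec, d, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  K <- spec$hidden_size * (if (spec$bidirectional) 2L else 1L)
  w <- list(attn = attn_init(K, spec$attn_size),
            out = list(W = nn_mat(K, 2L), b = numeric(2L)))
  w$rnn <- if (spec$bidirectional) {
    bi_rnn_init(spec$cell, d, spec$hidden_size)
  } else {
    rnn_init(spec$cell, d, spec$hidden_size)
  }
  w
}

#' Forward pass of the attention RNN
#'
#' @param x Document matrix (`s x d` or padded `s_max x d` with attribute
#'   `n_tokens`).
#' @param spec An [attn_rnn_spec()].
#' @param weights Model weights.
#' @return List with `logits` (length 2), `probs`, `attention` (per-token
#'   weights over the real tokens, summing to 1) and `cache`.
#' @export
rnn_attention_forward <- function(x, spec, weights) {
  s <- attr(x, "n_tokens")
  if (is.null(s)) s <- nrow(x)
  s <- max(1L, min(s, nrow(x)))
  X <- lapply(seq_len(s), function(t) x[t, , drop = FALSE])
  mask <- matrix(1, 1, s)
  enc <- if (spec$bidirectional) {
    bi_rnn_forward(X, weights$rnn, spec$cell, mask)
  } else {
    rnn_forward(X, weights$rnn, spec$cell, mask)
  }
  att <- attn_forward(enc$H, weights$attn, mask)
  ctx <- drop(att$ctx)
  logits <- drop(crossprod(weights$out$W, ctx)) + weights$out$b
  p <- exp(logits - max(logits)); p <- p / sum(p)
  list(logits = logits, probs = p, attention = drop(att$alpha),
       cache = list(enc = enc, att = att, ctx = ctx, spec = spec,
                    weights = weights))
}

rnn_attn_backward <- function(dlogits, cache) {
  w <- cache$weights
  spec <- cache$spec
  g <- list(out = list(W = outer(cache$ctx, dlogits), b = dlogits))
  dctx <- matrix(w$out$W %*% dlogits, nrow = 1)
  ab <- attn_backward(dctx, cache$att$cache)
  g$attn <- ab$grads
  g$rnn <- if (spec$bidirectional) {
    bi_rnn_backward(ab$dH, cache$enc$cache)$grads
  } else {
    rnn_backward(ab$dH, cache$enc$cache)$grads
  }
  g
}
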