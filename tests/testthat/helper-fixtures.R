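# Shared fixtures and independent oracles, all built in code.

mk_docs <- function(n, tokens = c("a", "b")) {
  lapply(seq_len(n), function(i) {
    clean_document(sprintf("d%04d", i), list(tokens))
  })
}

# random raw article text with the artefacts clean_text removes
random_raw_text <- function(seed) {
  set.seed(seed)
  words <- c("the", "rats", "were", "tested", "in", "a", "maze", "daily",
             "and", "scored", "for", "latency", "by", "observers")
  para <- function() paste(sample(words, sample(5:12, 1), TRUE),
                           collapse = " ")
  parts <- c("Running head 12", "Introduction", para(),
             sprintf("%s [3] (Smith, %d).", para(), sample(1990:2020, 1)),
             paste0(para(), " see http://example.org/x?id=", sample(99, 1)),
             para(), "References", "Smith J et al 2010")
  paste(parts, collapse = "\n")
}

# brute-force convolution oracle: explicit double loop over filters and
# window positions, independent of the unrolled-matmul implementation
cnn_logits_oracle <- function(x, spec, weights) {
  pooled <- c()
  for (h in spec$filter_sizes) {
    W <- weights[[paste0("conv", h)]]$W
    b <- weights[[paste0("conv", h)]]$b
    for (f in seq_len(ncol(W))) {
      filt <- matrix(W[, f], nrow = h, byrow = TRUE)
      n <- nrow(x) - h + 1
      w <- vapply(seq_len(n), function(i) {
        sum(x[i:(i + h - 1), , drop = FALSE] * filt) + b[f]
      }, 0)
      pooled <- c(pooled, max(pmax(w, 0)))
    }
  }
  drop(crossprod(weights$out$W, pooled)) + weights$out$b
}

# exhaustive McNemar oracle: enumerate every assignment of the b + c
# discordant records under the symmetric null
mcnemar_p_enum <- function(b, c_) {
  n <- b + c_
  if (n == 0) return(1)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  wins <- rowSums(outcomes)
  mean(abs(wins - n / 2) >= abs(b - n / 2))
}

# finite-difference gradient check over a few coordinates per parameter
fd_grad_check <- function(forward_loss, params, eps = 1e-5, probes = 2) {
  base <- forward_loss(params)
  flat_g <- prerob:::flatten_params(base$grads)
  flat_p <- prerob:::flatten_params(params)
  worst <- 0
  for (key in names(flat_g)) {
    g <- flat_g[[key]]
    for (ix in sample(length(g), min(probes, length(g)))) {
      p_hi <- flat_p; p_hi[[key]][ix] <- p_hi[[key]][ix] + eps
      p_lo <- flat_p; p_lo[[key]][ix] <- p_lo[[key]][ix] - eps
      num <- (forward_loss(prerob:::unflatten_into(params, p_hi))$loss -
                forward_loss(prerob:::unflatten_into(params, p_lo))$loss) /
        (2 * eps)
      rel <- abs(num - g[ix]) / max(1e-6, abs(num) + abs(g[ix]))
      worst <- max(worst, rel)
    }
  }
  worst
}

# small planted-phrase corpus + split, shared across tests
small_synth_corpus <- function(n = 150, seed = 23, mean_sentences = 7,
                               mean_tokens = 8) {
  spec <- synth_spec(n, mean_sentences = mean_sentences,
                     mean_tokens = mean_tokens, distractor_rate = 0.2,
                     seed = seed)
  docs <- generate_corpus(spec)
  corpus <- split_corpus(docs, seed = seed)
  list(spec = spec, docs = docs, corpus = corpus,
       planted = attr(docs, "planted"))
}

# token span of a document's planted sentence for an item
planted_token_span <- function(doc, planted_idx) {
  sl <- vapply(doc$sentences, length, 1L)
  lo <- if (planted_idx == 1) 1L else sum(sl[seq_len(planted_idx - 1)]) + 1L
  c(lo, sum(sl[seq_len(planted_idx)]))
}

# lazily trained small HAN shared by interpretation tests
.trained_cache <- new.env(parent = emptyenv())
trained_small_han <- function() {
  if (!is.null(.trained_cache$han)) return(.trained_cache$han)
  fix <- small_synth_corpus(n = 120, seed = 37, mean_sentences = 6,
                            mean_tokens = 7)
  tr <- corpus_split(fix$corpus, "train")
  va <- corpus_split(fix$corpus, "valid")
  vocab <- build_vocabulary(tr, min_df = 2)
  emb <- random_embedding_table(vocab, dim = 12, seed = 37)
  m <- neural_model("han", han_spec(word_hidden = 6L, sent_hidden = 6L),
                    emb, max_sentences = 30L, max_sent_tokens = 25L,
                    seed = 37)
  m <- train_neural(m, tr, va, "blinding",
                    config = list(epochs = 3, lr = 5e-3, batch = 8,
                                  imbalance = "loss-weighting", seed = 37))
  .trained_cache$han <- list(model = m, fix = fix)
  .trained_cache$han
}
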