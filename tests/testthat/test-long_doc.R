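test_that("chunking follows the ceiling rule and loses no tokens", {
  expect_equal(chunk_document(1:510)$m, 1)
  cs <- chunk_document(1:1021)
  expect_equal(cs$m, 3)
  expect_equal(length(cs$chunks[[3]]) - 2L, 1L)  # last payload length 1
  expect_equal(chunk_document(seq_len(4977))$m, 10)
  expect_error(chunk_document(integer(0)), "empty")
  set.seed(3)
  for (i in 1:100) {
    s <- sample(6000, 1)
    ids <- sample.int(30000, s, replace = TRUE)
    cs <- chunk_document(ids)
    expect_equal(cs$m, ceiling(s / 510))
    expect_true(all(vapply(cs$chunks, length, 1L) <= 512))
    expect_identical(chunk_payload(cs), ids)
  }
})

test_that("dcp matches a straight-line stub-encoder oracle composition", {
  enc <- stub_chunk_encoder(n_layers = 4, hidden_size = 6,
                            vocab_size = 500, seed = 11)
  ids <- sample.int(400, 30)
  cs <- chunk_document(ids, chunk_size = 510)
  cfg <- dcp_config(layers = 3:4, token_pool = "avg", head = "linear",
                    head_pool = "avg")
  w <- dcp_init_head(cfg, enc, seed = 12)
  out <- dcp_encode_pool(cs, enc, cfg, w)
  # oracle: layer-average -> token-avg -> chunk-avg -> linear, by hand
  layers <- enc$encode(cs$chunks[[1]])
  avg_layers <- (layers[[3]] + layers[[4]]) / 2
  v <- colMeans(avg_layers)
  expect_equal(out$logits, drop(crossprod(w$W, v)) + w$b, tolerance = 1e-6)
  expect_equal(sum(out$probs), 1, tolerance = 1e-12)
})

test_that("constant hidden states collapse max/avg/first_token pooling", {
  ce <- list(n_layers = 2, hidden_size = 4,
             encode = function(ids) {
               lapply(1:2, function(l) matrix(1.5, length(ids), 4))
             })
  cs <- chunk_document(1:50)
  outs <- vapply(c("max", "avg", "first_token"), function(tp) {
    cfg <- dcp_config(layers = 1:2, token_pool = tp, head = "linear")
    w <- dcp_init_head(cfg, ce, seed = 7)
    dcp_encode_pool(cs, ce, cfg, w)$logits
  }, numeric(2))
  expect_equal(outs[, "max"], outs[, "avg"])
  expect_equal(outs[, "max"], outs[, "first_token"])
})

test_that("concat pooling doubles the feature width; illegal config errors", {
  enc <- stub_chunk_encoder(hidden_size = 5, vocab_size = 100, seed = 4)
  cs <- chunk_document(1:40)
  cfg <- dcp_config(token_pool = "concat_max_avg", head = "lstm")
  w <- dcp_init_head(cfg, enc, seed = 5)
  out <- dcp_encode_pool(cs, enc, cfg, w)
  expect_equal(ncol(out$chunk_features), 10L)
  expect_error(dcp_config(token_pool = "all_tokens", head = "linear"),
               "all_tokens")
})

test_that("every pooling/head combination yields finite two-class logits", {
  enc <- stub_chunk_encoder(hidden_size = 4, vocab_size = 300, seed = 6)
  cs <- chunk_document(sample.int(300, 1200, TRUE))
  for (tp in c("max", "avg", "concat_max_avg", "first_token", "all_tokens")) {
    for (hd in c("linear", "conv", "lstm")) {
      if (tp == "all_tokens" && hd == "linear") next
      cfg <- dcp_config(token_pool = tp, head = hd)
      w <- dcp_init_head(cfg, enc, seed = 8)
      out <- dcp_encode_pool(cs, enc, cfg, w)
      expect_length(out$logits, 2)
      expect_true(all(is.finite(out$logits)))
    }
  }
})

test_that("a verbatim item description ranks first with cosine 1", {
  enc <- bow_sentence_encoder(256L)
  desc <- rob_item_description("welfare_compliance")
  doc <- clean_document("v1", c(
    list(c("unrelated", "filler", "sentence", "here")),
    tokenize(desc),
    list(c("more", "filler", "text"))
  ))
  p <- extract_relevant_sentences(doc, "welfare_compliance", enc, k = 2)
  expect_equal(p$sentences$index[1], 2L)
  expect_equal(p$sentences$score[1], 1.0, tolerance = 1e-12)
})

test_that("cosine ranking matches hand-computed similarities on a toy", {
  # unit bag-of-words vectors over a 4-word universe, computable by hand
  enc <- list(dim = 4L, embed = function(tokens) {
    universe <- c("wa", "wb", "wc", "wd")
    vapply(universe, function(u) sum(tokens == u), 0)
  })
  doc <- clean_document("t1", list(c("wa", "wb"), c("wa"), c("wc", "wd")))
  item <- list(key = "x", description = "wa wb")
  p <- extract_relevant_sentences(doc, item, enc, k = 3)
  # query (1,1,0,0): s1 cos = 2/(sqrt2*sqrt2) = 1; s2 = 1/sqrt2; s3 = 0
  expect_equal(p$sentences$index, c(1L, 2L, 3L))
  expect_equal(p$sentences$score, c(1, 1 / sqrt(2), 0), tolerance = 1e-12)
})

test_that("extraction boundary and invariance rules hold", {
  enc <- bow_sentence_encoder(128L)
  doc <- clean_document("b1", list(c("a", "b"), c("c", "d"), c("e", "f")))
  p <- extract_relevant_sentences(doc, "blinding", enc, k = 5)
  expect_equal(nrow(p$sentences), 3)  # fewer sentences than k
  # zero-norm sentence vectors score 0
  zenc <- list(dim = 3L, embed = function(tokens) numeric(3))
  pz <- extract_relevant_sentences(doc, "blinding", zenc, k = 2)
  expect_true(all(pz$sentences$score == 0))
  # scores are invariant to sentence order (set semantics before ranking)
  doc2 <- clean_document("b2", doc$sentences[c(3, 1, 2)])
  p2 <- extract_relevant_sentences(doc2, "blinding", enc, k = 5)
  expect_equal(sort(p2$sentences$score), sort(p$sentences$score))
  # equal scores break ties toward the lower index
  expect_equal(pz$sentences$index, c(1L, 2L))
})

test_that("passage JSONL output follows the evidence schema", {
  enc <- bow_sentence_encoder(64L)
  doc <- clean_document("j1", list(c("a", "b"), c("c")))
  p <- extract_relevant_sentences(doc, "blinding", enc, k = 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_passages_jsonl(list(p), path)
  rec <- jsonlite::fromJSON(readLines(path)[1])
  expect_named(rec, c("doc_id", "item", "sentences"))
  expect_named(rec$sentences, c("index", "text", "score"))
})

test_that("se classifier: zero head gives 0.5; training is deterministic", {
  enc <- bow_sentence_encoder(64L)
  doc <- clean_document("s1", list(c("a", "b", "c"), c("d", "e")))
  p <- extract_relevant_sentences(doc, "blinding", enc, k = 2)
  m <- se_model(enc, "linear", hidden = 8L, seed = 3)
  m$weights$out$W[] <- 0
  m$weights$out$b[] <- 0
  expect_equal(se_classify(p, m), 0.5)
  empty <- structure(list(doc_id = "x", item = "blinding",
                          sentences = p$sentences[0, ]),
                     class = "rob_passage")
  expect_error(se_classify(empty, m), "empty")
  # same passages, same seed, two training runs -> identical probability
  fix <- small_synth_corpus(n = 40, seed = 19)
  tr <- corpus_split(fix$corpus, "train")
  passages <- lapply(tr, extract_relevant_sentences, item = "blinding",
                     encoder = enc, k = 3)
  labels <- corpus_labels(tr, "blinding")
  m1 <- se_train(se_model(enc, "linear", seed = 5), passages, labels,
                 config = list(epochs = 3, seed = 5))
  m2 <- se_train(se_model(enc, "linear", seed = 5), passages, labels,
                 config = list(epochs = 3, seed = 5))
  expect_identical(se_classify(passages[[1]], m1),
                   se_classify(passages[[1]], m2))
})

test_that("se pipeline separates planted-phrase positives end to end", {
  enc <- bow_sentence_encoder(256L)
  fix <- small_synth_corpus(n = 300, seed = 31, mean_sentences = 10,
                            mean_tokens = 9)
  tr <- corpus_split(fix$corpus, "train")
  te <- corpus_split(fix$corpus, "test")
  mkpass <- function(ds) lapply(ds, extract_relevant_sentences,
                                item = "blinding", encoder = enc, k = 3)
  m <- se_model(enc, "linear", hidden = 16L, seed = 31)
  m <- se_train(m, mkpass(tr), corpus_labels(tr, "blinding"),
                config = list(epochs = 20, lr = 1e-2, seed = 31))
  probs <- vapply(mkpass(te), se_classify, 0, model = m)
  f1 <- metrics(confusion(corpus_labels(te, "blinding"), decide(probs)))$f1
  expect_gte(f1, 0.9)
})
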