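toy_tfidf_docs <- function() {
  words <- c("rat", "maze", "dose", "brain", "test", "drug", "cage")
  lapply(1:10, function(i) {
    set.seed(100 + i)
    clean_document(paste0("t", i),
                   list(sample(words, 6, TRUE), sample(words, 5, TRUE)))
  })
}

test_that("tfidf matches a brute-force two-pass counting oracle", {
  docs <- toy_tfidf_docs()
  stats <- tfidf_fit(docs, min_df = 1)
  # oracle: explicit counts, ln(N/df)
  all_toks <- lapply(docs, function(d) unlist(d$sentences))
  for (i in seq_along(docs)) {
    v <- tfidf_vectorize(docs[[i]], stats)
    dense <- as.numeric(v[seq_along(stats$terms)])
    for (j in seq_along(stats$terms)) {
      term <- stats$terms[j]
      tf <- sum(all_toks[[i]] == term)
      df <- sum(vapply(all_toks, function(t) term %in% t, TRUE))
      expect_equal(dense[j], tf * log(length(docs) / df), tolerance = 1e-12)
    }
  }
})

test_that("tfidf edge rules: ubiquitous, absent and OOV terms; N = 0", {
  docs <- list(clean_document("a", list(c("x", "y"))),
               clean_document("b", list(c("x", "q", "q", "q"))))
  stats <- tfidf_fit(docs, min_df = 1)
  va <- tfidf_vectorize(docs[[1]], stats)
  # x occurs in every document: idf = ln(1) = 0
  expect_equal(as.numeric(va[match("x", stats$terms)]), 0)
  # q absent from doc a
  expect_equal(as.numeric(va[match("q", stats$terms)]), 0)
  # tf = 3, N = 2, df = 1 -> 3 ln 2
  vb <- tfidf_vectorize(docs[[2]], stats)
  expect_equal(as.numeric(vb[match("q", stats$terms)]), 3 * log(2))
  # OOV terms are dropped
  d_new <- clean_document("c", list(c("zzz", "y")))
  vc <- tfidf_vectorize(d_new, stats)
  expect_equal(sum(as.numeric(vc[seq_along(stats$terms)]) != 0), 1)
  expect_error(tfidf_fit(list()), "N = 0")
})

test_that("embed_document pads, truncates and zeroes exactly", {
  vocab <- build_vocabulary(list(clean_document("a", list(c("x", "y", "z"))),
                                 clean_document("b", list(c("x", "y", "z")))),
                            min_df = 1)
  emb <- random_embedding_table(vocab, dim = 4, seed = 2)
  empty <- clean_document("e", list())
  expect_true(all(embed_document(empty, emb, 5) == 0))
  d3 <- clean_document("d", list(c("x", "y", "z")))
  m <- embed_document(d3, emb, 5)
  expect_equal(dim(m), c(5L, 4L))
  norms <- sqrt(rowSums(m^2))
  expect_true(all(norms[1:3] > 0))
  expect_identical(norms[4:5], c(0, 0))
  d6 <- clean_document("f", list(c("x", "y", "z", "x", "y", "z")))
  m6 <- embed_document(d6, emb, 5)
  expect_equal(m6[5, ], unname(emb["y", ]))
  # OOV tokens share the single zero-initialised unknown row
  doov <- clean_document("g", list(c("nope", "x")))
  moov <- embed_document(doov, emb, 2)
  expect_equal(moov[1, ], unname(emb["<unk>", ]))
})

test_that("word2vec text format round-trips", {
  vocab <- build_vocabulary(mk_docs(3, c("alpha", "beta", "gamma")),
                            min_df = 1)
  emb <- random_embedding_table(vocab, dim = 5, seed = 8)
  path <- withr::local_tempfile(fileext = ".txt")
  write_word2vec(emb, path)
  back <- read_word2vec(path)
  expect_setequal(rownames(back), rownames(emb))
  expect_equal(back[rownames(emb), ], emb, tolerance = 1e-6)
  aligned <- align_embeddings(back, vocab)
  expect_equal(nrow(aligned), length(vocab$tokens))
})

test_that("paragraph vectors: length, determinism and duplicate affinity", {
  vocabulary <- prerob:::synth_filler_vocab()
  corp <- lapply(1:50, function(i) {
    set.seed(i + 700)
    clean_document(paste0("dv", i), list(sample(vocabulary, 25, TRUE)))
  })
  corp[[51]] <- clean_document("dup", corp[[1]]$sentences)
  dv <- train_doc_vectors(corp, dim_dm = 15, dim_dbow = 15, seed = 9,
                          epochs = 8)
  expect_length(dv$vectors[[1]], 30)
  dv2 <- train_doc_vectors(corp, dim_dm = 15, dim_dbow = 15, seed = 9,
                           epochs = 8)
  expect_identical(dv$vectors, dv2$vectors)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  dup_sim <- cosv(dv$vectors[["dv1"]], dv$vectors[["dup"]])
  set.seed(42)
  rand_sim <- replicate(100, {
    ij <- sample(2:50, 2)
    cosv(dv$vectors[[ij[1]]], dv$vectors[[ij[2]]])
  })
  expect_gt(dup_sim, mean(rand_sim))
  # inference path embeds unseen documents deterministically
  unseen <- clean_document("new", list(sample(vocabulary, 20)))
  expect_identical(infer_doc_vector(unseen, dv$model),
                   infer_doc_vector(unseen, dv$model))
  expect_error(train_doc_vectors(corp, dim_dm = 0), "positive")
})
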