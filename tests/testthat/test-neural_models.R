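test_that("cnn_forward matches the hand element-wise example", {
  spec <- conv_spec(2L, 1L, dropout = 0)
  w <- prerob:::cnn_init(spec, 2, seed = 1)
  w$conv2$W[, 1] <- 1
  w$conv2$b[] <- 0
  x <- matrix(c(1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  attr(x, "n_tokens") <- 3L
  fw <- cnn_forward(x, spec, w)
  expect_equal(fw$pooled, 3)           # conv [2,3] -> relu -> max-pool 3
  w$conv2$W[, 1] <- 0                   # all-zero filter pools to 0
  expect_equal(cnn_forward(x, spec, w)$pooled, 0)
})

test_that("cnn output is two logits regardless of document length", {
  spec <- conv_spec(c(2L, 3L), 4L, dropout = 0)
  w <- prerob:::cnn_init(spec, 3, seed = 2)
  for (s in c(5, 40, 200)) {
    set.seed(s)
    x <- matrix(rnorm(s * 3), s, 3)
    attr(x, "n_tokens") <- s
    expect_length(cnn_forward(x, spec, w)$logits, 2)
  }
  short <- matrix(0, 1, 3)
  attr(short, "n_tokens") <- 1L
  expect_error(cnn_forward(short, spec, w), "shorter")
})

test_that("cnn_forward equals the brute-force double-loop oracle", {
  spec <- conv_spec(c(2L, 3L), 3L, dropout = 0)
  w <- prerob:::cnn_init(spec, 4, seed = 3)
  for (i in 1:25) {
    set.seed(i)
    x <- matrix(rnorm(24), 6, 4)
    attr(x, "n_tokens") <- 6L
    expect_equal(cnn_forward(x, spec, w)$logits,
                 cnn_logits_oracle(x, spec, w), tolerance = 1e-6)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(5)
  d <- 3
  # cnn
  cspec <- conv_spec(c(2L, 3L), 4L, dropout = 0)
  cw <- prerob:::cnn_init(cspec, d, seed = 2)
  x <- matrix(rnorm(6 * d), 6, d)
  attr(x, "n_tokens") <- 6L
  err <- fd_grad_check(function(p) {
    fw <- cnn_forward(x, cspec, p)
    ls <- prerob:::softmax_xent(fw$logits, 1)
    list(loss = ls$loss, grads = prerob:::cnn_backward(ls$dlogits, fw$cache))
  }, cw)
  expect_lt(err, 1e-4)
  # bidirectional gru and lstm with attention
  xr <- matrix(rnorm(5 * d), 5, d)
  attr(xr, "n_tokens") <- 5L
  for (cell in c("gru", "lstm")) {
    rspec <- attn_rnn_spec(cell, hidden_size = 4L)
    rw <- prerob:::rnn_attn_init(rspec, d, seed = 3)
    err <- fd_grad_check(function(p) {
      fw <- rnn_attention_forward(xr, rspec, p)
      ls <- prerob:::softmax_xent(fw$logits, 0)
      list(loss = ls$loss,
           grads = prerob:::rnn_attn_backward(ls$dlogits, fw$cache))
    }, rw)
    expect_lt(err, 1e-4)
  }
  # han with both sentence encoders
  sm <- list(matrix(rnorm(4 * d), 4, d), matrix(rnorm(2 * d), 2, d),
             matrix(rnorm(3 * d), 3, d))
  for (senc in c("projection", "gru")) {
    hspec <- han_spec(word_hidden = 3L, sent_hidden = 4L,
                      sentence_encoder = senc)
    hw <- prerob:::han_init(hspec, d, seed = 5)
    err <- fd_grad_check(function(p) {
      fw <- han_forward(sm, hspec, p)
      ls <- prerob:::softmax_xent(fw$logits, 1)
      list(loss = ls$loss,
           grads = prerob:::han_backward(ls$dlogits, fw$cache))
    }, hw)
    expect_lt(err, 1e-4)
  }
})

test_that("attention distributions are simplex-valued on random inputs", {
  set.seed(6)
  rspec <- attn_rnn_spec("gru", hidden_size = 5L)
  rw <- prerob:::rnn_attn_init(rspec, 4, seed = 6)
  hspec <- han_spec(word_hidden = 4L, sent_hidden = 4L)
  hw <- prerob:::han_init(hspec, 4, seed = 6)
  for (i in 1:20) {
    s <- sample(2:30, 1)
    x <- matrix(rnorm(s * 4), s, 4)
    attr(x, "n_tokens") <- s
    a <- rnn_attention_forward(x, rspec, rw)$attention
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1, tolerance = 1e-5)
    sm <- lapply(seq_len(sample(2:6, 1)), function(j) {
      matrix(rnorm(sample(2:8, 1) * 4), ncol = 4)
    })
    fw <- han_forward(sm, hspec, hw)
    expect_equal(sum(fw$sentence_attention), 1, tolerance = 1e-5)
    for (wa in fw$word_attention) {
      expect_true(all(wa >= 0))
      expect_equal(sum(wa), 1, tolerance = 1e-5)
    }
  }
})

test_that("uniform attention reduces the context to the mean hidden state", {
  set.seed(7)
  rspec <- attn_rnn_spec("gru", hidden_size = 4L)
  rw <- prerob:::rnn_attn_init(rspec, 3, seed = 7)
  # constant scores: zero the attention projection and direction
  rw$attn$Wa[] <- 0
  rw$attn$va[] <- 0
  x <- matrix(rnorm(18), 6, 3)
  attr(x, "n_tokens") <- 6L
  fw <- rnn_attention_forward(x, rspec, rw)
  expect_equal(unname(fw$attention), rep(1 / 6, 6), tolerance = 1e-12)
  H <- do.call(rbind, fw$cache$enc$H)
  expect_equal(drop(fw$cache$ctx), colMeans(H), tolerance = 1e-12)
})

test_that("single-sentence documents get sentence attention exactly 1", {
  hspec <- han_spec(word_hidden = 3L, sent_hidden = 3L)
  hw <- prerob:::han_init(hspec, 3, seed = 8)
  fw <- han_forward(list(matrix(rnorm(9), 3, 3)), hspec, hw)
  expect_equal(unname(fw$sentence_attention), 1)
})

test_that("permuting sentences permutes HAN sentence scores identically", {
  set.seed(9)
  hspec <- han_spec(word_hidden = 3L, sent_hidden = 4L)
  hw <- prerob:::han_init(hspec, 3, seed = 9)
  sm <- lapply(1:5, function(j) matrix(rnorm(9), 3, 3))
  base <- han_forward(sm, hspec, hw)$sentence_attention
  perm <- c(3, 1, 5, 2, 4)
  permuted <- han_forward(sm[perm], hspec, hw)$sentence_attention
  expect_equal(permuted, base[perm], tolerance = 1e-10)
})

test_that("imbalance handling: weights and undersampling counts", {
  expect_equal(unname(class_loss_weights(c(0, 0, 1, 1))), c(1, 1))
  set.seed(10)
  labels <- c(rep(1L, round(1000 * 0.122)), rep(0L, 1000 - round(1000 * 0.122)))
  idx <- undersample_indices(labels, seed = 10)
  expect_equal(sum(labels[idx] == 1), 122)
  expect_equal(sum(labels[idx] == 0), 122)
})
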