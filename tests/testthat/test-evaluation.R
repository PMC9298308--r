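test_that("confusion counts follow the four definitions", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cc)[c("tp", "fn", "fp", "tn")],
               list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0)
  allmiss <- confusion(rep(1, 7), rep(0, 7))
  expect_equal(allmiss$fn, 7)
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("metrics agree with a per-record counting oracle", {
  set.seed(14)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    labels <- rbinom(n, 1, 0.4)
    preds <- rbinom(n, 1, 0.5)
    m <- metrics(confusion(labels, preds))
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (labels[j] == 1 && preds[j] == 1) tp <- tp + 1
      if (labels[j] == 0 && preds[j] == 1) fp <- fp + 1
      if (labels[j] == 0 && preds[j] == 0) tn <- tn + 1
      if (labels[j] == 1 && preds[j] == 0) fn <- fn + 1
    }
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1 <- if (recall + precision == 0) 0 else
      2 * recall * precision / (recall + precision)
    expect_equal(m$recall, recall)
    expect_equal(m$precision, precision)
    expect_equal(m$f1, f1)
    expect_equal(m$specificity, if (tn + fp == 0) 0 else tn / (tn + fp))
    if (tp > 0) expect_gt(m$f1, 0) else expect_equal(m$f1, 0)
    if (m$f1 > 0) {
      expect_gte(m$f1, min(recall, precision) - 1e-12)
      expect_lte(m$f1, max(recall, precision) + 1e-12)
    }
  }
})

test_that("F1 recomputes published recall/precision pairs", {
  # rule-based baseline rows: recall/precision pairs reported alongside F1
  expect_equal(f1_from_recall_precision(33.8, 87.1), 48.7, tolerance = 0.005)
  expect_equal(f1_from_recall_precision(59.8, 79.6), 68.3, tolerance = 0.005)
  # degenerate: no true positives
  m0 <- metrics(confusion(c(1, 1, 0), c(0, 0, 0)))
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)
  expect_equal(m0$f1, 0)
})

test_that("exact McNemar p equals exhaustive enumeration for b+c <= 12", {
  for (n in 0:12) {
    for (b in 0:n) {
      c_ <- n - b
      # b records a-correct/b-wrong, c the reverse, plus 2 concordant
      labels <- rep(0L, n + 2)
      pa <- labels; pb <- labels
      if (b > 0) pb[seq_len(b)] <- 1L           # b wrong, a correct
      if (c_ > 0) pa[b + seq_len(c_)] <- 1L     # a wrong, b correct
      r <- mcnemar_test(labels, pa, pb)
      expect_equal(r$b, b)
      expect_equal(r$c, c_)
      expect_equal(r$p_value, mcnemar_p_enum(b, c_), tolerance = 1e-12)
    }
  }
})

test_that("McNemar edge rules and monotonicity", {
  # b = c: symmetric -> p = 1
  labels <- rep(0L, 6)
  pa <- c(1L, 1L, 0L, 0L, 0L, 0L)
  pb <- c(0L, 0L, 1L, 1L, 0L, 0L)
  expect_equal(mcnemar_test(labels, pa, pb)$p_value, 1)
  # worked binomial example: b = 10, c = 2
  labels <- rep(0L, 12)
  pa <- labels; pb <- labels
  pb[1:10] <- 1L; pa[11:12] <- 1L
  expect_equal(mcnemar_test(labels, pa, pb)$p_value, 158 / 4096,
               tolerance = 1e-12)
  # b = 1, c = 0 -> two-sided p = 1
  expect_equal(mcnemar_test(0L, 0L, 1L)$p_value, 1)
  # degenerate: no discordant pairs
  r0 <- mcnemar_test(c(1, 0), c(1, 0), c(1, 0))
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)
  # larger |b - c| at fixed b + c gives smaller p
  ps <- vapply(6:10, function(b) {
    labels <- rep(0L, 10)
    pa <- labels; pb <- labels
    pb[seq_len(b)] <- 1L
    if (b < 10) pa[b + seq_len(10 - b)] <- 1L
    mcnemar_test(labels, pa, pb)$p_value
  }, 0)
  expect_true(all(diff(ps) < 0))
  # chi-square alternative is available and agrees directionally
  labels <- rep(0L, 40)
  pa <- labels; pb <- labels
  pb[1:25] <- 1L; pa[26:30] <- 1L
  ex <- mcnemar_test(labels, pa, pb, method = "exact")$p_value
  ch <- mcnemar_test(labels, pa, pb, method = "chisq")$p_value
  expect_lt(ex, 0.05)
  expect_lt(ch, 0.05)
})

test_that("model selection maximises F1 with recall then key tie-breaks", {
  ms <- list(cnn = list(f1 = 86.4, recall = 93.2),
             rnn = list(f1 = 87.2, recall = 92.4),
             han = list(f1 = 86.2, recall = 91.3))
  expect_identical(select_best(ms), "rnn")
  expect_identical(select_best(ms["han"]), "han")
  tie <- list(a = list(f1 = 80, recall = 70), b = list(f1 = 80, recall = 75))
  expect_identical(select_best(tie), "b")
  tie2 <- list(z = list(f1 = 80, recall = 70), a = list(f1 = 80, recall = 70))
  expect_identical(select_best(tie2), "a")
})

test_that("error-corrupted synthetic predictions behave as configured", {
  gp <- generate_labelled_predictions(1000, prevalence = 0.275,
                                      fn_rate = 0, fp_rate = 0, seed = 2)
  expect_equal(sum(gp$labels), 275)
  expect_identical(gp$labels, gp$preds)
  expect_equal(metrics(confusion(gp$labels, gp$preds))$f1, 1)
  gp2 <- generate_labelled_predictions(1000, prevalence = 0.275,
                                       fn_rate = 0, fp_rate = 0, seed = 2)
  expect_identical(gp2$preds, gp$preds)
  # symmetric 0.5 flips: F1 concentrates near the analytic value
  # recall -> 0.5; precision -> p/(p + (1-p)) with p = prevalence... at
  # flip 0.5 preds are coin flips: precision -> prevalence, so
  # F1 -> 2*0.5*q/(0.5+q), q = prevalence
  sims <- vapply(1:200, function(s) {
    g <- generate_labelled_predictions(400, prevalence = 0.3,
                                       fn_rate = 0.5, fp_rate = 0.5,
                                       seed = s)
    metrics(confusion(g$labels, g$preds))$f1
  }, 0)
  q <- 0.3
  expect_equal(mean(sims), 2 * 0.5 * q / (0.5 + q), tolerance = 0.02)
})

test_that("evaluation report emits the documented columns", {
  rep <- evaluation_report(list(
    cnn = list(labels = c(1, 0, 1), preds = c(1, 0, 0),
               item = "blinding", split = "test")
  ))
  expect_identical(names(rep),
                   c("item", "model", "split", "tp", "fp", "tn", "fn",
                     "recall", "precision", "f1", "specificity"))
  expect_equal(rep$recall, 50.0)
})
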