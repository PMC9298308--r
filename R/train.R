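#' Construct an (untrained) neural document classifier
#'
#' @param type `"cnn"`, `"rnn"` or `"han"`.
#' @param spec A [conv_spec()], [attn_rnn_spec()] or [han_spec()] matching
#'   `type`.
#' @param embeddings Embedding matrix with token row names (frozen during
#'   training; pretrained vectors are an input, not an output).
#' @param s_max Maximum document length in tokens for `"cnn"`/`"rnn"`
#'   (default 5000).
#' @param max_sentences,max_sent_tokens Caps for `"han"` input (defaults
#'   200 and 60).
#' @param seed Seed for weight initialisation.
#' @return A `neural_model`.
#' @export
neural_model <- function(type = c("cnn", "rnn", "han"), spec, embeddings,
                         s_max = 5000L, max_sentences = 200L,
                         max_sent_tokens = 60L, seed = 1L) {
  type <- match.arg(type)
  d <- ncol(embeddings)
  weights <- switch(type,
                    cnn = cnn_init(spec, d, seed),
                    rnn = rnn_attn_init(spec, d, seed),
                    han = han_init(spec, d, seed))
  structure(
    list(type = type, spec = spec, embeddings = embeddings,
         s_max = as.integer(s_max), max_sentences = as.integer(max_sentences),
         max_sent_tokens = as.integer(max_sent_tokens),
         weights = weights, threshold = 0.5, seed = as.integer(seed),
         history = NULL),
    class = "neural_model"
  )
}

#' @exportS3Method base::print
print.neural_model <- function(x, ...) {
  trained <- if (is.null(x$history)) "untrained" else
    sprintf("trained, best valid F1 %.3f (epoch %d)",
            max(x$history$valid_f1), which.max(x$history$valid_f1))
  cat(sprintf("<neural_model %s: %s>\n", x$type, trained))
  invisible(x)
}

#' Build the model-specific input representation of a document
#' @param model A `neural_model`.
#' @param doc A `clean_document`.
#' @return Document matrix (cnn/rnn) or list of sentence matrices (han).
#' @export
doc_representation <- function(model, doc) {
  tab <- model$embeddings
  d <- ncol(tab)
  if (model$type == "cnn") {
    embed_document(doc, tab, model$s_max)
  } else if (model$type == "rnn") {
    toks <- doc_tokens(doc)
    toks <- head(toks, model$s_max)
    if (length(toks) == 0) {
      x <- matrix(0, 1, d)
      attr(x, "n_tokens") <- 1L
      x
    } else {
      x <- embed_tokens(toks, tab)
      attr(x, "n_tokens") <- nrow(x)
      x
    }
  } else {
    sents <- head(doc$sentences, model$max_sentences)
    if (length(sents) == 0) sents <- list(character(0))
    lapply(sents, function(s) {
      s <- head(s, model$max_sent_tokens)
      if (length(s) == 0) matrix(0, 1, d) else embed_tokens(s, tab)
    })
  }
}

model_forward <- function(model, rep, train = FALSE) {
  switch(model$type,
         cnn = cnn_forward(rep, model$spec, model$weights, train = train),
         rnn = rnn_attention_forward(rep, model$spec, model$weights),
         han = han_forward(rep, model$spec, model$weights))
}

model_backward <- function(model, dlogits, cache) {
  switch(model$type,
         cnn = cnn_backward(dlogits, cache),
         rnn = rnn_attn_backward(dlogits, cache),
         han = han_backward(dlogits, cache))
}

#' Predict the probability that a document reports the item
#' @param model A (trained) `neural_model`.
#' @param doc A `clean_document`, or a pre-built representation.
#' @return Probability of "reported" (softmax over the two logits).
#' @export
predict_neural <- function(model, doc) {
  rep <- if (inherits(doc, "clean_document")) {
    doc_representation(model, doc)
  } else doc
  model_forward(model, rep, train = FALSE)$probs[2]
}

#' Class-balancing loss weights
#'
#' Inverse-prevalence weights normalised so that balanced classes get
#' `(1, 1)`: class `c` receives `n / (2 * n_c)`.
#'
#' @param labels 0/1 vector.
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
class_loss_weights <- function(labels) {
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Undersample the majority class to the minority count
#' @param labels 0/1 vector.
#' @param seed Optional seed.
#' @return Integer indices of the retained, class-balanced subsample.
#' @export
undersample_indices <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) <= length(neg)) {
    keep <- c(pos, sample(neg, length(pos)))
  } else {
    keep <- c(sample(pos, length(neg)), neg)
  }
  sort(keep)
}

#' Train a neural classifier with validation-F1 checkpointing
#'
#' Per-document Adam updates of softmax cross-entropy; the checkpoint kept
#' is the epoch with the highest validation F1 (the model-selection metric
#' throughout). Class imbalance can be addressed by inverse-prevalence loss
#' weighting or by undersampling the majority class each epoch. If the
#' validation split contains no positive documents, selection falls back to
#' validation loss with a warning.
#'
#' @param model A `neural_model`.
#' @param train_docs,valid_docs Lists of `clean_document`s.
#' @param item Risk-of-bias item key (labels are read from the documents).
#' @param config List: `epochs` (10), `lr` (1e-3), `batch` (32, gradient
#'   accumulation size), `imbalance` (`"none"`, `"loss-weighting"`,
#'   `"undersampling"`), `seed` (1), `verbose` (FALSE).
#' @return The trained `neural_model`, with `history` (per-epoch data frame
#'   of train loss and validation recall/precision/F1) and weights set to
#'   the selected checkpoint.
#' @export
train_neural <- function(model, train_docs, valid_docs, item,
                         config = list()) {
  cfg <- utils::modifyList(
    list(epochs = 10L, lr = 1e-3, batch = 32L, imbalance = "none",
         seed = 1L, verbose = FALSE),
    config
  )
  stopifnot(length(train_docs) > 0, length(valid_docs) > 0)
  stopifnot(cfg$imbalance %in% c("none", "loss-weighting", "undersampling"))
  y_train <- corpus_labels(train_docs, item)
  y_valid <- corpus_labels(valid_docs, item)
  keep <- !is.na(y_train)
  train_docs <- train_docs[keep]; y_train <- y_train[keep]
  keepv <- !is.na(y_valid)
  valid_docs <- valid_docs[keepv]; y_valid <- y_valid[keepv]

  loss_w <- c("0" = 1, "1" = 1)
  if (cfg$imbalance == "loss-weighting") loss_w <- class_loss_weights(y_train)
  select_by_loss <- FALSE
  if (sum(y_valid == 1) == 0) {
    warning("validation split has no positive documents; ",
            "selecting checkpoint by validation loss")
    select_by_loss <- TRUE
  }

  reps_train <- lapply(train_docs, doc_representation, model = model)
  reps_valid <- lapply(valid_docs, doc_representation, model = model)

  set.seed(cfg$seed)
  opt <- adam_init(model$weights)
  best <- list(score = -Inf, weights = model$weights, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     valid_loss = numeric(0), valid_recall = numeric(0),
                     valid_precision = numeric(0), valid_f1 = numeric(0))

  for (ep in seq_len(cfg$epochs)) {
    idx <- seq_along(reps_train)
    if (cfg$imbalance == "undersampling") idx <- undersample_indices(y_train)
    idx <- sample(idx)
    total_loss <- 0
    acc <- NULL
    n_in_batch <- 0L
    for (i in idx) {
      fw <- model_forward(model, reps_train[[i]], train = TRUE)
      y <- y_train[i]
      ls <- softmax_xent(fw$logits, y, loss_w[[as.character(y)]])
      total_loss <- total_loss + ls$loss
      g <- model_backward(model, ls$dlogits, fw$cache)
      acc <- if (is.null(acc)) g else acc_grads_deep(acc, g)
      n_in_batch <- n_in_batch + 1L
      if (n_in_batch >= cfg$batch) {
        st <- adam_step(model$weights, scale_grads(acc, 1 / n_in_batch),
                        opt, lr = cfg$lr)
        model$weights <- st$params
        opt <- st$state
        acc <- NULL; n_in_batch <- 0L
      }
    }
    if (n_in_batch > 0) {
      st <- adam_step(model$weights, scale_grads(acc, 1 / n_in_batch),
                      opt, lr = cfg$lr)
      model$weights <- st$params
      opt <- st$state
    }

    vloss <- 0
    probs <- vapply(reps_valid, function(r) {
      model_forward(model, r, train = FALSE)$probs[2]
    }, 0)
    for (j in seq_along(probs)) {
      p <- min(max(probs[j], 1e-12), 1 - 1e-12)
      vloss <- vloss - (if (y_valid[j] == 1) log(p) else log(1 - p))
    }
    preds <- decide(probs, model$threshold)
    ms <- metrics(confusion(y_valid, preds))
    score <- if (select_by_loss) -vloss else ms$f1
    hist <- rbind(hist, data.frame(
      epoch = ep, train_loss = total_loss / length(idx),
      valid_loss = vloss / max(length(probs), 1),
      valid_recall = ms$recall, valid_precision = ms$precision,
      valid_f1 = ms$f1
    ))
    if (score > best$score) {
      best <- list(score = score, weights = model$weights, epoch = ep)
    }
    if (isTRUE(cfg$verbose)) {
      message(sprintf("epoch %d: train loss %.4f, valid F1 %.3f",
                      ep, total_loss / length(idx), ms$f1))
    }
  }
  model$weights <- best$weights
  model$history <- hist
  model$selected_epoch <- best$epoch
  model
}

acc_grads_deep <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) acc_grads_deep(a[[nm]], b[[nm]])
    else a[[nm]] + b[[nm]]
  }
  a
}

scale_grads <- function(g, k) {
  lapply(g, function(x) if (is.list(x)) scale_grads(x, k) else x * k)
}
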