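#' Fit a baseline document classifier
#'
#' Three families: a linear support vector machine (hinge loss, via
#' \pkg{e1071}), logistic regression (log loss, via [stats::glm()]) and a
#' random forest (an ensemble of decision trees grown on bootstrap
#' sub-samples, via \pkg{randomForest}). Any document representation
#' (TF-IDF, mean word embeddings, paragraph vectors) can be used as the
#' feature matrix.
#'
#' @param features Numeric matrix (dense or sparse), one row per document.
#' @param labels Binary vector (0/1), one per row of `features`.
#' @param family `"svm"`, `"logistic"` or `"random_forest"`.
#' @param hyperparams List: `C` (SVM cost, default 1), `n_trees` (forest
#'   size, default 500), `threshold` (decision threshold, default 0.5).
#' @param seed Integer seed; refitting with the same seed is deterministic.
#' @return A `baseline_model` with fields `family`, `fit`, `threshold`,
#'   `n_features`, `seed`.
#' @export
fit_baseline <- function(features, labels,
                         family = c("svm", "logistic", "random_forest"),
                         hyperparams = list(), seed = 1L) {
  family <- match.arg(family)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("degenerate training set: both classes must be present")
  }
  hp <- utils::modifyList(list(C = 1.0, n_trees = 500L, threshold = 0.5,
                               maxnodes = NULL, replace = TRUE),
                          hyperparams)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  set.seed(as.integer(seed))
  fit <- switch(
    family,
    svm = e1071::svm(x = features, y = factor(labels, levels = c(0, 1)),
                     kernel = "linear", cost = hp$C, scale = FALSE),
    logistic = suppressWarnings(
      glm.fit(cbind(1, features), labels, family = binomial())
    ),
    random_forest = {
      rf_args <- list(x = features, y = factor(labels, levels = c(0, 1)),
                      ntree = hp$n_trees, replace = hp$replace)
      if (!is.null(hp$maxnodes)) rf_args$maxnodes <- hp$maxnodes
      if (!hp$replace) rf_args$sampsize <- nrow(features)
      do.call(randomForest::randomForest, rf_args)
    }
  )
  structure(list(family = family, fit = fit, threshold = hp$threshold,
                 n_features = ncol(features), seed = as.integer(seed)),
            class = "baseline_model")
}

#' @exportS3Method base::print
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model: %s, %d features, threshold %.2f>\n",
              x$family, x$n_features, x$threshold))
  invisible(x)
}

#' Predict reporting probabilities from a baseline model
#'
#' SVM probabilities are sigmoid-mapped decision values (sign-preserving:
#' probability >= 0.5 exactly when the margin is non-negative); logistic
#' probabilities come from the fitted log-odds; forest probabilities are
#' vote fractions.
#'
#' @param model A `baseline_model`.
#' @param features Matrix with the same number of columns used at fit time.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_baseline <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 model$n_features, ncol(features)))
  }
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  switch(
    model$family,
    svm = {
      dv <- attr(predict(model$fit, features, decision.values = TRUE),
                 "decision.values")
      # e1071 orients the decision value by its internal level order
      if (colnames(dv)[1] == "0/1") dv <- -dv
      unname(plogis(drop(dv)))
    },
    logistic = {
      coefs <- model$fit$coefficients
      coefs[is.na(coefs)] <- 0  # rank-deficient columns carry no signal
      drop(plogis(cbind(1, features) %*% coefs))
    },
    random_forest = unname(predict(model$fit, features,
                                   type = "prob")[, "1"])
  )
}

#' Hard labels from probabilities (ties go positive)
#' @param probs Probability vector.
#' @param threshold Decision threshold.
#' @return Integer 0/1 vector; `prob >= threshold` maps to 1.
#' @export
decide <- function(probs, threshold = 0.5) as.integer(probs >= threshold)

#' Mean hinge loss of margin scores against +/-1 labels
#' @param scores Real-valued margins.
#' @param labels 0/1 labels.
#' @return Mean of `max(0, 1 - y * s)` with `y` in `{-1, +1}`.
#' @export
hinge_loss <- function(scores, labels) {
  y <- ifelse(labels == 1, 1, -1)
  mean(pmax(0, 1 - y * scores))
}

#' Mean log loss of probabilities against 0/1 labels
#' @param probs Probabilities.
#' @param labels 0/1 labels.
#' @param eps Clamp for numerical safety.
#' @return Mean negative log-likelihood.
#' @export
log_loss <- function(probs, labels, eps = 1e-12) {
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(ifelse(labels == 1, log(p), log(1 - p)))
}

#' Save a baseline model (binary with JSON sidecar)
#'
#' Writes `<path>` (RDS) plus `<path>.json` recording family, feature
#' count, threshold, seed and a format version.
#'
#' @param model A `baseline_model`.
#' @param path Output path.
#' @export
save_baseline <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(format_version = 1L, family = model$family,
         n_features = model$n_features, threshold = model$threshold,
         seed = model$seed),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Load a baseline model saved by [save_baseline()]
#' @param path Path given to [save_baseline()].
#' @return A `baseline_model`.
#' @export
load_baseline <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "baseline_model"))
  model
}
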