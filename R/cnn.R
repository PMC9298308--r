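#' Specification of a one-layer convolutional text classifier
#'
#' Filters of height `h` (tokens) and width `d` (the embedding dimension)
#' slide over the document matrix; each filter position contributes the sum
#' of the element-wise product between the filter and the `h x d` submatrix
#' starting there. ReLU, max-over-time pooling per filter, dropout (training
#' only) and a linear map to two logits follow, in that order.
#'
#' @param filter_sizes Integer vector of filter heights (default `c(3,4,5)`).
#' @param n_filters Filters per size (default 32).
#' @param dropout Dropout rate on the pooled feature vector (default 0.5).
#' @return A `conv_spec` list.
#' @export
conv_spec <- function(filter_sizes = c(3L, 4L, 5L), n_filters = 32L,
                      dropout = 0.5) {
  stopifnot(all(filter_sizes >= 1), n_filters >= 1,
            dropout >= 0, dropout < 1)
  structure(list(filter_sizes = as.integer(filter_sizes),
                 n_filters = as.integer(n_filters), dropout = dropout),
            class = "conv_spec")
}

cnn_init <- function(spec, d, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- list()
  for (h in spec$filter_sizes) {
    key <- paste0("conv", h)
    w[[key]] <- list(W = nn_mat(h * d, spec$n_filters),
                     b = numeric(spec$n_filters))
  }
  total <- length(spec$filter_sizes) * spec$n_filters
  w$out <- list(W = nn_mat(total, 2L), b = numeric(2L))
  w
}

unroll_rows <- function(X, h, s) {
  # (s - h + 1) x (h * d) matrix of flattened h x d windows (row-major by
  # window row, matching filters stored as stacked rows)
  n <- s - h + 1
  do.call(cbind, lapply(seq_len(h), function(off) {
    X[off:(off + n - 1), , drop = FALSE]
  }))
}

#' Forward pass of the convolutional classifier
#'
#' @param x Document matrix (`s_max x d`, zero-padded) with optional
#'   attribute `n_tokens`; rows beyond `n_tokens` are padding.
#' @param spec A [conv_spec()].
#' @param weights Weights from the internal initialiser or a trained model.
#' @param train Apply dropout (requires RNG) if `TRUE`.
#' @return List with `logits` (length 2), `probs` (softmax of the logits;
#'   second entry is the probability of "reported"), `pooled`, and `cache`
#'   for the backward pass.
#' @export
cnn_forward <- function(x, spec, weights, train = FALSE) {
  s <- attr(x, "n_tokens")
  if (is.null(s)) s <- nrow(x)
  s <- max(s, 1L)
  if (s < max(spec$filter_sizes) && nrow(x) < max(spec$filter_sizes)) {
    stop("document shorter than the largest filter")
  }
  # padding rows are zero, so windows overlapping padding contribute only
  # the real-token part; cap the window count at the true length where
  # possible to keep pooling over content
  s_eff <- max(s, min(nrow(x), max(spec$filter_sizes)))
  pooled <- c()
  conv_cache <- list()
  for (h in spec$filter_sizes) {
    key <- paste0("conv", h)
    A <- unroll_rows(x, h, s_eff)
    z <- addb(A %*% weights[[key]]$W, weights[[key]]$b)
    r <- pmax(z, 0)
    amax <- max.col(t(r), ties.method = "first")
    pool <- r[cbind(amax, seq_along(amax))]
    pooled <- c(pooled, pool)
    conv_cache[[key]] <- list(A = A, z = z, amax = amax)
  }
  drop_mask <- rep(1, length(pooled))
  if (train && spec$dropout > 0) {
    drop_mask <- rbinom(length(pooled), 1, 1 - spec$dropout) /
      (1 - spec$dropout)
  }
  dropped <- pooled * drop_mask
  logits <- drop(crossprod(weights$out$W, dropped)) + weights$out$b
  p <- exp(logits - max(logits)); p <- p / sum(p)
  list(logits = logits, probs = p, pooled = pooled,
       cache = list(conv = conv_cache, dropped = dropped,
                    drop_mask = drop_mask, spec = spec, weights = weights))
}

cnn_backward <- function(dlogits, cache, want_dx = FALSE, x_dim = NULL) {
  w <- cache$weights
  spec <- cache$spec
  g <- list(out = list(W = w$out$W * 0, b = dlogits))
  g$out$W <- outer(cache$dropped, dlogits)
  dpooled <- drop(w$out$W %*% dlogits) * cache$drop_mask
  dx <- if (want_dx) matrix(0, x_dim[1], x_dim[2]) else NULL
  off <- 0L
  for (h in spec$filter_sizes) {
    key <- paste0("conv", h)
    cc <- cache$conv[[key]]
    nf <- spec$n_filters
    dpool <- dpooled[off + seq_len(nf)]
    off <- off + nf
    dz <- matrix(0, nrow(cc$z), nf)
    sel <- cbind(cc$amax, seq_len(nf))
    dz[sel] <- dpool * (cc$z[sel] > 0)
    g[[key]] <- list(W = crossprod(cc$A, dz), b = colSums(dz))
    if (want_dx) {
      dA <- dz %*% t(w[[key]]$W)
      d <- x_dim[2]
      n <- nrow(dA)
      for (offr in seq_len(h)) {
        rows <- offr:(offr + n - 1)
        keep <- rows <= x_dim[1]
        dx[rows[keep], ] <- dx[rows[keep], , drop = FALSE] +
          dA[keep, (offr - 1) * d + seq_len(d), drop = FALSE]
      }
    }
  }
  if (want_dx) attr(g, "dx") <- dx
  g
}
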