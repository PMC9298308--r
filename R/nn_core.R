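# Minimal neural-network core: batched GRU/LSTM with BPTT, additive
# attention, Adam, and softmax cross-entropy. Layouts: sequences are lists
# over time steps of B x d matrices; masks are B x T (1 = real token).
# Gradients are verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

addb <- function(M, b) sweep(M, 2, b, "+")

nn_mat <- function(nr, nc) {
  matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

zeros_like <- function(params) lapply(params, function(p) p * 0)

acc_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

#' Masked row-wise softmax
#' @param s Numeric matrix of scores.
#' @param mask 0/1 matrix of the same shape; masked entries get weight 0.
#' @return Matrix of the same shape; each row with any unmasked entry sums
#'   to 1.
#' @keywords internal
masked_softmax <- function(s, mask = NULL) {
  if (!is.null(mask)) s[mask == 0] <- -Inf
  mx <- apply(s, 1, max)
  mx[!is.finite(mx)] <- 0
  e <- exp(s - mx)
  e[!is.finite(e)] <- 0
  sums <- rowSums(e)
  sums[sums == 0] <- 1
  e / sums
}

softmax_xent <- function(logits, y, w = 1) {
  # logits: length-2 vector; y in {0,1}; w: scalar sample weight
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  onehot <- c(1 - y, y)
  loss <- -w * log(max(p[y + 1], 1e-12))
  list(loss = loss, probs = p, dlogits = w * (p - onehot))
}

## ---- recurrent cells -------------------------------------------------

rnn_init <- function(cell, d, H) {
  if (cell == "gru") {
    list(Wz = nn_mat(d, H), Uz = nn_mat(H, H), bz = numeric(H),
         Wr = nn_mat(d, H), Ur = nn_mat(H, H), br = numeric(H),
         Wh = nn_mat(d, H), Uh = nn_mat(H, H), bh = numeric(H))
  } else {
    list(Wi = nn_mat(d, H), Ui = nn_mat(H, H), bi = numeric(H),
         Wf = nn_mat(d, H), Uf = nn_mat(H, H), bf = rep(1, H),
         Wo = nn_mat(d, H), Uo = nn_mat(H, H), bo = numeric(H),
         Wg = nn_mat(d, H), Ug = nn_mat(H, H), bg = numeric(H))
  }
}

rnn_forward <- function(X, p, cell, mask) {
  T_ <- length(X)
  B <- nrow(X[[1]])
  H <- length(p[[3]])
  h <- matrix(0, B, H)
  c_ <- matrix(0, B, H)
  Hs <- vector("list", T_)
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- X[[t]]
    m <- mask[, t]
    h_prev <- h; c_prev <- c_
    if (cell == "gru") {
      z <- sigmoid(addb(x %*% p$Wz + h_prev %*% p$Uz, p$bz))
      r <- sigmoid(addb(x %*% p$Wr + h_prev %*% p$Ur, p$br))
      hh <- tanh(addb(x %*% p$Wh + (r * h_prev) %*% p$Uh, p$bh))
      h_new <- (1 - z) * h_prev + z * hh
      h <- m * h_new + (1 - m) * h_prev
      cache[[t]] <- list(x = x, h_prev = h_prev, z = z, r = r, hh = hh,
                         m = m)
    } else {
      i <- sigmoid(addb(x %*% p$Wi + h_prev %*% p$Ui, p$bi))
      f <- sigmoid(addb(x %*% p$Wf + h_prev %*% p$Uf, p$bf))
      o <- sigmoid(addb(x %*% p$Wo + h_prev %*% p$Uo, p$bo))
      g <- tanh(addb(x %*% p$Wg + h_prev %*% p$Ug, p$bg))
      c_new <- f * c_prev + i * g
      tc <- tanh(c_new)
      h_new <- o * tc
      c_ <- m * c_new + (1 - m) * c_prev
      h <- m * h_new + (1 - m) * h_prev
      cache[[t]] <- list(x = x, h_prev = h_prev, c_prev = c_prev, i = i,
                         f = f, o = o, g = g, c_new = c_new, tc = tc,
                         m = m)
    }
    Hs[[t]] <- h
  }
  list(H = Hs, cache = list(steps = cache, cell = cell, p = p))
}

rnn_backward <- function(dH, cache) {
  p <- cache$p
  cell <- cache$cell
  steps <- cache$steps
  T_ <- length(steps)
  g <- zeros_like(p)
  B <- nrow(steps[[1]]$x)
  Hn <- ncol(dH[[1]])
  dX <- vector("list", T_)
  dh_carry <- matrix(0, B, Hn)
  dc_carry <- matrix(0, B, Hn)
  for (t in rev(seq_len(T_))) {
    s <- steps[[t]]
    dh <- dh_carry + dH[[t]]
    m <- s$m
    dh_new <- m * dh
    dh_prev <- (1 - m) * dh
    if (cell == "gru") {
      dhh <- dh_new * s$z
      dz <- dh_new * (s$hh - s$h_prev)
      dh_prev <- dh_prev + dh_new * (1 - s$z)
      da_h <- dhh * (1 - s$hh^2)
      g$Wh <- g$Wh + crossprod(s$x, da_h)
      g$Uh <- g$Uh + crossprod(s$r * s$h_prev, da_h)
      g$bh <- g$bh + colSums(da_h)
      drh <- da_h %*% t(p$Uh)
      dr <- drh * s$h_prev
      dh_prev <- dh_prev + drh * s$r
      da_r <- dr * s$r * (1 - s$r)
      g$Wr <- g$Wr + crossprod(s$x, da_r)
      g$Ur <- g$Ur + crossprod(s$h_prev, da_r)
      g$br <- g$br + colSums(da_r)
      dh_prev <- dh_prev + da_r %*% t(p$Ur)
      da_z <- dz * s$z * (1 - s$z)
      g$Wz <- g$Wz + crossprod(s$x, da_z)
      g$Uz <- g$Uz + crossprod(s$h_prev, da_z)
      g$bz <- g$bz + colSums(da_z)
      dh_prev <- dh_prev + da_z %*% t(p$Uz)
      dX[[t]] <- da_z %*% t(p$Wz) + da_r %*% t(p$Wr) + da_h %*% t(p$Wh)
      dh_carry <- dh_prev
    } else {
      dc <- m * dc_carry
      dc_prev <- (1 - m) * dc_carry
      do_ <- dh_new * s$tc
      dc <- dc + dh_new * s$o * (1 - s$tc^2)
      di <- dc * s$g
      df <- dc * s$c_prev
      dg <- dc * s$i
      dc_prev <- dc_prev + dc * s$f
      da_i <- di * s$i * (1 - s$i)
      da_f <- df * s$f * (1 - s$f)
      da_o <- do_ * s$o * (1 - s$o)
      da_g <- dg * (1 - s$g^2)
      g$Wi <- g$Wi + crossprod(s$x, da_i); g$Ui <- g$Ui + crossprod(s$h_prev, da_i)
      g$bi <- g$bi + colSums(da_i)
      g$Wf <- g$Wf + crossprod(s$x, da_f); g$Uf <- g$Uf + crossprod(s$h_prev, da_f)
      g$bf <- g$bf + colSums(da_f)
      g$Wo <- g$Wo + crossprod(s$x, da_o); g$Uo <- g$Uo + crossprod(s$h_prev, da_o)
      g$bo <- g$bo + colSums(da_o)
      g$Wg <- g$Wg + crossprod(s$x, da_g); g$Ug <- g$Ug + crossprod(s$h_prev, da_g)
      g$bg <- g$bg + colSums(da_g)
      dh_prev <- dh_prev + da_i %*% t(p$Ui) + da_f %*% t(p$Uf) +
        da_o %*% t(p$Uo) + da_g %*% t(p$Ug)
      dX[[t]] <- da_i %*% t(p$Wi) + da_f %*% t(p$Wf) +
        da_o %*% t(p$Wo) + da_g %*% t(p$Wg)
      dh_carry <- dh_prev
      dc_carry <- dc_prev
    }
  }
  list(grads = g, dX = dX)
}

bi_rnn_init <- function(cell, d, H) {
  list(fwd = rnn_init(cell, d, H), bwd = rnn_init(cell, d, H))
}

bi_rnn_forward <- function(X, p, cell, mask) {
  T_ <- length(X)
  fw <- rnn_forward(X, p$fwd, cell, mask)
  bw <- rnn_forward(rev(X), p$bwd, cell, mask[, rev(seq_len(T_)), drop = FALSE])
  H <- lapply(seq_len(T_), function(t) cbind(fw$H[[t]], bw$H[[T_ + 1 - t]]))
  list(H = H, cache = list(fw = fw$cache, bw = bw$cache, T_ = T_,
                           Hd = ncol(fw$H[[1]])))
}

bi_rnn_backward <- function(dH, cache) {
  T_ <- cache$T_
  Hd <- cache$Hd
  dHf <- lapply(dH, function(m) m[, seq_len(Hd), drop = FALSE])
  dHb_doc <- lapply(dH, function(m) m[, Hd + seq_len(Hd), drop = FALSE])
  dHb <- rev(dHb_doc)
  bf <- rnn_backward(dHf, cache$fw)
  bb <- rnn_backward(dHb, cache$bw)
  dX <- lapply(seq_len(T_), function(t) bf$dX[[t]] + bb$dX[[T_ + 1 - t]])
  list(grads = list(fwd = bf$grads, bwd = bb$grads), dX = dX)
}

## ---- additive attention over time ------------------------------------

attn_init <- function(K, A) {
  list(Wa = nn_mat(K, A), ba = numeric(A), va = runif(A, -1, 1) * sqrt(3 / A))
}

attn_forward <- function(H, p, mask) {
  # H: list over t of B x K; returns context (B x K) and weights (B x T)
  T_ <- length(H)
  B <- nrow(H[[1]])
  U <- vector("list", T_)
  s <- matrix(0, B, T_)
  for (t in seq_len(T_)) {
    U[[t]] <- tanh(addb(H[[t]] %*% p$Wa, p$ba))
    s[, t] <- U[[t]] %*% p$va
  }
  alpha <- masked_softmax(s, mask)
  ctx <- matrix(0, B, ncol(H[[1]]))
  for (t in seq_len(T_)) ctx <- ctx + alpha[, t] * H[[t]]
  list(ctx = ctx, alpha = alpha,
       cache = list(H = H, U = U, alpha = alpha, mask = mask, p = p))
}

attn_backward <- function(dctx, cache, dalpha_ext = NULL) {
  H <- cache$H; U <- cache$U; alpha <- cache$alpha; p <- cache$p
  T_ <- length(H)
  B <- nrow(H[[1]])
  dalpha <- matrix(0, B, T_)
  dH <- vector("list", T_)
  for (t in seq_len(T_)) {
    dalpha[, t] <- rowSums(dctx * H[[t]])
    dH[[t]] <- alpha[, t] * dctx
  }
  if (!is.null(dalpha_ext)) dalpha <- dalpha + dalpha_ext
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))
  if (!is.null(cache$mask)) ds[cache$mask == 0] <- 0
  g <- list(Wa = p$Wa * 0, ba = p$ba * 0, va = p$va * 0)
  for (t in seq_len(T_)) {
    dU <- ds[, t] %o% p$va
    g$va <- g$va + drop(crossprod(U[[t]], ds[, t]))
    daU <- dU * (1 - U[[t]]^2)
    g$Wa <- g$Wa + crossprod(H[[t]], daU)
    g$ba <- g$ba + colSums(daU)
    dH[[t]] <- dH[[t]] + daU %*% t(p$Wa)
  }
  list(grads = g, dH = dH)
}

## ---- optimiser -------------------------------------------------------

adam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0L)
}

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[nm]])) {
      out <- c(out, flatten_params(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

unflatten_into <- function(params, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    params[[path]] <- flat[[key]]
  }
  params
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1L
  for (key in names(fp)) {
    gk <- fg[[key]]
    if (is.null(gk)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * gk
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * gk^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    fp[[key]] <- fp[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = unflatten_into(params, fp), state = state)
}
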