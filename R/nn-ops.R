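# Low-level network primitives with hand-written backward passes.
#
# Layout conventions (chosen so every heavy op is one BLAS gemm):
#   * local feature batches: matrix (C*H*W) x N, each column one sample,
#     flattened channel-fastest: row index = c + C*(h-1) + C*H*(w-1)
#   * token batches: array (N, T, D); matrix(A, N*T, D) is the flat view
#     with token-t rows ((t-1)*N+1):(t*N)
# Convolutions use im2col with index vectors precomputed per layer shape.

#' Output spatial size of a convolution layer
#'
#' `floor((n + 2*padding - kernel) / stride) + 1`, the quotient form of the
#' standard convolution arithmetic.
#'
#' @param n Input size (>= 1).
#' @param kernel,stride,padding Layer geometry (`kernel`, `stride` >= 1,
#'   `padding` >= 0).
#' @return Integer output size; error if it would fall below 1.
#' @export
#' @examples
#' conv_output_size(32, 7, 2, 3)  # 16
conv_output_size <- function(n, kernel, stride, padding) {
  stopifnot(n >= 1, kernel >= 1, stride >= 1, padding >= 0)
  out <- (n + 2 * padding - kernel) %/% stride + 1
  if (out < 1) stop("conv_output_size: degenerate spatial size (", out, ")")
  as.integer(out)
}

#' Output spatial size of a pooling layer
#'
#' Same quotient arithmetic as [conv_output_size()]; the padding-free form
#' is the `padding = 0` special case.
#'
#' @inheritParams conv_output_size
#' @return Integer output size; error if it would fall below 1.
#' @export
#' @examples
#' pool_output_size(17, 3, 2, 0)  # 8
pool_output_size <- function(n, kernel, stride, padding = 0) {
  conv_output_size(n, kernel, stride, padding)
}

# ---- convolution ----------------------------------------------------------

conv_meta <- function(C, H, W, kernel, stride, pad) {
  outH <- conv_output_size(H, kernel, stride, pad)
  outW <- conv_output_size(W, kernel, stride, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  # rows of the unpadded sample inside the padded sample
  g <- expand.grid(c = seq_len(C), h = seq_len(H), w = seq_len(W))
  inner <- g$c + C * (g$h + pad - 1L) + C * Hp * (g$w + pad - 1L)
  # gather indices: offsets (c, dh, dw) fastest, then positions (oh, ow)
  off <- expand.grid(c = seq_len(C), dh = seq_len(kernel), dw = seq_len(kernel))
  pos <- expand.grid(oh = seq_len(outH), ow = seq_len(outW))
  hh <- outer(off$dh, (pos$oh - 1L) * stride, "+")        # (C*k*k) x P
  ww <- outer(off$dw, (pos$ow - 1L) * stride, "+")
  idx <- as.vector(off$c + C * (hh - 1L) + C * Hp * (ww - 1L))
  list(C = C, H = H, W = W, outH = outH, outW = outW,
       ck2 = C * kernel^2, P = outH * outW, npad = C * Hp * Wp,
       inner = inner, idx = idx)
}

conv2d_fwd <- function(X, Wm, b, meta) {
  N <- ncol(X)
  if (meta$npad == nrow(X) && all(meta$inner == seq_len(nrow(X)))) {
    Xpad <- X
  } else {
    Xpad <- matrix(0, meta$npad, N)
    Xpad[meta$inner, ] <- X
  }
  cols <- matrix(Xpad[meta$idx, , drop = FALSE], meta$ck2, meta$P * N)
  Y <- Wm %*% cols
  if (!is.null(b)) Y <- Y + b
  list(y = matrix(Y, nrow(Wm) * meta$P, N), cache = list(cols = cols, N = N))
}

conv2d_bwd <- function(dY, cache, Wm, meta) {
  outC <- nrow(Wm); N <- cache$N
  dYm <- matrix(dY, outC, meta$P * N)
  dW <- tcrossprod(dYm, cache$cols)            # outC x ck2
  db <- rowSums(dYm)
  dcols <- crossprod(Wm, dYm)                  # ck2 x (P*N)
  dcols_full <- matrix(dcols, meta$ck2 * meta$P, N)
  acc <- rowsum(dcols_full, meta$idx)
  dXpad <- matrix(0, meta$npad, N)
  dXpad[as.integer(rownames(acc)), ] <- acc
  list(dx = dXpad[meta$inner, , drop = FALSE], dW = dW, db = db)
}

# ---- max pooling ----------------------------------------------------------

pool_meta <- function(C, H, W, kernel, stride, pad) {
  outH <- pool_output_size(H, kernel, stride, pad)
  outW <- pool_output_size(W, kernel, stride, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  g <- expand.grid(c = seq_len(C), h = seq_len(H), w = seq_len(W))
  inner <- g$c + C * (g$h + pad - 1L) + C * Hp * (g$w + pad - 1L)
  pos <- expand.grid(c = seq_len(C), oh = seq_len(outH), ow = seq_len(outW))
  offs <- expand.grid(dh = seq_len(kernel), dw = seq_len(kernel))
  idx <- vapply(seq_len(nrow(offs)), function(o)
    as.integer(pos$c + C * ((pos$oh - 1L) * stride + offs$dh[o] - 1L) +
                 C * Hp * ((pos$ow - 1L) * stride + offs$dw[o] - 1L)),
    integer(nrow(pos)))                         # (C*P) x k^2
  idx <- matrix(idx, nrow = nrow(pos))          # vapply drops dim when P*C = 1
  list(C = C, outH = outH, outW = outW, P = outH * outW,
       npad = C * Hp * Wp, inner = inner, idx = idx, k2 = nrow(offs))
}

maxpool_fwd <- function(X, meta) {
  N <- ncol(X)
  Xpad <- matrix(-Inf, meta$npad, N)
  Xpad[meta$inner, ] <- X
  cur <- Xpad[meta$idx[, 1L], , drop = FALSE]
  arg <- matrix(1L, nrow(cur), N)
  for (o in seq_len(meta$k2)[-1L]) {
    cand <- Xpad[meta$idx[, o], , drop = FALSE]
    upd <- cand > cur
    arg[upd] <- o
    cur[upd] <- cand[upd]
  }
  list(y = cur, cache = list(arg = arg, N = N))
}

maxpool_bwd <- function(dY, cache, meta) {
  CP <- nrow(cache$arg); N <- cache$N
  chosen <- matrix(meta$idx[cbind(rep(seq_len(CP), N), as.vector(cache$arg))], CP, N)
  lin <- as.vector(chosen) + rep((seq_len(N) - 1L) * meta$npad, each = CP)
  acc <- rowsum(as.vector(dY), lin)
  dXpad <- numeric(meta$npad * N)
  dXpad[as.numeric(rownames(acc))] <- acc
  dXpad <- matrix(dXpad, meta$npad, N)
  dXpad[meta$inner, , drop = FALSE]
}

# ---- batch normalization (2d, per channel) --------------------------------

bn2d_fwd <- function(X, gamma, beta, C, aux_name, aux, training,
                     momentum = 0.1, eps = 1e-5) {
  HW <- nrow(X) %/% C; N <- ncol(X)
  chan <- rep(seq_len(C), times = HW)
  if (training) {
    M <- HW * N
    m <- rowSums(rowsum(X, chan)) / M
    v <- rowSums(rowsum(X * X, chan)) / M - m^2
    v <- pmax(v, 0)
    rm <- (1 - momentum) * aux[[paste0(aux_name, ".mean")]] + momentum * m
    unb <- if (M > 1) M / (M - 1) else 1
    rv <- (1 - momentum) * aux[[paste0(aux_name, ".var")]] + momentum * v * unb
    aux[[paste0(aux_name, ".mean")]] <- rm
    aux[[paste0(aux_name, ".var")]] <- rv
  } else {
    m <- aux[[paste0(aux_name, ".mean")]]
    v <- aux[[paste0(aux_name, ".var")]]
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (X - m[chan]) * ivar[chan]
  y <- gamma[chan] * xhat + beta[chan]
  list(y = y, cache = list(xhat = xhat, ivar = ivar, chan = chan,
                           M = HW * N, training = training, gamma = gamma))
}

bn2d_bwd <- function(dY, cache) {
  chan <- cache$chan
  dxhat <- dY * cache$gamma[chan]
  dgamma <- rowSums(rowsum(dY * cache$xhat, chan))
  dbeta <- rowSums(rowsum(dY, chan))
  if (cache$training) {
    M <- cache$M
    r1 <- rowSums(rowsum(dxhat, chan)) / M
    r2 <- rowSums(rowsum(dxhat * cache$xhat, chan)) / M
    dx <- cache$ivar[chan] * (dxhat - r1[chan] - cache$xhat * r2[chan])
  } else {
    dx <- cache$ivar[chan] * dxhat
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- elementwise ----------------------------------------------------------

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, y) dy * (y > 0)

gelu_fwd <- function(x) x * stats::pnorm(x)
gelu_bwd <- function(dy, x) dy * (stats::pnorm(x) + x * stats::dnorm(x))

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}
dropout_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

# ---- token-space ops ------------------------------------------------------

linear_fwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(X))
  Y
}

layernorm_fwd <- function(X, gamma, beta, eps = 1e-6) {
  R <- nrow(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * ivar
  y <- xhat * rep(gamma, each = R) + rep(beta, each = R)
  list(y = y, cache = list(xhat = xhat, ivar = ivar, gamma = gamma))
}

layernorm_bwd <- function(dY, cache) {
  R <- nrow(dY)
  dxhat <- dY * rep(cache$gamma, each = R)
  r1 <- rowMeans(dxhat)
  r2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$ivar * (dxhat - r1 - cache$xhat * r2)
  list(dx = dx, dgamma = colSums(dY * cache$xhat), dbeta = colSums(dY))
}

softmax_rows <- function(S) {
  e <- exp(S - apply(S, 1L, max))
  e / rowSums(e)
}

# Multi-head self-attention on a token array (N, T, D).
# Projections follow the Concat(head_1..head_h) W^O formulation; no
# projection biases (none appear in the defining equations).
mha_fwd <- function(A, Wq, Wk, Wv, Wo, h) {
  dm <- dim(A); N <- dm[1L]; T <- dm[2L]; D <- dm[3L]
  if (D %% h != 0) stop("multi_head_attention: head count must divide embed_dim")
  dh <- D %/% h; scale <- 1 / sqrt(dh)
  X <- matrix(A, N * T, D)
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  O <- matrix(0, N * T, D)
  Wgt <- array(0, c(N, T, T, h))
  rows <- function(t) ((t - 1L) * N + 1L):(t * N)
  for (i in seq_len(h)) {
    ci <- ((i - 1L) * dh + 1L):(i * dh)
    S <- array(0, c(N, T, T))
    for (t in seq_len(T)) {
      Qt <- Q[rows(t), ci, drop = FALSE]
      for (s in seq_len(T))
        S[, t, s] <- rowSums(Qt * K[rows(s), ci, drop = FALSE]) * scale
    }
    for (t in seq_len(T)) {
      Wgt[, t, , i] <- softmax_rows(matrix(S[, t, ], N, T))
      acc <- 0
      for (s in seq_len(T))
        acc <- acc + V[rows(s), ci, drop = FALSE] * Wgt[, t, s, i]
      O[rows(t), ci] <- acc
    }
  }
  Y <- O %*% Wo
  list(y = array(Y, c(N, T, D)),
       cache = list(X = X, Q = Q, K = K, V = V, O = O, Wgt = Wgt,
                    N = N, T = T, D = D, h = h, dh = dh, scale = scale))
}

mha_bwd <- function(dYarr, cache, Wq, Wk, Wv, Wo) {
  N <- cache$N; T <- cache$T; D <- cache$D
  h <- cache$h; dh <- cache$dh; scale <- cache$scale
  dY <- matrix(dYarr, N * T, D)
  dWo <- crossprod(cache$O, dY)
  dO <- tcrossprod(dY, Wo)
  dQ <- matrix(0, N * T, D); dK <- dQ; dV <- dQ
  rows <- function(t) ((t - 1L) * N + 1L):(t * N)
  for (i in seq_len(h)) {
    ci <- ((i - 1L) * dh + 1L):(i * dh)
    for (t in seq_len(T)) {
      dOt <- dO[rows(t), ci, drop = FALSE]
      dWgt <- matrix(0, N, T)
      for (s in seq_len(T)) {
        dWgt[, s] <- rowSums(dOt * cache$V[rows(s), ci, drop = FALSE])
        dV[rows(s), ci] <- dV[rows(s), ci] + cache$Wgt[, t, s, i] * dOt
      }
      Wt <- matrix(cache$Wgt[, t, , i], N, T)
      dS <- Wt * (dWgt - rowSums(dWgt * Wt))
      Qt <- cache$Q[rows(t), ci, drop = FALSE]
      dQt <- 0
      for (s in seq_len(T)) {
        dQt <- dQt + dS[, s] * cache$K[rows(s), ci, drop = FALSE] * scale
        dK[rows(s), ci] <- dK[rows(s), ci] + dS[, s] * Qt * scale
      }
      dQ[rows(t), ci] <- dQt
    }
  }
  dX <- tcrossprod(dQ, Wq) + tcrossprod(dK, Wk) + tcrossprod(dV, Wv)
  list(dx = array(dX, c(N, T, D)),
       dWq = crossprod(cache$X, dQ), dWk = crossprod(cache$X, dK),
       dWv = crossprod(cache$X, dV), dWo = dWo)
}
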