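# User-facing wrappers over the network internals: single operations with
# explicit inputs, used for inspection and testing. All take/return natural
# array shapes; the internal batch layouts stay private.

loc_to_array <- function(m, C, h, w) array(m, c(C, h, w, ncol(m)))
arr_to_loc <- function(a) {
  d <- dim(a)
  if (length(d) == 3L) d <- c(d, 1L)
  matrix(a, d[1] * d[2] * d[3], d[4])
}

#' Scaled dot-product attention
#'
#' `Softmax(Q K' / sqrt(d_k)) V` with `d_k = ncol(K)`. Each output row is a
#' convex combination of the rows of `V`; the attention weights (returned
#' as attribute `"weights"`) are row-stochastic.
#'
#' @param Q,K,V Numeric matrices; `K` and `V` must have equal row counts,
#'   `Q` and `K` equal column counts.
#' @return Matrix `nrow(Q) x ncol(V)` with attribute `"weights"`.
#' @export
#' @examples
#' Q <- matrix(rnorm(6), 2); K <- V <- matrix(rnorm(9), 3)
#' rowSums(attr(scaled_dot_attention(Q, K, V), "weights"))  # all 1
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(K) == 0L) stop("scaled_dot_attention: d_k = 0 (configuration error)")
  stopifnot(nrow(K) == nrow(V), ncol(Q) == ncol(K),
            all(is.finite(Q)), all(is.finite(K)), all(is.finite(V)))
  W <- softmax_rows(tcrossprod(Q, K) / sqrt(ncol(K)))
  structure(W %*% V, weights = W)
}

#' Multi-head self-attention
#'
#' Splits the embedding into `params$h` heads, runs scaled dot-product
#' attention per head on the projected tokens, concatenates the heads and
#' applies the output projection.
#'
#' @param x Token matrix `T x D` or batch array `(N, T, D)`.
#' @param params List with square `D x D` matrices `Wq`, `Wk`, `Wv`, `Wo`
#'   and head count `h` (must divide `D`).
#' @return Same shape as `x`.
#' @export
multi_head_attention <- function(x, params) {
  single <- is.matrix(x)
  A <- if (single) array(x, c(1L, nrow(x), ncol(x))) else x
  if (dim(A)[3] %% params$h != 0)
    stop("multi_head_attention: h must divide the embedding dim")
  y <- mha_fwd(A, params$Wq, params$Wk, params$Wv, params$Wo, params$h)$y
  if (single) matrix(y[1, , ], dim(A)[2], dim(A)[3]) else y
}

#' Layer normalization over the embedding axis
#'
#' `gamma * (x - mu) / sqrt(sigma^2 + eps) + beta`, with mean and variance
#' taken per row (per token).
#'
#' @param x Token matrix (rows = tokens) or `(N, T, D)` array.
#' @param gamma,beta Scale/shift vectors of length `ncol(x)` (default 1/0).
#' @param eps Variance floor.
#' @return Same shape as `x`.
#' @export
layer_norm <- function(x, gamma = NULL, beta = NULL, eps = 1e-6) {
  single <- is.matrix(x)
  X <- if (single) x else matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3])
  D <- ncol(X)
  if (is.null(gamma)) gamma <- rep(1, D)
  if (is.null(beta)) beta <- rep(0, D)
  y <- layernorm_fwd(X, gamma, beta, eps)$y
  if (single) y else array(y, dim(x))
}

#' Position-wise MLP block
#'
#' `Dropout(Dropout(GELU(x W1 + b1)) W2 + b2)`; dropout is the identity in
#' inference mode (`training = FALSE`) or at rate 0.
#'
#' @param x Matrix of token vectors (rows).
#' @param W1,b1,W2,b2 The two affine maps.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param training Apply dropout stochastically if `TRUE`.
#' @return Matrix of the same shape as `x`.
#' @export
mlp_block <- function(x, W1, b1, W2, b2, dropout = 0, training = FALSE) {
  h1 <- x %*% W1 + rep(b1, each = nrow(x))
  d1 <- dropout_fwd(gelu_fwd(h1), dropout, training)
  h2 <- d1$y %*% W2 + rep(b2, each = nrow(x))
  dropout_fwd(h2, dropout, training)$y
}

#' Patch embedding of spatial-spectral maps
#'
#' Partitions each map into `patch_size x patch_size` single-band patches,
#' flattens each and projects it to `embed_dim` with a shared linear map,
#' then adds a learned positional embedding. With 32 x 32 x 5 maps and
#' patch size 32, each band slice becomes one token (5 tokens).
#'
#' @param x A map, list of maps, or `(H, W, B, N)` array.
#' @param patch_size Patch edge; must tile H and W exactly.
#' @param embed_dim Token width (ignored when `params` given).
#' @param params Optional `list(W, b, pos)`; freshly initialized from
#'   `seed` when `NULL`.
#' @param seed Seed for fresh parameter initialization.
#' @return Token array `(N, n_tokens, embed_dim)`.
#' @export
patch_embed <- function(x, patch_size, embed_dim = 768, params = NULL, seed = 0L) {
  X <- as_map_batch(x)
  d <- if (is.list(x)) dim(x[[1]]) else dim(x)[1:3]
  H <- d[1]; W <- d[2]; B <- d[3]
  if (H %% patch_size != 0 || W %% patch_size != 0)
    stop("patch_embed: patch_size must divide the map dimensions")
  pm <- patch_meta(B, H, W, patch_size)
  if (is.null(params)) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    params <- list(W = init_lin(patch_size^2, embed_dim),
                   b = rep(0, embed_dim),
                   pos = matrix(init_normal(pm$n_tokens * embed_dim, 0.02),
                                pm$n_tokens, embed_dim))
  }
  D <- ncol(params$W); N <- ncol(X)
  G <- array(0, c(N, pm$n_tokens, D))
  for (t in seq_len(pm$n_tokens))
    G[, t, ] <- crossprod(X[pm$gidx[[t]], , drop = FALSE], params$W) +
      rep(params$b, each = N) + rep(params$pos[t, ], each = N)
  G
}

#' Stage-0 stem of the CNN branch
#'
#' `MaxPool(ReLU(BN(Conv7x7(x))))`: 7x7 stride-2 convolution (no bias) to
#' 64 channels, batch normalization, ReLU, then 3x3 stride-2 max pooling
#' (padding 1). Padding of the convolution follows
#' `config$stem_padding_mode`.
#'
#' @param model A [cit_init()] model.
#' @param x Map(s) accepted by [as_map_batch()].
#' @param training Batch statistics (`TRUE`) or running statistics.
#' @return Feature array `(64, h, w, N)`.
#' @export
stem_forward <- function(model, x, training = FALSE) {
  X <- as_map_batch(x)
  y <- stem_fwd(model, X, training)$y
  sz <- model$config$stage_sizes[1, ]
  loc_to_array(y, model$config$channels[1], sz[1], sz[2])
}

#' One residual basic block
#'
#' Main path `BN(Conv3x3(ReLU(BN(Conv3x3(x)))))` added to the shortcut and
#' passed through ReLU. The shortcut is the identity when shapes match, a
#' BN(Conv1x1) projection when the block downsamples, or the literal
#' BN(Conv1x1(Conv3x3(x))) composition when the model was configured with
#' `paper_exact_shortcut = TRUE`.
#'
#' @param model A [cit_init()] model.
#' @param stage,block Stage (1-4) and block (1-`blocks_per_stage`) index.
#' @param x `(C, h, w, N)` array matching the block's input shape.
#' @param training Batch-norm mode.
#' @return `(C', h', w', N)` array.
#' @export
basic_block_forward <- function(model, stage, block, x, training = FALSE) {
  m <- model$meta$cnn[[stage]][[block]]
  y <- block_fwd(model, stage, block, arr_to_loc(x), training)$y
  loc_to_array(y, m$outC, m$out_sz[1], m$out_sz[2])
}

#' One CNN stage (two basic blocks)
#'
#' @inheritParams basic_block_forward
#' @param k Stage index 1-4. Stage 1 preserves 64 channels and spatial
#'   size; stages 2-4 halve the spatial size and double the channels.
#' @return `(C_k, h_k, w_k, N)` array.
#' @export
cnn_stage_forward <- function(model, k, x, training = FALSE) {
  X <- arr_to_loc(x)
  for (j in seq_len(model$config$blocks_per_stage))
    X <- block_fwd(model, k, j, X, training)$y
  m <- model$meta$cnn[[k]][[model$config$blocks_per_stage]]
  loc_to_array(X, m$outC, m$out_sz[1], m$out_sz[2])
}

#' One Transformer stage (three encoder blocks)
#'
#' Each encoder block is pre-norm: `x + MSA(LN(x))` then `x + MLP(LN(x))`.
#' Token count and embedding width are preserved.
#'
#' @inheritParams basic_block_forward
#' @param k Stage index 1-4.
#' @param tokens `(N, T, D)` token array.
#' @return `(N, T, D)` token array.
#' @export
encoder_stage_forward <- function(model, k, tokens, training = FALSE) {
  for (j in seq_len(model$config$encoders_per_stage))
    tokens <- encoder_fwd(model, k, j, tokens, training)$y
  tokens
}

#' Local-to-global fusion block
#'
#' Spatially averages the CNN feature map (`F_Mean`), projects it to the
#' embedding width (`F_Linear = W' F_Mean + b`) and joins it to the token
#' sequence: prepended as a new fusion token (`fusion = "concat"`, the
#' default; all pre-existing tokens pass through unchanged) or added to
#' every token (`fusion = "add"`).
#'
#' @param model A [cit_init()] model.
#' @param k CIT stage (1-3).
#' @param f_local `(C_k, h, w, N)` array from CNN stage `k`.
#' @param f_global `(N, T, D)` tokens from Transformer stage `k`.
#' @return `(N, T', D)` tokens (`T' = T + 1` under concat fusion).
#' @export
l2g <- function(model, k, f_local, f_global) {
  l2g_fwd(model, k, arr_to_loc(f_local), f_global, training = FALSE)$y
}

#' Global-to-local fusion block
#'
#' Extracts the first token (`F_Squeeze`), broadcasts it over the local
#' spatial grid (`F_Expand`, spatially constant), concatenates it with the
#' CNN feature map along channels (`F_Concat`, `C_k + D` channels) and maps
#' back to `C_k` channels with a 1x1 convolution.
#'
#' @inheritParams l2g
#' @param return_intermediates Also return `F_Squeeze`, the `F_Expand`
#'   shape and the `F_Concat` channel count.
#' @return `(C_k, h, w, N)` array, or a list with `y` and intermediates.
#' @export
g2l <- function(model, k, f_global, f_local, return_intermediates = FALSE) {
  Xloc <- arr_to_loc(f_local)
  r <- g2l_fwd(model, k, f_global, Xloc, training = FALSE)
  d <- dim(f_local); if (length(d) == 3L) d <- c(d, 1L)
  y <- loc_to_array(r$y, d[1], d[2], d[3])
  if (!return_intermediates) return(y)
  N <- dim(f_global)[1]; D <- dim(f_global)[3]
  list(y = y,
       F_Squeeze = matrix(f_global[, 1, ], N),
       F_Expand_shape = c(D, d[2], d[3]),
       F_Concat_channels = nrow(r$cache$M),
       out_channels = d[1])
}

#' Apply (or bypass) CIT fusion after a stage
#'
#' For `k` in the model's enabled `cit_stages`, returns the fused pair
#' `(g2l output, l2g output)`; otherwise both branches pass through
#' unchanged (independent branches, late concatenation).
#'
#' @inheritParams l2g
#' @param f_local,f_global Stage-`k` outputs of the two branches.
#' @return `list(local =, global =)` inputs for stage `k + 1`.
#' @export
apply_cit <- function(model, k, f_local, f_global) {
  cfg <- model$config
  if (!(k %in% cfg$cit_stages) || !(cfg$l2g || cfg$g2l))
    return(list(local = f_local, global = f_global))
  out_local <- if (cfg$g2l) g2l(model, k, f_global, f_local) else f_local
  out_global <- if (cfg$l2g) l2g(model, k, f_local, f_global) else f_global
  list(local = out_local, global = out_global)
}

#' Forward pass of the assembled network
#'
#' @param model A [cit_init()] or trained model.
#' @param maps Input maps (list, single map, or `(H, W, B, N)` array).
#' @param training Use batch statistics and dropout if `TRUE`.
#' @return `N x num_classes` logit matrix (softmax is applied only inside
#'   the loss and in `predict(type = "prob")`).
#' @export
cit_forward <- function(model, maps, training = FALSE) {
  X <- as_map_batch(maps)
  expected <- model$config$bands * model$config$H * model$config$W
  if (nrow(X) != expected)
    stop("cit_forward: input has ", nrow(X), " values per sample, expected ",
         expected, " (configuration error)")
  cit_fwd_full(model, X, training = training)$logits
}
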