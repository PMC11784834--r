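#' Experiment configuration for the CIT network
#'
#' Collects every architecture and training hyper-parameter, including the
#' ablation switches. Defaults follow the published protocol: Adam with
#' learning rate 1e-5, batch size 32, dropout 0.2, a 6:4 train/test split,
#' cross-entropy loss; 7x7/stride-2 stem with 3x3 max pooling; channel plan
#' 64-64-128-256-512 with two residual blocks per CNN stage; patch size 32
#' (five band-patch tokens), embedding width 768, 8 attention heads, three
#' encoder blocks per Transformer stage; CIT fusion after stages 1-3.
#'
#' @param num_classes Number of emotion classes (>= 2; 3 or 4 in the
#'   reference datasets).
#' @param H,W,bands Input map dimensions (default 32 x 32 x 5).
#' @param embed_dim Token embedding width. 768 by default (the width the
#'   fusion-block shapes are stated for); 256 is the alternative stated
#'   with the patch embedding.
#' @param heads Attention heads (must divide `embed_dim`).
#' @param mlp_ratio Hidden width of the encoder MLP as a multiple of
#'   `embed_dim`.
#' @param patch_size Patch edge length; 32 turns each band slice into one
#'   token.
#' @param channels Channel plan for CNN stages 0-4.
#' @param blocks_per_stage Residual blocks per CNN stage (2).
#' @param encoders_per_stage Encoder blocks per Transformer stage (3).
#' @param stem_padding_mode `"standard"` (pad 3, giving the documented
#'   H/4 x W/4 stem output) or `"paper"` (pad 4 as printed, giving 9x9
#'   from 32x32).
#' @param paper_exact_shortcut If `TRUE`, every residual shortcut is the
#'   literal BN(Conv1x1(Conv3x3(x))) composition; default uses the
#'   standard identity/projection shortcut.
#' @param cit_stages Subset of `1:3` after which CIT fusion is applied.
#' @param fusion `"concat"` (fusion token prepended to the sequence,
#'   default) or `"add"` (projected local vector added to every token).
#' @param l2g,g2l Enable the local-to-global / global-to-local block.
#' @param tfm With `l2g`, keep (concatenate) the prior token sequence; if
#'   `FALSE` the fusion token replaces it.
#' @param cfm With `g2l`, concatenate the local feature map before the 1x1
#'   convolution; if `FALSE` the convolution sees only the broadcast token.
#' @param fusion_norm Apply LayerNorm to the fusion token (off by default;
#'   the fusion blocks contain no normalization as defined).
#' @param variant `"full"`, `"cnn_only"`, `"transformer_only"`, or
#'   `"baseline_concat"` (both branches, no fusion, late concatenation;
#'   identical to `"full"` with empty `cit_stages`).
#' @param dropout Dropout rate in the encoder MLPs and before the head.
#' @param learning_rate,batch_size,epochs Adam training protocol.
#' @param split_ratio Training fraction of the stratified split.
#' @param patience Early-stopping patience on the training-loss plateau.
#' @param seed Default seed for initialization/training.
#' @return An object of class `cit_config`.
#' @export
cit_config <- function(num_classes = 3, H = 32, W = 32, bands = 5,
                       embed_dim = 768, heads = 8, mlp_ratio = 4,
                       patch_size = 32,
                       channels = c(64, 64, 128, 256, 512),
                       blocks_per_stage = 2, encoders_per_stage = 3,
                       stem_padding_mode = c("standard", "paper"),
                       paper_exact_shortcut = FALSE,
                       cit_stages = 1:3,
                       fusion = c("concat", "add"),
                       l2g = TRUE, g2l = TRUE, tfm = TRUE, cfm = TRUE,
                       fusion_norm = FALSE,
                       variant = c("full", "cnn_only", "transformer_only",
                                   "baseline_concat"),
                       dropout = 0.2, learning_rate = 1e-5,
                       batch_size = 32, epochs = 100, split_ratio = 0.6,
                       patience = 10, seed = 1L) {
  stem_padding_mode <- match.arg(stem_padding_mode)
  fusion <- match.arg(fusion)
  variant <- match.arg(variant)
  stopifnot(num_classes >= 2, embed_dim %% heads == 0,
            split_ratio > 0, split_ratio < 1,
            dropout >= 0, dropout < 1, length(channels) == 5,
            all(cit_stages %in% 1:3))
  cit_stages <- sort(unique(as.integer(cit_stages)))
  if (variant %in% c("cnn_only", "transformer_only", "baseline_concat"))
    cit_stages <- integer(0)
  cfg <- list(num_classes = as.integer(num_classes), H = H, W = W,
              bands = bands, embed_dim = embed_dim, heads = heads,
              mlp_ratio = mlp_ratio, patch_size = patch_size,
              channels = channels, blocks_per_stage = blocks_per_stage,
              encoders_per_stage = encoders_per_stage,
              stem_padding_mode = stem_padding_mode,
              paper_exact_shortcut = paper_exact_shortcut,
              cit_stages = cit_stages, fusion = fusion,
              l2g = l2g, g2l = g2l, tfm = tfm, cfm = cfm,
              fusion_norm = fusion_norm, variant = variant,
              dropout = dropout, learning_rate = learning_rate,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              split_ratio = split_ratio, patience = as.integer(patience),
              seed = as.integer(seed))
  # spatial plan: stem then stage strides 1,2,2,2
  pad <- if (stem_padding_mode == "paper") 4L else 3L
  sH <- pool_output_size(conv_output_size(H, 7, 2, pad), 3, 2, 1)
  sW <- pool_output_size(conv_output_size(W, 7, 2, pad), 3, 2, 1)
  sizes <- matrix(0L, 5, 2)
  sizes[1, ] <- c(sH, sW)          # stage-0 output = stage-1 input/output
  sizes[2, ] <- sizes[1, ]
  for (k in 3:5)
    sizes[k, ] <- c(conv_output_size(sizes[k - 1, 1], 3, 2, 1),
                    conv_output_size(sizes[k - 1, 2], 3, 2, 1))
  cfg$stage_sizes <- sizes          # rows: stage 0..4 outputs
  if (H %% patch_size != 0 || W %% patch_size != 0)
    stop("cit_config: patch_size must tile the map exactly")
  cfg$n_tokens0 <- bands * (H %/% patch_size) * (W %/% patch_size)
  structure(cfg, class = "cit_config")
}

#' @export
print.cit_config <- function(x, ...) {
  cat(sprintf(paste0("<cit_config> %s: %dx%dx%d maps, %d classes\n",
                     "  CNN %s (x%d blocks/stage), Transformer D=%d h=%d (x%d blocks/stage)\n",
                     "  CIT stages {%s} fusion=%s, stem pad mode=%s\n",
                     "  Adam lr=%g, batch=%d, dropout=%g, split=%.0f:%.0f\n"),
              x$variant, x$H, x$W, x$bands, x$num_classes,
              paste(x$channels, collapse = "-"), x$blocks_per_stage,
              x$embed_dim, x$heads, x$encoders_per_stage,
              paste(x$cit_stages, collapse = ","), x$fusion,
              x$stem_padding_mode, x$learning_rate, x$batch_size, x$dropout,
              100 * x$split_ratio, 100 * (1 - x$split_ratio)))
  invisible(x)
}

init_normal <- function(n, sd) stats::rnorm(n, 0, sd)
init_conv <- function(outC, fan) matrix(init_normal(outC * fan, sqrt(2 / fan)), outC, fan)
init_lin <- function(din, dout) matrix(init_normal(din * dout, sqrt(2 / (din + dout))), din, dout)

#' Initialize an untrained CIT network
#'
#' Creates all parameters (He initialization for convolutions, Glorot for
#' linear maps, unit/zero batch- and layer-norm) deterministically from
#' `seed`. Parameters for every stage, branch and fusion block are always
#' created in a fixed order regardless of `variant` or `cit_stages`, so
#' differently ablated models share identical initial weights under the
#' same seed.
#'
#' @param config A [cit_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return An object of class `cit_model` (untrained).
#' @export
cit_init <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cit_config"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  p <- list(); aux <- list(); meta <- list()
  ch <- config$channels; D <- config$embed_dim
  pad <- if (config$stem_padding_mode == "paper") 4L else 3L

  # stem
  p[["stem.W"]] <- init_conv(ch[1], config$bands * 49)
  p[["stem.bn.gamma"]] <- rep(1, ch[1]); p[["stem.bn.beta"]] <- rep(0, ch[1])
  aux[["stem.bn.mean"]] <- rep(0, ch[1]); aux[["stem.bn.var"]] <- rep(1, ch[1])
  meta$stem_conv <- conv_meta(config$bands, config$H, config$W, 7L, 2L, pad)
  cs <- c(meta$stem_conv$outH, meta$stem_conv$outW)
  meta$stem_pool <- pool_meta(ch[1], cs[1], cs[2], 3L, 2L, 1L)

  # CNN stages
  meta$cnn <- vector("list", 4)
  for (k in 1:4) {
    inC <- ch[k]; outC <- ch[k + 1]
    stride <- if (k == 1) 1L else 2L
    insz <- config$stage_sizes[k, ]
    meta$cnn[[k]] <- vector("list", config$blocks_per_stage)
    for (j in seq_len(config$blocks_per_stage)) {
      s <- if (j == 1L) stride else 1L
      ic <- if (j == 1L) inC else outC
      pfx <- sprintf("cnn.s%d.b%d", k, j)
      p[[paste0(pfx, ".conv1.W")]] <- init_conv(outC, ic * 9)
      p[[paste0(pfx, ".bn1.gamma")]] <- rep(1, outC)
      p[[paste0(pfx, ".bn1.beta")]] <- rep(0, outC)
      aux[[paste0(pfx, ".bn1.mean")]] <- rep(0, outC)
      aux[[paste0(pfx, ".bn1.var")]] <- rep(1, outC)
      p[[paste0(pfx, ".conv2.W")]] <- init_conv(outC, outC * 9)
      p[[paste0(pfx, ".bn2.gamma")]] <- rep(1, outC)
      p[[paste0(pfx, ".bn2.beta")]] <- rep(0, outC)
      aux[[paste0(pfx, ".bn2.mean")]] <- rep(0, outC)
      aux[[paste0(pfx, ".bn2.var")]] <- rep(1, outC)
      m <- list(conv1 = conv_meta(ic, insz[1], insz[2], 3L, s, 1L))
      osz <- c(m$conv1$outH, m$conv1$outW)
      m$conv2 <- conv_meta(outC, osz[1], osz[2], 3L, 1L, 1L)
      if (config$paper_exact_shortcut) {
        p[[paste0(pfx, ".sc3.W")]] <- init_conv(outC, ic * 9)
        p[[paste0(pfx, ".sc1.W")]] <- init_conv(outC, outC)
        p[[paste0(pfx, ".scbn.gamma")]] <- rep(1, outC)
        p[[paste0(pfx, ".scbn.beta")]] <- rep(0, outC)
        aux[[paste0(pfx, ".scbn.mean")]] <- rep(0, outC)
        aux[[paste0(pfx, ".scbn.var")]] <- rep(1, outC)
        m$sc3 <- conv_meta(ic, insz[1], insz[2], 3L, s, 1L)
        m$sc1 <- conv_meta(outC, osz[1], osz[2], 1L, 1L, 0L)
      } else if (s != 1L || ic != outC) {
        p[[paste0(pfx, ".proj.W")]] <- init_conv(outC, ic)
        p[[paste0(pfx, ".projbn.gamma")]] <- rep(1, outC)
        p[[paste0(pfx, ".projbn.beta")]] <- rep(0, outC)
        aux[[paste0(pfx, ".projbn.mean")]] <- rep(0, outC)
        aux[[paste0(pfx, ".projbn.var")]] <- rep(1, outC)
        m$proj <- conv_meta(ic, insz[1], insz[2], 1L, s, 0L)
      }
      m$in_sz <- insz; m$out_sz <- osz; m$inC <- ic; m$outC <- outC
      meta$cnn[[k]][[j]] <- m
      insz <- osz
    }
  }

  # patch embedding
  ps <- config$patch_size
  p[["pe.W"]] <- init_lin(ps * ps, D)
  p[["pe.b"]] <- rep(0, D)
  p[["pe.pos"]] <- matrix(init_normal(config$n_tokens0 * D, 0.02),
                          config$n_tokens0, D)
  meta$pe <- patch_meta(config$bands, config$H, config$W, ps)

  # transformer stages
  Dm <- config$mlp_ratio * D
  for (k in 1:4) for (j in seq_len(config$encoders_per_stage)) {
    pfx <- sprintf("tr.s%d.e%d", k, j)
    p[[paste0(pfx, ".ln1.gamma")]] <- rep(1, D)
    p[[paste0(pfx, ".ln1.beta")]] <- rep(0, D)
    p[[paste0(pfx, ".attn.Wq")]] <- init_lin(D, D)
    p[[paste0(pfx, ".attn.Wk")]] <- init_lin(D, D)
    p[[paste0(pfx, ".attn.Wv")]] <- init_lin(D, D)
    p[[paste0(pfx, ".attn.Wo")]] <- init_lin(D, D)
    p[[paste0(pfx, ".ln2.gamma")]] <- rep(1, D)
    p[[paste0(pfx, ".ln2.beta")]] <- rep(0, D)
    p[[paste0(pfx, ".mlp.W1")]] <- init_lin(D, Dm)
    p[[paste0(pfx, ".mlp.b1")]] <- rep(0, Dm)
    p[[paste0(pfx, ".mlp.W2")]] <- init_lin(Dm, D)
    p[[paste0(pfx, ".mlp.b2")]] <- rep(0, D)
  }

  # CIT fusion blocks (always created; used per cit_stages/variant)
  for (k in 1:3) {
    C <- ch[k + 1]
    pfx <- sprintf("cit.s%d", k)
    p[[paste0(pfx, ".l2g.W")]] <- init_lin(C, D)
    p[[paste0(pfx, ".l2g.b")]] <- rep(0, D)
    p[[paste0(pfx, ".g2l.W")]] <- init_conv(C, D + C)
    p[[paste0(pfx, ".g2l.b")]] <- rep(0, C)
    p[[paste0(pfx, ".ln.gamma")]] <- rep(1, D)
    p[[paste0(pfx, ".ln.beta")]] <- rep(0, D)
  }

  # classification head
  feat_dim <- switch(config$variant,
                     cnn_only = ch[5],
                     transformer_only = D,
                     ch[5] + D)
  p[["head.W"]] <- init_lin(feat_dim, config$num_classes)
  p[["head.b"]] <- rep(0, config$num_classes)

  structure(list(config = config, params = p,
                 aux = list2env(aux, parent = emptyenv()), meta = meta,
                 history = NULL, trained = FALSE, seed = as.integer(seed)),
            class = "cit_model")
}

patch_meta <- function(B, H, W, ps) {
  nTh <- H %/% ps; nTw <- W %/% ps
  gidx <- list(); t <- 0L
  for (j in seq_len(nTw)) for (i in seq_len(nTh)) for (c in seq_len(B)) {
    g <- expand.grid(h = ((i - 1L) * ps + 1L):(i * ps),
                     w = ((j - 1L) * ps + 1L):(j * ps))
    t <- t + 1L
    gidx[[t]] <- c + B * (g$h - 1L) + B * H * (g$w - 1L)
  }
  list(gidx = gidx, n_tokens = t, ps2 = ps * ps)
}
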