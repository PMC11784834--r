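# Forward and backward passes of the assembled network.
#
# The forward pass records per-op caches; cit_bwd_full() walks them in
# reverse and returns a named gradient list parallel to model$params.

#' Stack spatial-spectral maps into an internal batch matrix
#'
#' @param maps List of `H x W x B` maps, or a single map, or an
#'   `H x W x B x N` array.
#' @return Matrix `(B*H*W) x N`, channel-fastest (the layout all network
#'   internals use).
#' @export
as_map_batch <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3L) maps <- list(maps)
  if (is.array(maps) && length(dim(maps)) == 4L)
    maps <- lapply(seq_len(dim(maps)[4]), function(i) maps[, , , i])
  vapply(maps, function(m) as.vector(aperm(m, c(3L, 1L, 2L))),
         numeric(length(maps[[1L]])))
}

stem_fwd <- function(model, X, training) {
  p <- model$params; meta <- model$meta
  cv <- conv2d_fwd(X, p[["stem.W"]], NULL, meta$stem_conv)
  bn <- bn2d_fwd(cv$y, p[["stem.bn.gamma"]], p[["stem.bn.beta"]],
                 model$config$channels[1], "stem.bn", model$aux, training)
  r <- relu_fwd(bn$y)
  pl <- maxpool_fwd(r, meta$stem_pool)
  list(y = pl$y, cache = list(conv = cv$cache, bn = bn$cache, r = r,
                              pool = pl$cache))
}

stem_bwd <- function(model, cache, dY, g) {
  meta <- model$meta
  dr <- maxpool_bwd(dY, cache$pool, meta$stem_pool)
  dbn <- relu_bwd(dr, cache$r)
  bb <- bn2d_bwd(dbn, cache$bn)
  g[["stem.bn.gamma"]] <- g0(g[["stem.bn.gamma"]]) + bb$dgamma
  g[["stem.bn.beta"]] <- g0(g[["stem.bn.beta"]]) + bb$dbeta
  cb <- conv2d_bwd(bb$dx, cache$conv, model$params[["stem.W"]], meta$stem_conv)
  g[["stem.W"]] <- g0(g[["stem.W"]]) + cb$dW
  list(dx = cb$dx, g = g)
}

g0 <- function(x) if (is.null(x)) 0 else x

block_fwd <- function(model, k, j, X, training) {
  p <- model$params; m <- model$meta$cnn[[k]][[j]]
  pfx <- sprintf("cnn.s%d.b%d", k, j)
  a1 <- conv2d_fwd(X, p[[paste0(pfx, ".conv1.W")]], NULL, m$conv1)
  b1 <- bn2d_fwd(a1$y, p[[paste0(pfx, ".bn1.gamma")]], p[[paste0(pfx, ".bn1.beta")]],
                 m$outC, paste0(pfx, ".bn1"), model$aux, training)
  r1 <- relu_fwd(b1$y)
  a2 <- conv2d_fwd(r1, p[[paste0(pfx, ".conv2.W")]], NULL, m$conv2)
  b2 <- bn2d_fwd(a2$y, p[[paste0(pfx, ".bn2.gamma")]], p[[paste0(pfx, ".bn2.beta")]],
                 m$outC, paste0(pfx, ".bn2"), model$aux, training)
  cache <- list(conv1 = a1$cache, bn1 = b1$cache, r1 = r1,
                conv2 = a2$cache, bn2 = b2$cache, kind = "identity")
  if (model$config$paper_exact_shortcut) {
    s3 <- conv2d_fwd(X, p[[paste0(pfx, ".sc3.W")]], NULL, m$sc3)
    s1 <- conv2d_fwd(s3$y, p[[paste0(pfx, ".sc1.W")]], NULL, m$sc1)
    sb <- bn2d_fwd(s1$y, p[[paste0(pfx, ".scbn.gamma")]], p[[paste0(pfx, ".scbn.beta")]],
                   m$outC, paste0(pfx, ".scbn"), model$aux, training)
    sc <- sb$y
    cache[c("sc3", "sc1", "scbn")] <- list(s3$cache, s1$cache, sb$cache)
    cache$kind <- "paper"
  } else if (!is.null(m$proj)) {
    pj <- conv2d_fwd(X, p[[paste0(pfx, ".proj.W")]], NULL, m$proj)
    pb <- bn2d_fwd(pj$y, p[[paste0(pfx, ".projbn.gamma")]], p[[paste0(pfx, ".projbn.beta")]],
                   m$outC, paste0(pfx, ".projbn"), model$aux, training)
    sc <- pb$y
    cache[c("proj", "projbn")] <- list(pj$cache, pb$cache)
    cache$kind <- "proj"
  } else {
    sc <- X
  }
  if (!identical(dim(b2$y), dim(sc)))
    stop("basic block: main/shortcut shape mismatch (internal contract error)")
  out <- relu_fwd(b2$y + sc)
  cache$out <- out
  list(y = out, cache = cache)
}

block_bwd <- function(model, k, j, cache, dY, g) {
  p <- model$params; m <- model$meta$cnn[[k]][[j]]
  pfx <- sprintf("cnn.s%d.b%d", k, j)
  dsum <- relu_bwd(dY, cache$out)
  # main path
  bb2 <- bn2d_bwd(dsum, cache$bn2)
  g[[paste0(pfx, ".bn2.gamma")]] <- g0(g[[paste0(pfx, ".bn2.gamma")]]) + bb2$dgamma
  g[[paste0(pfx, ".bn2.beta")]] <- g0(g[[paste0(pfx, ".bn2.beta")]]) + bb2$dbeta
  cb2 <- conv2d_bwd(bb2$dx, cache$conv2, p[[paste0(pfx, ".conv2.W")]], m$conv2)
  g[[paste0(pfx, ".conv2.W")]] <- g0(g[[paste0(pfx, ".conv2.W")]]) + cb2$dW
  dr1 <- relu_bwd(cb2$dx, cache$r1)
  bb1 <- bn2d_bwd(dr1, cache$bn1)
  g[[paste0(pfx, ".bn1.gamma")]] <- g0(g[[paste0(pfx, ".bn1.gamma")]]) + bb1$dgamma
  g[[paste0(pfx, ".bn1.beta")]] <- g0(g[[paste0(pfx, ".bn1.beta")]]) + bb1$dbeta
  cb1 <- conv2d_bwd(bb1$dx, cache$conv1, p[[paste0(pfx, ".conv1.W")]], m$conv1)
  g[[paste0(pfx, ".conv1.W")]] <- g0(g[[paste0(pfx, ".conv1.W")]]) + cb1$dW
  dX <- cb1$dx
  # shortcut path
  if (cache$kind == "paper") {
    sb <- bn2d_bwd(dsum, cache$scbn)
    g[[paste0(pfx, ".scbn.gamma")]] <- g0(g[[paste0(pfx, ".scbn.gamma")]]) + sb$dgamma
    g[[paste0(pfx, ".scbn.beta")]] <- g0(g[[paste0(pfx, ".scbn.beta")]]) + sb$dbeta
    c1 <- conv2d_bwd(sb$dx, cache$sc1, p[[paste0(pfx, ".sc1.W")]], m$sc1)
    g[[paste0(pfx, ".sc1.W")]] <- g0(g[[paste0(pfx, ".sc1.W")]]) + c1$dW
    c3 <- conv2d_bwd(c1$dx, cache$sc3, p[[paste0(pfx, ".sc3.W")]], m$sc3)
    g[[paste0(pfx, ".sc3.W")]] <- g0(g[[paste0(pfx, ".sc3.W")]]) + c3$dW
    dX <- dX + c3$dx
  } else if (cache$kind == "proj") {
    pb <- bn2d_bwd(dsum, cache$projbn)
    g[[paste0(pfx, ".projbn.gamma")]] <- g0(g[[paste0(pfx, ".projbn.gamma")]]) + pb$dgamma
    g[[paste0(pfx, ".projbn.beta")]] <- g0(g[[paste0(pfx, ".projbn.beta")]]) + pb$dbeta
    cp <- conv2d_bwd(pb$dx, cache$proj, p[[paste0(pfx, ".proj.W")]], m$proj)
    g[[paste0(pfx, ".proj.W")]] <- g0(g[[paste0(pfx, ".proj.W")]]) + cp$dW
    dX <- dX + cp$dx
  } else {
    dX <- dX + dsum
  }
  list(dx = dX, g = g)
}

patch_embed_fwd <- function(model, X) {
  p <- model$params; pm <- model$meta$pe
  N <- ncol(X); D <- model$config$embed_dim
  G <- array(0, c(N, pm$n_tokens, D))
  for (t in seq_len(pm$n_tokens)) {
    tok <- crossprod(X[pm$gidx[[t]], , drop = FALSE], p[["pe.W"]])
    G[, t, ] <- tok + rep(p[["pe.b"]], each = N) +
      rep(p[["pe.pos"]][t, ], each = N)
  }
  list(y = G, cache = list(X = X))
}

patch_embed_bwd <- function(model, cache, dG, g) {
  p <- model$params; pm <- model$meta$pe
  N <- dim(dG)[1]
  dW <- 0; db <- 0
  dpos <- matrix(0, pm$n_tokens, ncol(p[["pe.pos"]]))
  for (t in seq_len(pm$n_tokens)) {
    dTok <- matrix(dG[, t, ], N)
    dW <- dW + cache$X[pm$gidx[[t]], , drop = FALSE] %*% dTok
    cs <- colSums(dTok)
    db <- db + cs
    dpos[t, ] <- cs
  }
  g[["pe.W"]] <- g0(g[["pe.W"]]) + dW
  g[["pe.b"]] <- g0(g[["pe.b"]]) + db
  g[["pe.pos"]] <- g0(g[["pe.pos"]]) + dpos
  g
}

encoder_fwd <- function(model, k, j, A, training) {
  p <- model$params; cfg <- model$config
  pfx <- sprintf("tr.s%d.e%d", k, j)
  dm <- dim(A); N <- dm[1]; Tn <- dm[2]; D <- dm[3]
  X2 <- matrix(A, N * Tn, D)
  ln1 <- layernorm_fwd(X2, p[[paste0(pfx, ".ln1.gamma")]], p[[paste0(pfx, ".ln1.beta")]])
  at <- mha_fwd(array(ln1$y, dm), p[[paste0(pfx, ".attn.Wq")]],
                p[[paste0(pfx, ".attn.Wk")]], p[[paste0(pfx, ".attn.Wv")]],
                p[[paste0(pfx, ".attn.Wo")]], cfg$heads)
  xa <- X2 + matrix(at$y, N * Tn, D)
  ln2 <- layernorm_fwd(xa, p[[paste0(pfx, ".ln2.gamma")]], p[[paste0(pfx, ".ln2.beta")]])
  h1 <- ln2$y %*% p[[paste0(pfx, ".mlp.W1")]] +
    rep(p[[paste0(pfx, ".mlp.b1")]], each = N * Tn)
  gl <- gelu_fwd(h1)
  d1 <- dropout_fwd(gl, cfg$dropout, training)
  h2 <- d1$y %*% p[[paste0(pfx, ".mlp.W2")]] +
    rep(p[[paste0(pfx, ".mlp.b2")]], each = N * Tn)
  d2 <- dropout_fwd(h2, cfg$dropout, training)
  y <- array(xa + d2$y, dm)
  list(y = y, cache = list(ln1 = ln1$cache, at = at$cache, ln2 = ln2$cache,
                           h1 = h1, d1y = d1$y, ln2y = ln2$y,
                           m1 = d1$mask, m2 = d2$mask, dm = dm))
}

encoder_bwd <- function(model, k, j, cache, dYarr, g) {
  p <- model$params
  pfx <- sprintf("tr.s%d.e%d", k, j)
  dm <- cache$dm; N <- dm[1]; Tn <- dm[2]; D <- dm[3]
  dy <- matrix(dYarr, N * Tn, D)
  # MLP sub-block
  dh2 <- dropout_bwd(dy, cache$m2)
  g[[paste0(pfx, ".mlp.W2")]] <- g0(g[[paste0(pfx, ".mlp.W2")]]) +
    crossprod(cache$d1y, dh2)
  g[[paste0(pfx, ".mlp.b2")]] <- g0(g[[paste0(pfx, ".mlp.b2")]]) + colSums(dh2)
  dd1 <- tcrossprod(dh2, p[[paste0(pfx, ".mlp.W2")]])
  dgl <- dropout_bwd(dd1, cache$m1)
  dh1 <- gelu_bwd(dgl, cache$h1)
  g[[paste0(pfx, ".mlp.W1")]] <- g0(g[[paste0(pfx, ".mlp.W1")]]) +
    crossprod(cache$ln2y, dh1)
  g[[paste0(pfx, ".mlp.b1")]] <- g0(g[[paste0(pfx, ".mlp.b1")]]) + colSums(dh1)
  dln2y <- tcrossprod(dh1, p[[paste0(pfx, ".mlp.W1")]])
  lb2 <- layernorm_bwd(dln2y, cache$ln2)
  g[[paste0(pfx, ".ln2.gamma")]] <- g0(g[[paste0(pfx, ".ln2.gamma")]]) + lb2$dgamma
  g[[paste0(pfx, ".ln2.beta")]] <- g0(g[[paste0(pfx, ".ln2.beta")]]) + lb2$dbeta
  dxa <- dy + lb2$dx
  # attention sub-block
  ab <- mha_bwd(array(dxa, dm), cache$at, p[[paste0(pfx, ".attn.Wq")]],
                p[[paste0(pfx, ".attn.Wk")]], p[[paste0(pfx, ".attn.Wv")]],
                p[[paste0(pfx, ".attn.Wo")]])
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    key <- paste0(pfx, ".attn.", nm)
    g[[key]] <- g0(g[[key]]) + ab[[paste0("d", nm)]]
  }
  lb1 <- layernorm_bwd(matrix(ab$dx, N * Tn, D), cache$ln1)
  g[[paste0(pfx, ".ln1.gamma")]] <- g0(g[[paste0(pfx, ".ln1.gamma")]]) + lb1$dgamma
  g[[paste0(pfx, ".ln1.beta")]] <- g0(g[[paste0(pfx, ".ln1.beta")]]) + lb1$dbeta
  list(dx = array(dxa + lb1$dx, dm), g = g)
}

l2g_fwd <- function(model, k, local, global, training) {
  p <- model$params; cfg <- model$config
  pfx <- sprintf("cit.s%d", k)
  C <- cfg$channels[k + 1]
  hw <- nrow(local) %/% C
  N <- ncol(local); D <- cfg$embed_dim
  chan <- rep(seq_len(C), times = hw)
  Fmean <- rowsum(local, chan) / hw                     # C x N
  Flin <- crossprod(Fmean, p[[paste0(pfx, ".l2g.W")]]) +
    rep(p[[paste0(pfx, ".l2g.b")]], each = N)           # N x D
  lncache <- NULL
  if (cfg$fusion_norm) {
    ln <- layernorm_fwd(Flin, p[[paste0(pfx, ".ln.gamma")]],
                        p[[paste0(pfx, ".ln.beta")]])
    Flin_out <- ln$y; lncache <- ln$cache
  } else Flin_out <- Flin
  Tn <- dim(global)[2]
  if (cfg$fusion == "add") {
    y <- global
    for (t in seq_len(Tn)) y[, t, ] <- y[, t, ] + Flin_out
  } else if (cfg$tfm) {
    y <- array(0, c(N, Tn + 1L, D))
    y[, 1, ] <- Flin_out
    y[, -1, ] <- global
  } else {
    y <- array(Flin_out, c(N, 1L, D))
  }
  list(y = y, cache = list(Fmean = Fmean, chan = chan, hw = hw, C = C,
                           ln = lncache, Tn = Tn))
}

l2g_bwd <- function(model, k, cache, dY, g) {
  p <- model$params; cfg <- model$config
  pfx <- sprintf("cit.s%d", k)
  N <- dim(dY)[1]; D <- dim(dY)[3]
  if (cfg$fusion == "add") {
    dFlin <- matrix(0, N, D)
    for (t in seq_len(dim(dY)[2])) dFlin <- dFlin + matrix(dY[, t, ], N)
    dglobal <- dY
  } else if (cfg$tfm) {
    dFlin <- matrix(dY[, 1, ], N)
    dglobal <- dY[, -1, , drop = FALSE]
  } else {
    dFlin <- matrix(dY[, 1, ], N)
    dglobal <- array(0, c(N, cache$Tn, D))
  }
  if (cfg$fusion_norm) {
    lb <- layernorm_bwd(dFlin, cache$ln)
    g[[paste0(pfx, ".ln.gamma")]] <- g0(g[[paste0(pfx, ".ln.gamma")]]) + lb$dgamma
    g[[paste0(pfx, ".ln.beta")]] <- g0(g[[paste0(pfx, ".ln.beta")]]) + lb$dbeta
    dFlin <- lb$dx
  }
  g[[paste0(pfx, ".l2g.W")]] <- g0(g[[paste0(pfx, ".l2g.W")]]) +
    cache$Fmean %*% dFlin
  g[[paste0(pfx, ".l2g.b")]] <- g0(g[[paste0(pfx, ".l2g.b")]]) + colSums(dFlin)
  dFmean <- p[[paste0(pfx, ".l2g.W")]] %*% t(dFlin)      # C x N
  dlocal <- dFmean[cache$chan, , drop = FALSE] / cache$hw
  list(dlocal = dlocal, dglobal = dglobal, g = g)
}

g2l_fwd <- function(model, k, global, local, training) {
  p <- model$params; cfg <- model$config
  pfx <- sprintf("cit.s%d", k)
  C <- cfg$channels[k + 1]
  hw <- nrow(local) %/% C
  N <- ncol(local); D <- cfg$embed_dim
  tok0 <- matrix(global[, 1, ], N)                       # N x D
  top <- t(tok0)[, rep(seq_len(N), each = hw), drop = FALSE]  # D x (hw*N)
  Wc <- p[[paste0(pfx, ".g2l.W")]]
  if (cfg$cfm) {
    M <- rbind(top, matrix(local, C, hw * N))
  } else {
    M <- top
    Wc <- Wc[, seq_len(D), drop = FALSE]
  }
  Y <- Wc %*% M + p[[paste0(pfx, ".g2l.b")]]
  list(y = matrix(Y, C * hw, N),
       cache = list(M = M, C = C, hw = hw, N = N, D = D, Tn = dim(global)[2]))
}

g2l_bwd <- function(model, k, cache, dY, g) {
  p <- model$params; cfg <- model$config
  pfx <- sprintf("cit.s%d", k)
  C <- cache$C; hw <- cache$hw; N <- cache$N; D <- cache$D
  dYm <- matrix(dY, C, hw * N)
  Wc_full <- p[[paste0(pfx, ".g2l.W")]]
  if (cfg$cfm) {
    dWc <- tcrossprod(dYm, cache$M)
    dM <- crossprod(Wc_full, dYm)
    dlocal <- matrix(dM[D + seq_len(C), , drop = FALSE], C * hw, N)
  } else {
    dWc_part <- tcrossprod(dYm, cache$M)
    dWc <- matrix(0, C, D + C)
    dWc[, seq_len(D)] <- dWc_part
    dM <- crossprod(Wc_full[, seq_len(D), drop = FALSE], dYm)
    dlocal <- matrix(0, C * hw, N)
  }
  g[[paste0(pfx, ".g2l.W")]] <- g0(g[[paste0(pfx, ".g2l.W")]]) + dWc
  g[[paste0(pfx, ".g2l.b")]] <- g0(g[[paste0(pfx, ".g2l.b")]]) + rowSums(dYm)
  dtop <- dM[seq_len(D), , drop = FALSE]                 # D x (hw*N)
  dtok0 <- t(colSums(aperm(array(dtop, c(D, hw, N)), c(2, 1, 3))))  # N x D
  dglobal <- array(0, c(N, cache$Tn, D))
  dglobal[, 1, ] <- dtok0
  list(dlocal = dlocal, dglobal = dglobal, g = g)
}

head_fwd <- function(model, local, global, training) {
  p <- model$params; cfg <- model$config
  use_cnn <- cfg$variant != "transformer_only"
  use_tr <- cfg$variant != "cnn_only"
  feats <- NULL; C4 <- cfg$channels[5]
  if (use_cnn) {
    hw <- nrow(local) %/% C4
    gap <- rowsum(local, rep(seq_len(C4), times = hw)) / hw   # C4 x N
    feats <- t(gap)
  }
  if (use_tr) {
    N <- dim(global)[1]; Tn <- dim(global)[2]
    tm <- matrix(0, N, dim(global)[3])
    for (t in seq_len(Tn)) tm <- tm + matrix(global[, t, ], N)
    tm <- tm / Tn
    feats <- if (is.null(feats)) tm else cbind(feats, tm)
  }
  dr <- dropout_fwd(feats, cfg$dropout, training)
  logits <- dr$y %*% p[["head.W"]] + rep(p[["head.b"]], each = nrow(feats))
  if (anyNA(logits) || !all(is.finite(logits)))
    stop("forward: non-finite logits (numerical failure); inspect learning ",
         "rate and input scaling")
  list(y = logits, cache = list(feats_dropped = dr$y, mask = dr$mask,
                                local_hw = if (use_cnn) nrow(local) %/% C4 else NULL,
                                gdim = if (use_tr) dim(global) else NULL))
}

head_bwd <- function(model, cache, dlogits, g) {
  p <- model$params; cfg <- model$config
  use_cnn <- cfg$variant != "transformer_only"
  use_tr <- cfg$variant != "cnn_only"
  C4 <- cfg$channels[5]
  g[["head.W"]] <- g0(g[["head.W"]]) + crossprod(cache$feats_dropped, dlogits)
  g[["head.b"]] <- g0(g[["head.b"]]) + colSums(dlogits)
  dfeats <- dropout_bwd(tcrossprod(dlogits, p[["head.W"]]), cache$mask)
  dlocal <- NULL; dglobal <- NULL
  off <- 0L
  if (use_cnn) {
    dgap <- t(dfeats[, seq_len(C4), drop = FALSE])       # C4 x N
    hw <- cache$local_hw
    dlocal <- dgap[rep(seq_len(C4), times = hw), , drop = FALSE] / hw
    off <- C4
  }
  if (use_tr) {
    gd <- cache$gdim
    dtm <- dfeats[, off + seq_len(gd[3]), drop = FALSE] / gd[2]
    dglobal <- array(0, gd)
    for (t in seq_len(gd[2])) dglobal[, t, ] <- dtm
  }
  list(dlocal = dlocal, dglobal = dglobal, g = g)
}

# Full forward. `count`, if an environment, accumulates structural counters
# (cnn_blocks / encoder_blocks per stage, cit applications).
cit_fwd_full <- function(model, X, training = FALSE, count = NULL) {
  cfg <- model$config
  use_cnn <- cfg$variant != "transformer_only"
  use_tr <- cfg$variant != "cnn_only"
  cache <- list()
  local <- NULL; global <- NULL
  if (use_cnn) {
    st <- stem_fwd(model, X, training)
    cache$stem <- st$cache
    local <- st$y
  }
  if (use_tr) {
    pe <- patch_embed_fwd(model, X)
    cache$pe <- pe$cache
    global <- pe$y
  }
  cache$cnn <- vector("list", 4); cache$tr <- vector("list", 4)
  cache$cit <- vector("list", 3)
  for (k in 1:4) {
    if (use_cnn) {
      cache$cnn[[k]] <- vector("list", cfg$blocks_per_stage)
      for (j in seq_len(cfg$blocks_per_stage)) {
        bf <- block_fwd(model, k, j, local, training)
        cache$cnn[[k]][[j]] <- bf$cache
        local <- bf$y
        if (is.environment(count)) count$cnn_blocks[k] <- count$cnn_blocks[k] + 1L
      }
    }
    if (use_tr) {
      cache$tr[[k]] <- vector("list", cfg$encoders_per_stage)
      for (j in seq_len(cfg$encoders_per_stage)) {
        ef <- encoder_fwd(model, k, j, global, training)
        cache$tr[[k]][[j]] <- ef$cache
        global <- ef$y
        if (is.environment(count)) count$encoder_blocks[k] <- count$encoder_blocks[k] + 1L
      }
    }
    if (k <= 3 && k %in% cfg$cit_stages && (cfg$l2g || cfg$g2l)) {
      cc <- list()
      newglobal <- global; newlocal <- local
      if (cfg$l2g) {
        lf <- l2g_fwd(model, k, local, global, training)
        cc$l2g <- lf$cache
        newglobal <- lf$y
      }
      if (cfg$g2l) {
        gf <- g2l_fwd(model, k, global, local, training)
        cc$g2l <- gf$cache
        newlocal <- gf$y
      }
      cache$cit[[k]] <- cc
      local <- newlocal; global <- newglobal
      if (is.environment(count)) count$cit <- count$cit + 1L
    }
  }
  hd <- head_fwd(model, local, global, training)
  cache$head <- hd$cache
  list(logits = hd$y, cache = cache)
}

cit_bwd_full <- function(model, cache, dlogits) {
  cfg <- model$config
  use_cnn <- cfg$variant != "transformer_only"
  use_tr <- cfg$variant != "cnn_only"
  g <- list()
  hb <- head_bwd(model, cache$head, dlogits, g)
  g <- hb$g; dlocal <- hb$dlocal; dglobal <- hb$dglobal
  for (k in 4:1) {
    if (use_tr) for (j in rev(seq_len(cfg$encoders_per_stage))) {
      eb <- encoder_bwd(model, k, j, cache$tr[[k]][[j]], dglobal, g)
      g <- eb$g; dglobal <- eb$dx
    }
    if (use_cnn) for (j in rev(seq_len(cfg$blocks_per_stage))) {
      bb <- block_bwd(model, k, j, cache$cnn[[k]][[j]], dlocal, g)
      g <- bb$g; dlocal <- bb$dx
    }
    kc <- k - 1L
    if (kc >= 1 && kc %in% cfg$cit_stages && (cfg$l2g || cfg$g2l)) {
      cc <- cache$cit[[kc]]
      dlocal_k <- 0; dglobal_k <- 0
      if (cfg$g2l) {
        gb <- g2l_bwd(model, kc, cc$g2l, dlocal, g)
        g <- gb$g
        dlocal_k <- dlocal_k + gb$dlocal
        dglobal_k <- dglobal_k + gb$dglobal
      } else dlocal_k <- dlocal_k + dlocal
      if (cfg$l2g) {
        lb <- l2g_bwd(model, kc, cc$l2g, dglobal, g)
        g <- lb$g
        dlocal_k <- dlocal_k + lb$dlocal
        dglobal_k <- dglobal_k + lb$dglobal
      } else dglobal_k <- dglobal_k + dglobal
      dlocal <- dlocal_k; dglobal <- dglobal_k
    }
  }
  if (use_cnn) {
    sb <- stem_bwd(model, cache$stem, dlocal, g)
    g <- sb$g
  }
  if (use_tr) g <- patch_embed_bwd(model, cache$pe, dglobal, g)
  g
}
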