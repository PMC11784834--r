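# Transformer branch: patch embedding, attention, LayerNorm, MLP, encoders.

test_that("patch embedding produces one token per band patch", {
  x <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  tok <- patch_embed(x, patch_size = 32, embed_dim = 24, seed = 1)
  expect_equal(dim(tok), c(1, 5, 24))
  tok16 <- patch_embed(array(rnorm(16 * 16 * 5), c(16, 16, 5)),
                       patch_size = 16, embed_dim = 24, seed = 1)
  expect_equal(dim(tok16), c(1, 5, 24))
  # zero input, zero bias and positional embedding -> all-zero tokens
  p <- list(W = matrix(rnorm(32 * 32 * 8), 1024, 8), b = rep(0, 8),
            pos = matrix(0, 5, 8))
  z <- patch_embed(array(0, c(32, 32, 5)), 32, params = p)
  expect_true(all(z == 0))
  expect_error(patch_embed(x, patch_size = 5), "divide")
})

test_that("scaled dot-product attention is a row-stochastic convex mixer", {
  set.seed(3)
  Q <- matrix(rnorm(12), 4, 3); K <- matrix(rnorm(15), 5, 3)
  V <- matrix(rnorm(10), 5, 2)
  out <- scaled_dot_attention(Q, K, V)
  W <- attr(out, "weights")
  expect_equal(rowSums(W), rep(1, 4), tolerance = 1e-12)
  expect_true(all(W >= 0))
  # identical keys -> uniform weights -> every row is the mean of V
  Kc <- matrix(1, 5, 3)
  outc <- scaled_dot_attention(Q, Kc, V)
  expect_equal(unclass(outc), matrix(colMeans(V), 4, 2, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # single token: output = V
  out1 <- scaled_dot_attention(matrix(rnorm(3), 1), matrix(rnorm(3), 1),
                               matrix(c(2, 7), 1))
  expect_equal(unclass(out1), matrix(c(2, 7), 1), ignore_attr = TRUE)
  # dominant key: hand-computed softmax oracle
  Qd <- matrix(c(10, 0), 1); Kd <- rbind(c(10, 0), c(-10, 0))
  Vd <- rbind(c(1, 1), c(-1, -1))
  s <- c(100, -100) / sqrt(2)
  w <- exp(s - max(s)); w <- w / sum(w)
  expect_equal(as.numeric(scaled_dot_attention(Qd, Kd, Vd)),
               as.numeric(w %*% Vd), tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(scaled_dot_attention(Qd, Kd, Vd)) - c(1, 1))), 1e-6)
  expect_error(scaled_dot_attention(Q[, 0], K[, 0], V), "d_k")
})

test_that("multi-head attention: h=1 oracle equivalence, permutation equivariance", {
  set.seed(4)
  D <- 8; Tn <- 5
  x <- matrix(rnorm(Tn * D), Tn, D)
  p1 <- list(Wq = matrix(rnorm(D * D), D), Wk = matrix(rnorm(D * D), D),
             Wv = matrix(rnorm(D * D), D), Wo = matrix(rnorm(D * D), D), h = 1)
  got <- multi_head_attention(x, p1)
  oracle <- unclass(scaled_dot_attention(x %*% p1$Wq, x %*% p1$Wk,
                                         x %*% p1$Wv)) %*% p1$Wo
  expect_equal(got, oracle, tolerance = 1e-6, ignore_attr = TRUE)

  p2 <- p1; p2$h <- 2
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(multi_head_attention(x[perm, ], p2),
               multi_head_attention(x, p2)[perm, ], tolerance = 1e-10)
  p0 <- p2; p0$Wo <- p0$Wo * 0
  expect_true(all(multi_head_attention(x, p0) == 0))
  p3 <- p2; p3$h <- 3
  expect_error(multi_head_attention(x, p3), "divide")
})

test_that("layer normalization standardizes tokens", {
  set.seed(5)
  x <- matrix(rnorm(6 * 10, sd = 4), 6, 10)
  y <- layer_norm(x)
  expect_lt(max(abs(rowMeans(y))), 1e-6)
  expect_true(all(abs(apply(y, 1, function(r) mean(r^2)) - 1) < 1e-3))
  # constant token -> beta
  beta <- rnorm(10)
  expect_equal(layer_norm(matrix(3, 1, 10), beta = beta)[1, ], beta,
               tolerance = 1e-2)
  # scale invariance
  expect_equal(layer_norm(5 * x), layer_norm(x), tolerance = 1e-6)
  # near-standardized token passes through
  expect_equal(as.numeric(layer_norm(matrix(c(1, -1), 1))), c(1, -1),
               tolerance = 1e-3)
})

test_that("MLP block follows Dropout(Dropout(GELU(xW1+b1))W2+b2)", {
  set.seed(6)
  W1 <- matrix(rnorm(4 * 8), 4); b1 <- rnorm(8)
  W2 <- matrix(rnorm(8 * 4), 8); b2 <- rnorm(4)
  x <- matrix(rnorm(12), 3, 4)
  # zero input and biases -> zero (GELU(0) = 0)
  expect_true(all(mlp_block(matrix(0, 3, 4), W1, b1 * 0, W2, b2 * 0) == 0))
  # inference dropout is the identity: equals the plain composition
  h <- x %*% W1 + rep(b1, each = 3)
  ref <- (h * pnorm(h)) %*% W2 + rep(b2, each = 3)
  expect_equal(mlp_block(x, W1, b1, W2, b2), ref, tolerance = 1e-12)
  expect_equal(mlp_block(x, W1, b1, W2, b2, dropout = 0.5, training = FALSE), ref)
  # training at rate 0.99 zeroes ~99% of first-layer activations
  set.seed(7)
  big <- matrix(rnorm(200 * 50), 200, 50)
  Wb <- diag(50); zb <- rep(0, 50)
  out <- mlp_block(big, Wb, zb, Wb, zb, dropout = 0.99, training = TRUE)
  expect_equal(mean(out == 0), 0.99, tolerance = 0.02)
})

test_that("encoder stages preserve shape and reduce to identity with zeroed residuals", {
  cfg <- tiny_config()
  model <- cit_init(cfg, seed = 8)
  tok <- array(rnorm(3 * 5 * cfg$embed_dim), c(3, 5, cfg$embed_dim))
  for (k in 1:4) {
    out <- encoder_stage_forward(model, k, tok)
    expect_equal(dim(out), dim(tok))
  }
  # attention weights are row-stochastic at every encoder layer
  ef <- citnet:::encoder_fwd(model, 1, 1, tok, training = FALSE)
  Wgt <- ef$cache$at$Wgt
  sums <- apply(Wgt, c(1, 2, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # zero residual branches (Wo = 0, W2 = 0, b2 = 0) -> exact identity
  m0 <- model
  for (k in 1:4) for (j in 1:cfg$encoders_per_stage) {
    pfx <- sprintf("tr.s%d.e%d", k, j)
    m0$params[[paste0(pfx, ".attn.Wo")]][] <- 0
    m0$params[[paste0(pfx, ".mlp.W2")]][] <- 0
    m0$params[[paste0(pfx, ".mlp.b2")]][] <- 0
  }
  h <- tok
  for (k in 1:4) h <- encoder_stage_forward(m0, k, h)
  expect_equal(h, tok, tolerance = 1e-12)
})
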