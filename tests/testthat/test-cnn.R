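# CNN branch: shape arithmetic, stem, residual blocks, stage plan.

test_that("conv/pool output-size formulas match the worked values", {
  expect_equal(conv_output_size(32, 7, 2, 4), 17)
  expect_equal(conv_output_size(32, 7, 2, 3), 16)
  for (n in c(1, 5, 32)) expect_equal(conv_output_size(n, 1, 1, 0), n)
  expect_equal(pool_output_size(17, 3, 2, 0), 8)
  expect_equal(pool_output_size(16, 3, 2, 1), 8)
  expect_equal(pool_output_size(3, 3, 2, 0), 1)
  expect_error(conv_output_size(2, 7, 1, 0), "degenerate")
})

test_that("size formulas agree with actually instantiated conv and pool layers", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(6:20, 1); k <- sample(1:5, 1)
    s <- sample(1:3, 1); p <- sample(0:3, 1)
    if (n + 2 * p < k) next
    C <- sample(1:3, 1); oc <- sample(1:4, 1)
    m <- citnet:::conv_meta(C, n, n, k, s, p)
    X <- matrix(rnorm(C * n * n * 2), ncol = 2)
    y <- citnet:::conv2d_fwd(X, matrix(rnorm(oc * C * k^2), oc), NULL, m)$y
    expect_equal(nrow(y), oc * conv_output_size(n, k, s, p)^2)
    pm <- citnet:::pool_meta(C, n, n, k, s, p)
    yp <- citnet:::maxpool_fwd(X, pm)$y
    expect_equal(nrow(yp), C * pool_output_size(n, k, s, p)^2)
  }
})

test_that("stem maps 32x32x5 to 64x8x8 (standard pad) or 64x9x9 (paper pad)", {
  cfg <- tiny_config(H = 32, W = 32, patch_size = 32, channels = c(64, 8, 16, 32, 64))
  model <- cit_init(cfg, seed = 3)
  x <- array(rnorm(32 * 32 * 5 * 2), c(32, 32, 5, 2))
  y <- stem_forward(model, x)
  expect_equal(dim(y), c(64, 8, 8, 2))
  expect_true(all(y >= 0))              # ReLU then max-pool of nonnegatives

  cfgp <- tiny_config(H = 32, W = 32, patch_size = 32,
                      channels = c(64, 8, 16, 32, 64),
                      stem_padding_mode = "paper")
  # oracle: compose the conv and pool formulas for pad-4 stem
  expect_equal(pool_output_size(conv_output_size(32, 7, 2, 4), 3, 2, 1), 9)
  yp <- stem_forward(cit_init(cfgp, seed = 3), x)
  expect_equal(dim(yp), c(64, 9, 9, 2))

  # all-zero input stays zero through conv/BN(inference)/ReLU/pool
  y0 <- stem_forward(model, array(0, c(32, 32, 5, 2)))
  expect_true(all(y0 == 0))
})

test_that("basic blocks: residual identity, shape preservation, stage plan", {
  cfg <- tiny_config()
  model <- cit_init(cfg, seed = 5)
  C1 <- cfg$channels[2]; s1 <- cfg$stage_sizes[2, 1]
  x <- array(rnorm(C1 * s1 * s1 * 3), c(C1, s1, s1, 3))

  # zero main path + identity shortcut (inference BN) => ReLU(x)
  m0 <- model
  m0$params[["cnn.s1.b1.conv1.W"]][] <- 0
  m0$params[["cnn.s1.b1.conv2.W"]][] <- 0
  y <- basic_block_forward(m0, 1, 1, x)
  expect_equal(y, pmax(x, 0), tolerance = 1e-12)

  # zero input, zero-initialized convolutions -> zero output
  y0 <- basic_block_forward(m0, 1, 1, array(0, dim(x)))
  expect_true(all(y0 == 0))

  # stride-1 block preserves shape
  expect_equal(dim(basic_block_forward(model, 1, 2, x)), dim(x))

  # stage plan: stage 1 preserves, stages 2-4 halve space / double channels
  h <- x
  for (k in 1:4) {
    h <- cnn_stage_forward(model, k, h)
    expect_equal(dim(h)[1], cfg$channels[k + 1])
    expect_equal(dim(h)[2], cfg$stage_sizes[k + 1, 1])
  }
  expect_equal(dim(h)[1:3], c(cfg$channels[5], 1, 1))
})

test_that("paper-literal shortcut mode changes every block but keeps declared shapes", {
  cfg <- tiny_config(paper_exact_shortcut = TRUE)
  model <- cit_init(cfg, seed = 5)
  C1 <- cfg$channels[2]; s1 <- cfg$stage_sizes[2, 1]
  x <- array(rnorm(C1 * s1 * s1 * 2), c(C1, s1, s1, 2))
  y <- basic_block_forward(model, 1, 1, x)
  expect_equal(dim(y), dim(x))
  # with a zeroed main path the output is ReLU(shortcut), not ReLU(x)
  m0 <- model
  m0$params[["cnn.s1.b1.conv1.W"]][] <- 0
  m0$params[["cnn.s1.b1.conv2.W"]][] <- 0
  expect_false(isTRUE(all.equal(basic_block_forward(m0, 1, 1, x), pmax(x, 0))))
})

test_that("every CNN-branch parameter receives a gradient after one backward pass", {
  # 64x64 input keeps all stage outputs >= 2x2, so every tap of every 3x3
  # kernel sees data; at 1x1 feature maps the off-centre taps of a 3x3
  # kernel are structurally inactive and their gradients are exactly zero.
  # batch of 32: with a tiny batch, a kernel tap whose few ReLU inputs are
  # all zero would get an exactly-zero gradient by chance.
  cfg <- tiny_config(variant = "cnn_only", H = 64, W = 64, patch_size = 32)
  model <- cit_init(cfg, seed = 2)
  set.seed(17)
  X <- matrix(rnorm(5 * 64 * 64 * 32), ncol = 32)
  fw <- citnet:::cit_fwd_full(model, X, training = TRUE)
  ce <- citnet:::softmax_ce(fw$logits, rep(1:3, length.out = 32))
  g <- citnet:::cit_bwd_full(model, fw$cache, ce$dlogits)
  cnn_names <- grep("^(stem|cnn)\\.", names(model$params), value = TRUE)
  expect_true(all(cnn_names %in% names(g)))          # defined gradients
  vals <- unlist(g[cnn_names])
  expect_gte(mean(vals != 0), 0.99)                  # almost all nonzero
})
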