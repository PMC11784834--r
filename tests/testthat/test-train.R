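# Training and evaluation protocol: splits, metrics, optimisation, ablations.

test_that("stratified 6:4 split is seeded, disjoint and exhaustive", {
  labels <- rep(0:2, c(34, 33, 33))
  sp <- split_dataset(labels, 0.6, seed = 5)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_true(abs(length(sp$train) - 60) <= 2)
  for (cl in 0:2) {
    frac <- sum(labels[sp$train] == cl) / sum(labels == cl)
    expect_true(abs(frac - 0.6) < 0.05)
  }
  expect_identical(split_dataset(labels, 0.6, seed = 5), sp)
  expect_false(identical(split_dataset(labels, 0.6, seed = 6)$train, sp$train))
  expect_error(split_dataset(c(0, 0, 1), 0.6), "stratification")
})

test_that("accuracy and score dispersion follow their defining formulas", {
  expect_equal(accuracy(c(TP = 50, TN = 50, FP = 0, FN = 0)), 1.0)
  expect_equal(accuracy(c(TP = 40, TN = 45, FP = 5, FN = 10)), 0.85)
  cc <- confusion_counts(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(accuracy(cc), 0.75)
  expect_equal(binary_counts(cc, "0"), c(TP = 1, TN = 2, FP = 0, FN = 1))
  expect_error(accuracy(confusion_counts(integer(0), integer(0), classes = 0:1)),
               "empty")
  # metric agreement with the direct mean on random label vectors
  set.seed(20)
  for (i in 1:20) {
    k <- sample(2:5, 1); n <- sample(10:60, 1)
    y <- sample(0:(k - 1), n, replace = TRUE)
    p <- sample(0:(k - 1), n, replace = TRUE)
    expect_equal(accuracy(confusion_counts(y, p, classes = 0:(k - 1))),
                 mean(y == p))
  }
  # uniform random predictions on k classes converge to 1/k
  set.seed(21)
  y <- sample(0:3, 20000, replace = TRUE)
  p <- sample(0:3, 20000, replace = TRUE)
  expect_equal(accuracy(confusion_counts(y, p)), 0.25, tolerance = 0.02)

  expect_equal(score_std(c(1, 2, 3)), 1.0)
  expect_equal(score_std(rep(0.7, 5)), 0)
  expect_equal(score_std(c(0.8, 1.0)), sqrt(0.02), tolerance = 1e-12)
  expect_true(is.na(score_std(0.9)))
})

test_that("training reduces the loss, is seed-deterministic, and overfits separable maps", {
  maps <- tiny_maps(n_per_class = 8, margin = 8, seed = 2)
  cfg <- tiny_config(epochs = 25, dropout = 0.1)
  fit <- cit_fit(maps, config = cfg, seed = 3)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  expect_equal(fit$history$train_acc[nrow(fit$history)], 1)   # overfit capacity
  # deterministic under the seed
  fit2 <- cit_fit(maps, config = cfg, seed = 3)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
  # inference determinism: the same batch gives identical logits
  lg <- predict(fit, maps[1:2], type = "logits")
  expect_identical(lg, predict(fit, maps[1:2], type = "logits"))
  # a sample's logits do not depend on its batch companions
  expect_equal(lg[1, ], predict(fit, maps[1], type = "logits")[1, ],
               tolerance = 1e-12)
  # zero epochs returns the initialized model unchanged
  f0 <- cit_fit(maps, config = tiny_config(epochs = 0), seed = 3)
  init <- cit_init(tiny_config(epochs = 0), seed = 3)
  expect_identical(f0$params, init$params)
  # probabilities are a softmax: rows sum to 1
  pr <- predict(fit, maps[1:4], type = "prob")
  expect_equal(rowSums(pr), rep(1, 4), tolerance = 1e-12)
  # head parameters receive nonzero gradients on a random batch
  X <- citnet:::as_map_batch(maps[1:4])
  fw <- citnet:::cit_fwd_full(fit, X, training = TRUE)
  ce <- citnet:::softmax_ce(fw$logits, c(1L, 2L, 3L, 1L))
  g <- citnet:::cit_bwd_full(fit, fw$cache, ce$dlogits)
  expect_true(all(g[["head.W"]] != 0))
})

test_that("cit_stages = {} under variant 'full' is bit-identical to baseline_concat", {
  maps <- tiny_maps(n_per_class = 4, margin = 5, seed = 6)
  cfg_a <- tiny_config(cit_stages = integer(0), epochs = 3)
  cfg_b <- tiny_config(variant = "baseline_concat", epochs = 3)
  fa <- cit_fit(maps, config = cfg_a, seed = 4)
  fb <- cit_fit(maps, config = cfg_b, seed = 4)
  expect_identical(fa$history, fb$history)
  expect_identical(fa$params[["head.W"]], fb$params[["head.W"]])
})

test_that("experiment protocol reports per-subject mean and dispersion", {
  set.seed(30)
  maps <- c(tiny_maps(6, margin = 6, seed = 7), tiny_maps(6, margin = 6, seed = 8))
  for (i in seq_along(maps)) attr(maps[[i]], "subject") <- if (i <= 18) 1L else 2L
  cfg <- tiny_config(epochs = 6)
  r <- run_experiment(maps, cfg, seed = 2, protocol = "per_subject")
  expect_equal(r$protocol, "per_subject")
  expect_length(r$per_subject, 2)
  expect_equal(r$acc, mean(r$per_subject))
  expect_equal(r$std, score_std(r$per_subject))
  expect_s3_class(r$confusion, "confusion_counts")
  # 18 maps per subject, 6 per class, 60/40 split: round(6*0.6)=4 train,
  # 2 test per class, so 6 test maps per subject
  expect_equal(sum(r$confusion), 12)
})

test_that("ablation grids emit the documented variant rows with shared seeds", {
  maps <- tiny_maps(n_per_class = 4, margin = 6, seed = 9)
  cfg <- tiny_config(epochs = 1)
  g8 <- run_ablation_grid(maps, cfg, grid = "cit", seed = 1, protocol = "pooled")
  expect_equal(nrow(g8), 8)
  expect_setequal(g8$variant, c("Baseline", "S1", "S2", "S3", "S1 & S2",
                                "S1 & S3", "S2 & S3", "Ours"))
  g3 <- run_ablation_grid(maps, cfg, grid = "table3", seed = 1, protocol = "pooled")
  expect_equal(nrow(g3), 4)
  g4 <- run_ablation_grid(maps, cfg, grid = "table4", seed = 1, protocol = "pooled")
  expect_equal(nrow(g4), 5)
  expect_true(all(g8$acc >= 0 & g8$acc <= 1))
})
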