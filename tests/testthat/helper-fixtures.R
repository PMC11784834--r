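# Shared fixtures: everything is generated in code at test time.

# A small network configuration that keeps every structural feature of the
# default architecture (2 basic blocks and 3 encoder blocks per stage, CIT
# at stages 1-3) but narrow widths, for fast tests.
tiny_config <- function(...) {
  args <- list(num_classes = 3, H = 16, W = 16, bands = 5,
               embed_dim = 16, heads = 2, mlp_ratio = 2, patch_size = 16,
               channels = c(8, 8, 16, 32, 64),
               blocks_per_stage = 2, encoders_per_stage = 3,
               cit_stages = 1:3, dropout = 0, learning_rate = 1e-3,
               batch_size = 16, epochs = 5, seed = 1L)
  override <- list(...)
  args[names(override)] <- override
  do.call(cit_config, args)
}

tiny_maps <- function(n_per_class = 8, n_classes = 3, margin = 6, seed = 1,
                      H = 16, W = 16) {
  generate_separable_maps(n_per_class, n_classes, margin, seed = seed,
                          H = H, W = W)
}

# A pure sinusoid recording on a single electrode set.
sine_recording <- function(freq, fs = 200, dur = 4, amp = 1, n_ch = 1) {
  t <- (seq_len(fs * dur) - 1) / fs
  raw_recording(matrix(rep(amp * sin(2 * pi * freq * t), n_ch),
                       n_ch, byrow = TRUE),
                paste0("CH", seq_len(n_ch)), fs = fs, label = 0L)
}

# Independent linear probe: nearest class centroid on flattened maps.
centroid_probe_accuracy <- function(maps, train_frac = 0.6, seed = 1) {
  y <- map_labels(maps)
  X <- t(as_map_batch(maps))
  sp <- split_dataset(y, train_frac, seed = seed)
  cls <- sort(unique(y))
  cent <- t(vapply(cls, function(cl)
    colMeans(X[sp$train[y[sp$train] == cl], , drop = FALSE]),
    numeric(ncol(X))))
  d <- vapply(seq_len(nrow(cent)), function(i)
    rowSums((X[sp$test, , drop = FALSE] -
               matrix(cent[i, ], length(sp$test), ncol(X), byrow = TRUE))^2),
    numeric(length(sp$test)))
  pred <- cls[max.col(-d, ties.method = "first")]
  mean(pred == y[sp$test])
}

# Zero the fusion parameters of a model so that the G2L 1x1 convolution
# reproduces the local features exactly and the L2G projection emits a
# zero token: the "additive capability" configuration.
zero_fusion_params <- function(model) {
  D <- model$config$embed_dim
  for (k in 1:3) {
    pfx <- sprintf("cit.s%d", k)
    C <- model$config$channels[k + 1]
    model$params[[paste0(pfx, ".l2g.W")]][] <- 0
    model$params[[paste0(pfx, ".l2g.b")]][] <- 0
    W <- matrix(0, C, D + C)
    W[, D + seq_len(C)] <- diag(C)
    model$params[[paste0(pfx, ".g2l.W")]] <- W
    model$params[[paste0(pfx, ".g2l.b")]][] <- 0
  }
  model
}
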