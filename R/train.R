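#' Stratified train/test split
#'
#' Seeded random shuffle followed by a stratified split: within each class,
#' `ratio` of the samples (rounded) go to the training set. The two index
#' sets are disjoint and exhaustive.
#'
#' @param labels Vector of class labels.
#' @param ratio Training fraction (default 0.6 for the 6:4 protocol).
#' @param seed Integer seed.
#' @return `list(train =, test =)` integer index vectors.
#' @export
split_dataset <- function(labels, ratio = 0.6, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("split_dataset: every class needs >= 2 samples (stratification error)")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n_tr <- max(1L, min(length(idx) - 1L, round(ratio * length(idx))))
    train <- c(train, idx[seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

softmax_ce <- function(logits, y1) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y1)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, dlogits = d / n, prob = p,
       acc = mean(max.col(logits, ties.method = "first") == y1))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gr * 0
      state$v[[nm]] <- gr * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}

#' Fit the CIT network
#'
#' Trains the configured network with Adam on the cross-entropy loss.
#' Mini-batches are reshuffled each epoch; the whole run is deterministic
#' in `seed` (single-threaded BLAS). Training stops after `config$epochs`
#' epochs, when the training loss has not improved for `config$patience`
#' epochs, or when training accuracy reaches `stop_train_acc`.
#'
#' @param maps List of labelled `spatial_spectral_map` objects (or any
#'   input accepted by [as_map_batch()] together with `labels`).
#' @param labels Optional 0-based integer class labels (read from the maps
#'   when `NULL`).
#' @param config A [cit_config()].
#' @param seed Seed for initialization, shuffling and dropout.
#' @param stop_train_acc Stop early once training accuracy reaches this
#'   value (default 1: stop when the training set is fit perfectly).
#' @param verbose Print one line per epoch.
#' @return A trained `cit_model`; `$history` holds per-epoch `loss` and
#'   `train_acc`.
#' @export
cit_fit <- function(maps, labels = NULL, config = cit_config(),
                    seed = config$seed, stop_train_acc = 1,
                    verbose = FALSE) {
  X <- as_map_batch(maps)
  if (is.null(labels)) labels <- map_labels(maps)
  if (length(labels) != ncol(X))
    stop("cit_fit: ", ncol(X), " samples but ", length(labels), " labels")
  classes <- sort(unique(labels))
  if (length(classes) > config$num_classes)
    stop("cit_fit: more observed classes than config$num_classes")
  y1 <- match(labels, classes)  # 1-based
  model <- cit_init(config, seed)
  model$classes <- classes
  n <- ncol(X)
  if (n == 0L) stop("cit_fit: empty training set")
  set.seed((as.integer(seed) + 1L) %% .Machine$integer.max)
  state <- new.env(parent = emptyenv())
  state$m <- list(); state$v <- list()
  hist_loss <- numeric(0); hist_acc <- numeric(0)
  best <- Inf; wait <- 0L; t_step <- 0L
  if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      fw <- cit_fwd_full(model, X[, b, drop = FALSE], training = TRUE)
      ce <- softmax_ce(fw$logits, y1[b])
      if (!is.finite(ce$loss)) stop("cit_fit: training diverged (loss is not finite)")
      grads <- cit_bwd_full(model, fw$cache, ce$dlogits)
      t_step <- t_step + 1L
      model$params <- adam_step(model$params, grads, state,
                                config$learning_rate, t_step)
      ep_loss <- ep_loss + ce$loss * length(b)
      ep_correct <- ep_correct + ce$acc * length(b)
    }
    hist_loss <- c(hist_loss, ep_loss / n)
    hist_acc <- c(hist_acc, ep_correct / n)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train acc %.3f",
                      ep, hist_loss[ep], hist_acc[ep]))
    if (hist_acc[ep] >= stop_train_acc) break
    if (hist_loss[ep] < best - 1e-6) { best <- hist_loss[ep]; wait <- 0L }
    else if ((wait <- wait + 1L) >= config$patience) break
  }
  model$history <- data.frame(epoch = seq_along(hist_loss),
                              loss = hist_loss, train_acc = hist_acc)
  model$trained <- TRUE
  model
}

#' Predict from a fitted CIT network
#'
#' @param object A `cit_model`.
#' @param maps Input maps.
#' @param type `"class"` (0-based labels as trained on), `"prob"` (softmax
#'   probabilities) or `"logits"`.
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return Vector of class labels, or an `N x num_classes` matrix.
#' @export
predict.cit_model <- function(object, maps, type = c("class", "prob", "logits"),
                              batch_size = 64L, ...) {
  type <- match.arg(type)
  X <- as_map_batch(maps)
  n <- ncol(X)
  out <- NULL
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    lg <- cit_fwd_full(object, X[, b, drop = FALSE], training = FALSE)$logits
    out <- rbind(out, lg)
  }
  if (type == "logits") return(out)
  if (type == "prob") {
    e <- exp(out - apply(out, 1L, max))
    return(e / rowSums(e))
  }
  cls <- if (!is.null(object$classes)) object$classes else
    seq_len(object$config$num_classes) - 1L
  cls[max.col(out, ties.method = "first")]
}

#' Classification accuracy of a model on labelled maps
#'
#' @param model A trained `cit_model`.
#' @param maps Labelled maps.
#' @param labels Optional labels (read from the maps when `NULL`).
#' @return Fraction correct in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, maps, labels = NULL) {
  if (is.null(labels)) labels <- map_labels(maps)
  mean(predict(model, maps) == labels)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized parameter set plus config and normalization
#' state. `load_checkpoint()` restores a ready-to-use model.
#'
#' @param model A `cit_model`.
#' @param path File path (`.rds`).
#' @return `path` / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  model$aux <- as.list(model$aux)
  saveRDS(model, path)
  path
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  model$aux <- list2env(model$aux, parent = emptyenv())
  model
}
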