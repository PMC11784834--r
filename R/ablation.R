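#' Run one training/evaluation experiment
#'
#' Implements the evaluation protocol: a seeded stratified 60/40 split,
#' training with the configured protocol, test accuracy from the confusion
#' matrix. With `protocol = "per_subject"` (the default) one model is
#' trained per subject on that subject's own data and the mean and sample
#' standard deviation of the per-subject accuracies are reported; with
#' `"pooled"` a single model is trained on the pooled split (dispersion is
#' then not applicable).
#'
#' @param maps Labelled (and, for per-subject evaluation, subject-tagged)
#'   `spatial_spectral_map` list.
#' @param config A [cit_config()].
#' @param seed Seed shared by split and training.
#' @param protocol `"per_subject"` or `"pooled"`.
#' @param stop_train_acc Passed to [cit_fit()].
#' @return List with `acc` (mean accuracy), `std` (sample SD across
#'   subjects, `NA` for a single subject or pooled protocol), `per_subject`
#'   accuracies, `confusion` (summed test confusion matrix) and `protocol`.
#' @export
run_experiment <- function(maps, config = cit_config(), seed = config$seed,
                           protocol = c("per_subject", "pooled"),
                           stop_train_acc = 1) {
  protocol <- match.arg(protocol)
  labels <- map_labels(maps)
  subjects <- map_subjects(maps)
  if (protocol == "per_subject" && length(unique(subjects)) >= 1 &&
      !anyNA(subjects)) {
    subj_ids <- sort(unique(subjects))
  } else {
    protocol <- "pooled"
    subj_ids <- NA
  }
  accs <- numeric(0)
  conf <- NULL
  groups <- if (protocol == "per_subject")
    lapply(subj_ids, function(s) which(subjects == s)) else
    list(seq_along(maps))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    sp <- split_dataset(labels[idx], ratio = config$split_ratio, seed = seed)
    tr <- idx[sp$train]; te <- idx[sp$test]
    fit <- cit_fit(maps[tr], labels[tr], config = config, seed = seed,
                   stop_train_acc = stop_train_acc)
    pred <- predict(fit, maps[te])
    cc <- confusion_counts(labels[te], pred,
                           classes = sort(unique(labels)))
    conf <- if (is.null(conf)) cc else structure(unclass(conf) + unclass(cc),
                                                 class = "confusion_counts")
    accs <- c(accs, accuracy(cc))
  }
  list(acc = mean(accs), std = score_std(accs), per_subject = accs,
       confusion = conf, protocol = protocol, seed = seed)
}

ablation_variants <- function(grid) {
  switch(grid,
    cit = {
      subsets <- list(integer(0), 1L, 2L, 3L, c(1L, 2L), c(1L, 3L),
                      c(2L, 3L), 1:3)
      names(subsets) <- c("Baseline", "S1", "S2", "S3", "S1 & S2", "S1 & S3",
                          "S2 & S3", "Ours")
      lapply(subsets, function(s) list(cit_stages = s))
    },
    table3 = list(
      `With only CNN branch` = list(variant = "cnn_only"),
      `With only Transformer branch` = list(variant = "transformer_only"),
      `Baseline` = list(variant = "baseline_concat"),
      `Full` = list(variant = "full")),
    table4 = list(
      `With only L2G block` = list(l2g = TRUE, g2l = FALSE),
      `With only L2G block and w/o TFM` = list(l2g = TRUE, g2l = FALSE, tfm = FALSE),
      `With only G2L block` = list(l2g = FALSE, g2l = TRUE),
      `With only G2L block and w/o CFM` = list(l2g = FALSE, g2l = TRUE, cfm = FALSE),
      `Full` = list()),
    stop("unknown ablation grid: ", grid))
}

#' Run an ablation grid
#'
#' Re-runs [run_experiment()] for each model variant of one of the three
#' ablation studies, with an identical seed (hence identical splits and
#' identical initial weights for shared components) across variants:
#' * `"cit"` - all 8 subsets of CIT stages \{1,2,3\} (none = Baseline,
#'   all = the full model);
#' * `"table3"` - CNN branch only, Transformer branch only, baseline late
#'   concatenation, full model;
#' * `"table4"` - L2G only (with/without fusing the prior token sequence),
#'   G2L only (with/without fusing the CNN feature map), full model.
#'
#' @inheritParams run_experiment
#' @param grid `"cit"`, `"table3"` or `"table4"`.
#' @param base_config Configuration shared by all variants.
#' @return Data frame with one row per variant: `variant`, `acc`, `std`.
#' @export
run_ablation_grid <- function(maps, base_config = cit_config(),
                              grid = c("cit", "table3", "table4"),
                              seed = base_config$seed,
                              protocol = "per_subject",
                              stop_train_acc = 1) {
  grid <- match.arg(grid)
  variants <- ablation_variants(grid)
  rows <- lapply(names(variants), function(nm) {
    cfg <- base_config
    for (f in names(variants[[nm]])) cfg[[f]] <- variants[[nm]][[f]]
    if (!is.null(variants[[nm]]$variant) &&
        variants[[nm]]$variant != "full") cfg$cit_stages <- integer(0)
    class(cfg) <- "cit_config"
    r <- run_experiment(maps, cfg, seed = seed, protocol = protocol,
                        stop_train_acc = stop_train_acc)
    data.frame(variant = nm, acc = r$acc, std = r$std)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
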