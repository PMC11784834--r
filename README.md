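# citnet

Emotion recognition from multichannel EEG with a parallel CNN +
Vision-Transformer network whose branches exchange information through
Convolution-Interactive-Transformer (CIT) fusion blocks.

## The problem and the model

Emotional state modulates scalp EEG as band-limited power changes with a
spatial topography. `citnet` implements the full pipeline from raw
62-channel recordings to class predictions:

1. **Spatial-spectral maps.** Recordings are segmented into non-overlapping
   4-s windows; each window is summarised as per-electrode power in the five
   canonical bands (δ 1–4, θ 4–8, α 8–14, β 14–31, γ 31–50 Hz), giving
   `S ∈ R^{62×5}`, then scattered onto a 32×32 scalp-layout grid:
   `S^M ∈ R^{32×32×5}`.
2. **Dual-branch network.** A modified-ResNet branch (stem
   `C0 = MaxPool(ReLU(BN(Conv7×7(S^M))))`, four stages of two basic blocks,
   channels 64-64-128-256-512) extracts local features `C1..C4`; a ViT
   branch (one token per band patch, four stages of three pre-norm encoder
   blocks with multi-head self-attention
   `Softmax(QKᵀ/√d_k)V`) extracts global features `T1..T4`.
3. **CIT fusion** after stages 1–3: the **L2G** block pools the CNN map
   (`F_Mean`), projects it (`F_Linear = Wᵀ F_Mean + b`) and joins it to the
   token sequence; the **G2L** block broadcasts the first token over the
   spatial grid, concatenates it with the CNN map along channels
   (64 + 768 → 832 at stage 1) and restores the channel plan with a 1×1
   convolution.
4. **Head and training:** concat(GAP(C4), mean(T4)) → dropout → affine →
   softmax cross-entropy, Adam (lr 1e-5, batch 32, dropout 0.2), stratified
   60/40 splits, accuracy `(TP+TN)/(TP+TN+FP+FN)` and across-subject sample
   standard deviation, plus the three ablation grids (CIT-stage subsets,
   branch-level variants, fusion-block variants).

Everything — convolutions, batch/layer norm, attention, backpropagation,
Adam — is implemented in base R over BLAS matrix products. A synthetic EEG
generator (1/f background noise plus class-specific band-limited
oscillations on class-specific electrode groups) makes the whole pipeline
testable without any licensed dataset. See the methods vignette
(`vignettes/cit-emotion-networks.Rmd`) for the design decisions and the
exact study conditions.

## Worked example

Synthetic 3-class dataset → spatial-spectral maps → reduced-width network
(embedding 64, 2 heads, 1 encoder block per stage) → held-out accuracy:

```r
library(citnet)
spec <- synthetic_spec(n_classes = 3, trials_per_class = 16, duration_s = 16,
                       snr = 10, seed = 5)
recs <- generate_dataset(spec)                 # 48 recordings, 16 s each
maps <- featurize_dataset(recs, standardize = TRUE, log10 = TRUE)
labels <- map_labels(maps)                     # 192 maps, 4 per recording
cfg <- cit_config(num_classes = 3, embed_dim = 64, heads = 2,
                  encoders_per_stage = 1, learning_rate = 1e-3, epochs = 60)
sp <- split_dataset(labels, ratio = 0.6, seed = 1)
fit <- cit_fit(maps[sp$train], labels[sp$train], config = cfg, seed = 1)
print(fit)
#> <cit_model> trained, 11,593,731 parameters
#> <cit_config> full: 32x32x5 maps, 3 classes
#>   CNN 64-64-128-256-512 (x2 blocks/stage), Transformer D=64 h=2 (x1 blocks/stage)
#>   CIT stages {1,2,3} fusion=concat, stem pad mode=standard
#>   Adam lr=0.001, batch=32, dropout=0.2, split=60:40
#>   12 epochs: final loss 0.0057, train accuracy 1.000
pred <- predict(fit, maps[sp$test])
cc <- confusion_counts(labels[sp$test], pred)
print(cc)
#> confusion counts (rows = truth, cols = predicted):
#>      0  1  2
#>   0 26  0  0
#>   1  0 24  2
#>   2  0  2 24
accuracy(cc)
#> 0.9487179
```

Each class plants an oscillation in one band over one electrode group
(α-frontal, β-temporal, γ-occipital at a 10:1 band-power SNR), so the maps
are separable by where and in which band slice power concentrates; the
network recovers 95% of held-out windows against a 33% majority rate.
Training this reduced model takes about a minute on one CPU core.

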