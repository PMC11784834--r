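---
title: "Dual-branch CNN-Transformer networks with interactive fusion for EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch CNN-Transformer networks with interactive fusion for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Emotion-related activity in scalp EEG expresses itself as band-limited power
changes with a spatial topography: which rhythm (delta, theta, alpha, beta,
gamma) changes, and over which electrodes. `citnet` classifies emotional
state from 62-channel EEG in two steps.

**Spatial-spectral representation.** Each recording is cut into
non-overlapping 4-second windows. For every window and every electrode the
power spectral density is summarised per band, giving a matrix
$S \in \mathbb{R}^{N_e \times B}$ ($N_e = 62$ electrodes, $B = 5$ bands:
delta 1--4, theta 4--8, alpha 8--14, beta 14--31, gamma 31--50 Hz). Each
band column is scattered onto an $H \times W$ grid (default $32 \times 32$)
at each electrode's scalp position, producing the map
$S^M \in \mathbb{R}^{H \times W \times B}$ that the network consumes.

**Dual-branch network.** Two parallel branches process $S^M$:

* a *CNN branch* (modified ResNet): a stem
  $C_0 = \mathrm{MaxPool}(\mathrm{ReLU}(\mathrm{BN}(\mathrm{Conv}_{7\times7}(S^M))))$
  followed by four stages of two residual basic blocks each, with channel
  plan 64-64-128-256-512 — local features $C_1 \dots C_4$;
* a *Transformer branch* (ViT-style): each band slice becomes one token via
  a shared linear patch projection (patch size 32, so 5 tokens), followed by
  four stages of three pre-norm encoder blocks
  ($x + \mathrm{MSA}(\mathrm{LN}(x))$, then $x + \mathrm{MLP}(\mathrm{LN}(x))$)
  — global features $T_1 \dots T_4$.

After stages 1, 2 and 3 the two branches exchange information through a
*Convolution-Interactive-Transformer* (CIT) fusion module with two halves:

* **L2G** (local to global): the stage-$k$ feature map is spatially averaged
  per channel ($F_{Mean}$), projected to the embedding width
  ($F_{Linear} = W^\top F_{Mean} + b$) and joined to the token sequence;
* **G2L** (global to local): the first token is extracted ($F_{Squeeze}$),
  broadcast over the stage's spatial grid ($F_{Expand}$), concatenated with
  the local feature map along channels ($F_{Concat}$, $C_k + D$ channels)
  and mapped back to $C_k$ channels by a $1 \times 1$ convolution.

The classifier concatenates the globally average-pooled $C_4$ (512 values)
with the token mean of $T_4$ ($D$ values), applies dropout and a single
affine map to class logits; training minimises the softmax cross-entropy
with Adam.

## Design decisions

Several architectural details are under-determined by the defining
equations; the package fixes them as follows, each behind a configuration
switch where a faithful alternative exists.

**Stem padding (`stem_padding_mode`).** The stem is specified with a
$7\times7$ kernel, stride 2 and *padding 4*, yet its output is also stated
to be $H/4 \times W/4 \times 64$. These are inconsistent: composing the
convolution and pooling arithmetic, pad 4 yields $9 \times 9$ from a
$32 \times 32$ input while the claimed $8 \times 8$ — on which the fusion
module's printed shapes depend — requires the standard ResNet pad 3.
The default is `"standard"` (pad 3, $8\times8$); `"paper"` keeps pad 4 and
produces $9\times9$, and all downstream shapes are then derived from the
size formulas rather than the printed values.

**Pooling arithmetic.** The stated pooling formula carries no padding term
although the pool itself is described with padding 1; the implementation
uses the padded quotient formula
$\lfloor (n + 2p - k)/s \rfloor + 1$ throughout, of which the padding-free
form is the $p = 0$ case.

**Residual shortcut (`paper_exact_shortcut`).** The printed shortcut
$\mathrm{BN}(\mathrm{Conv}_{1\times1}(\mathrm{Conv}_{3\times3}(x)))$ on
*every* block is nonstandard — as written it also transforms blocks whose
input and output shapes match. The default is the standard ResNet rule
(identity when shapes match, BN(Conv$_{1\times1}$) projection when
downsampling); the literal composition is available behind the flag.

**Embedding width (`embed_dim`).** The patch-embedding description uses a
hidden width of 256 while every fusion-module shape uses 768. A single knob
controls it; 768 is the default so that the fusion shapes
($64 + 768 \to 832 \to 64$) hold as printed.

**Transformer details.** Head count, MLP width, encoder ordering and the
presence of a class token are unstated: the package uses 8 heads
($d_h = D/8$), MLP width $4D$, pre-norm ordering, no class token (the
stage-0 output is one token per patch) and learned positional embeddings at
stage 0 only. Attention projections carry no biases — none appear in the
defining equations.

**Token growth in L2G (`fusion`).** The fusion equation
$F_G^{k+1} = \mathrm{Expand}(F_{Linear}) \,\|\, F_G^k$ concatenates, so the
token sequence grows; the growth is capped at one fusion token per enabled
stage (5, 6, 7, 8 tokens at the inputs of stages 1--4), and the fusion
token is *prepended* so that G2L's "first channel" extraction always reads
the most recent fusion token. The alternative reading — adding the
projected vector to every token, leaving the count at 5 — is available as
`fusion = "add"`. No normalization is applied inside the fusion blocks
(none is defined); an optional LayerNorm on the fusion token sits behind
`fusion_norm`, default off.

**Fusion as an additive capability.** With zeroed fusion parameters
($W = b = 0$ in the L2G projection; $1\times1$ convolution weights zero on
the broadcast-token channels and identity on the local channels) the G2L
path reproduces the unfused CNN branch *exactly*, and under `fusion = "add"`
the whole zero-fusion network equals the fusion-free network exactly. Under
the default concatenating fusion this equivalence cannot hold: even a
zero-valued extra token enters every softmax attention denominator of later
encoder stages (its key score is 0, contributing $e^0$ to the
normalisation) and the token-mean head, so the fused and pass-through
models differ by design — on a small test network the logit deviation is
order 1. The test suite asserts the exact equivalences where they hold and
records this structural deviation where it does not.

**Evaluation protocol.** Samples are shuffled and split 60/40, stratified
by class, with the seed fixed across ablation variants. Dispersion is
reported as the sample standard deviation of per-subject accuracies
($\sqrt{\sum_i (x_i - \bar x)^2 / (n-1)}$); the package defaults to
training one model per subject (`protocol = "per_subject"`) and reporting
mean ± SD across subjects, with a pooled mode available, since the original
protocol does not state which was used. Ablation grids (`run_ablation_grid`)
cover the three studies: the eight subsets of CIT stages, the four
branch-level variants, and the five fusion-block variants, where "without
TFM" replaces the token sequence by the fusion token and "without CFM" lets
the $1\times1$ convolution see only the broadcast token.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_s` | 4 s | segmentation window; a trailing partial window is discarded |
| bands | 1--4, 4--8, 8--14, 14--31, 31--50 Hz | delta, theta, alpha, beta, gamma |
| `psd` | `"welch"` | Welch: 1-s Hann windows, 50% overlap, band power = mean of in-band bins; `"mean_square"`: mean squared amplitude of the 4th-order Butterworth band-passed signal (the literal expectation-of-$x^2$ definition) |
| `H`, `W` | 32, 32 | map grid |
| `log10`, `standardize` | off | optional power transform and per-feature standardization (training-split statistics, reused for test data to avoid leakage) |
| `learning_rate` | 1e-5 | Adam step size (the published setting for full-scale training) |
| `batch_size`, `dropout` | 32, 0.2 | published protocol |
| `epochs`, `patience` | 100, 10 | epoch budget (unstated in the protocol; configurable) with early stopping on a training-loss plateau |

## Electrode layout

No electrode-to-grid mapping is published. The package ships a versioned
schematic table (`citnet-62-v1`, `inst/extdata/electrode_coords_62.tsv`) of
2-D scalp-projection coordinates for the 62-channel extended 10--20 montage
(authored for this package; nose up, unit disc). Electrodes are scattered to
their nearest grid cell; collisions are resolved by a deterministic outward
scan to the nearest free cell, keeping the mapping injective (at
$32\times32$ no collisions occur). Unmapped cells are zero by default;
`mode = "interpolate"` fills them by inverse-squared-distance weighting.
Whether the original maps were scattered or interpolated is unknown — both
are provided, neither claimed as the original choice. The table can be
replaced by any file with the same columns.

## Synthetic data: what it does and does not emulate

`synthetic_spec()` / `generate_dataset()` emulate the *structure* of the
reference recordings: 62 channels at 200 Hz, 3 or 4 emotion classes,
balanced trials per subject. The background is 1/f-shaped Gaussian noise at
10 µV RMS (so band-power statistics behave like EEG across the five bands);
each class adds an amplitude-modulated sinusoid at a random frequency inside
a class-specific band on a class-specific electrode group (defaults:
alpha-frontal, beta-temporal, gamma-occipital, theta-central), scaled so the
ratio of signal band power to background band power equals `snr`.
`generate_separable_maps()` skips the signal chain entirely and emits
unit-variance Gaussian maps whose class means differ by a margin in disjoint
cell blocks — a fast fixture for optimisation and ablation tests.

What the generator does **not** contain: ocular/muscle artifacts,
non-stationarity, volume-conduction correlation structure between channels,
inter-subject variability, or label noise. A model that learns these
synthetic datasets demonstrates that the pipeline, architecture, gradients
and training loop are correct and that the network can exploit band-limited,
spatially localised power differences — it says nothing about accuracy on
real emotion EEG, which is why no real-data accuracy figures are quoted
anywhere in this package.

## Numerical choices

* Batch norm: batch statistics in training, running statistics (momentum
  0.1, unbiased variance) in inference; $\varepsilon = 10^{-5}$.
* Layer norm: per-token mean/variance with $\varepsilon = 10^{-6}$.
* Initialization: He-normal for convolutions, Glorot-normal for linear
  maps, $\mathcal{N}(0, 0.02)$ positional embeddings, unit/zero norms.
  All parameters are created in a fixed order regardless of the ablation
  switches, so differently ablated models share identical initial weights
  under the same seed (this is what makes "no CIT stages" bit-identical to
  the late-concatenation baseline).
* Max pooling pads with $-\infty$ so padding never wins the max; ties keep
  the first offset.
* GELU uses the exact Gaussian form $x\,\Phi(x)$.
* Softmax (attention and loss) subtracts the row maximum before
  exponentiation.
* Degenerate spatial sizes (a layer whose output would be smaller than
  $1\times1$) raise an error rather than silently clamping. Note that at
  $1\times1$ feature maps only the centre tap of a $3\times3$ kernel sees
  data, so the off-centre weights of the deepest stage receive structurally
  zero gradients — expected, not a defect.
* All forward/backward passes are hand-written in base R over BLAS matrix
  products (im2col convolutions); the test suite verifies every layer
  type's gradient against central finite differences, and the training
  loop is exactly reproducible under a fixed seed in single-threaded
  execution.

## Problem sizes used by the tests and the acceptance script

Desk-scale runs use reduced widths — these are the package's documented
study conditions, not tuned values: the "reduced model" has embedding width
64, 2 heads, one encoder block per stage, and the full CNN channel plan;
optimisation checks use 240 separable maps (margin 5, 80 per class); the
end-to-end pipeline check uses 48 synthetic recordings (3 classes x 16
trials of 16 s, SNR 10, one subject), i.e. 192 maps, split 60/40. For these
small runs the Adam step size is 1e-3: the published 1e-5 is tailored to
GPU-scale training on hundreds of thousands of windows and underfits a
few-hundred-map problem inside any reasonable epoch budget. Ablation-grid
structure checks run 1-epoch trainings on 16x16 maps with narrow channels.

## Known limitations

* Inputs are plain-text array archives or in-memory recordings; EDF readers
  are not included. Feature stores and checkpoints are written as RDS.
* Training is CPU-bound base R: suitable for the desk-scale experiments
  above (minutes), not for full-scale training on real datasets.
* The per-subject vs pooled evaluation ambiguity and the scatter vs
  interpolation layout ambiguity are surfaced as options rather than
  resolved.
* `fusion = "concat"` changes the attention normalisation of later stages
  by construction (see *Fusion as an additive capability* above).
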