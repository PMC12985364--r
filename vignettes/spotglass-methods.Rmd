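---
title: "Methods: graph-transformer prediction of cell-type abundance from histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-transformer prediction of cell-type abundance from histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spatial transcriptomics assigns, to each capture spot on a tissue slide
(~100 µm, thousands of spots per slide), an estimate of how many cells of
each transcriptional type sit there — typically produced upstream by
deconvolving spot expression against a single-cell reference. These
abundance maps are expensive to produce. spotglass learns to predict them
directly from the H&E histology image: morphology is informative about
cellular composition, so a model trained on (patch image, abundance) pairs
can annotate slides for which only the image exists.

## Model

A slide becomes an undirected spatial graph: nodes are spots (each carrying
a square image patch centered on it), and each node is connected to its k
nearest neighbors by Euclidean distance, symmetrized by union (k = 6
reproduces hexagonal Visium adjacency; k = 8 suits square ST grids). Ties
are broken by (distance, node index) so graphs are platform-reproducible.

The unit of computation is the k-hop subgraph: a minibatch of center spots
B is expanded to its closure B^k (all spots within k hops, k = 2
throughout), with the induced edges. Training samples minibatches so every
spot is a center exactly once per epoch; inference makes every spot the
center of its own subgraph and keeps only the center prediction, which
makes predictions independent of how centers are grouped.

Per forward pass:

1. **Patch encoder.** Each node's patch is embedded to `d_emb` dimensions.
   The default `small_cnn` is a two-branch design: a pointwise (1×1)
   convolution extracts per-pixel color features which are pooled at count
   scale (summed over positions, divided by sqrt(P) — pooling preserves
   color composition exactly and delivers it at unit scale), while 3×3
   convolutions (stride 4, then 2) over the raw pixels summarize local
   texture and are mean-pooled at the deepest level; the concatenation is
   projected linearly to `d_emb = 64` and passed through a LayerNorm. The
   aggressive stride keeps one training run in CPU-minutes. A `plugin`
   encoder accepts any function producing embeddings (e.g. a pathology
   foundation model), treated as frozen.
2. **Local message passing.** Two GATv2 layers on the subgraph edges. The
   edge score is `a' LeakyReLU(W_l h_i + W_r h_j)` (slope 0.2), softmaxed
   over each node's neighborhood into attention weights; the update is
   `elu(sum_j alpha_ij W_r h_j)`. A node with no neighbors falls back to its
   self-message `elu(W_r h_i)`, since the aggregation is undefined on an
   empty neighborhood. Attention rows are asserted to sum to 1 on every
   pass.
3. **Long-range attention.** Two post-norm Transformer layers treat all
   nodes of the batch's closure as tokens: scaled dot-product multi-head
   self-attention (4 heads), residual + LayerNorm, position-wise
   feed-forward (width 128), residual + LayerNorm. There is no positional
   encoding — similarity of morphology, not proximity, drives long-range
   sharing, and the layer is permutation-equivariant. The Transformer
   consumes the GAT output; whether it should instead consume raw encoder
   embeddings is not determined by the architecture's description, and the
   serial choice both matches the layer-naming (the features "fed into" the
   Transformer are the GNN representations) and gives the fusion stage
   three genuinely different scales.
4. **Fusion and head.** `X_fuse = w_i I_emb + w_g X_GAT + w_t X_Trans` with
   pre-defined weights (default 1, 1, 1 — a pure residual sum), then a
   2-layer MLP with a final softplus so predicted abundances are
   non-negative while MSE gradients stay smooth. The loss is the MSE over
   *all* nodes of the closure, not only centers.

All layers, including backpropagation, are implemented in vectorized base R
(no deep-learning runtime is available or required at this scale); analytic
gradients are verified against central finite differences in the test
suite. Optimization is Adam, default learning rate 1e-4 — the conservative
choice appropriate for fine-tuning a pretrained encoder. The worked
end-to-end experiments in this package train `small_cnn` from scratch and
therefore use a larger step size with a short warmup (4e-3, 6 warmup
epochs, 48 centers per minibatch over 30 epochs); all values are
configurable in `train_config()`. Two further residual-friendly choices
matter when the whole stack trains from scratch in a fixed budget: the
encoder embedding passes through a LayerNorm (so pooled-feature offsets
cannot saturate the attention stacks), and the context branches start small
(the last GAT message transform and the last Transformer block's output
gain at one tenth scale), letting the fused representation begin as
essentially the patch embedding with spatial context growing in as it
reduces the loss.

During training, attention in step 3 spans the whole minibatch closure (a
stochastic, batch-composition-dependent scope that acts as a regularizer);
at inference the scope is the center's own subgraph, so results are
deterministic and batch-independent. The two scopes differ; determinism at
inference was judged more valuable than matching the training-time token
distribution, and held-out accuracy measured with both scopes agrees to a
few percent on synthetic slides.

## Downstream analyses

**Colocalization.** Spatial co-occurrence of two cell types x, y is scored
by bivariate Moran's R under RBF spatial weights
`w0_ij = exp(-d_ij^2 / (2 l^2))` with zero diagonal and element-wise
normalization to total sum n:

R = Σ_i Σ_j w_ij (x_i − x̄)(y_j − ȳ) / (√Σ(x_i − x̄)² · √Σ(y_i − ȳ)²).

With y = x this is univariate Moran's I, which forms the diagonal of the
type × type colocalization matrix. The diagonal of the *weight* matrix is
zeroed before normalization (standard Moran practice; self-pairs carry no
spatial information). The length scale defaults to 1.2 × the modal
nearest-neighbor spot distance — on the lattice's own scale, large enough
to reach the first neighbor ring and small enough not to flatten local
structure. Matrices from predictions and ground truth are compared by
cosine similarity and Pearson correlation of their upper triangles;
consensus across slides is the element-wise mean plus the count of slides
with R > 0.20.

**Evaluation metrics.** Per cell type: Pearson correlation across spots,
and Jensen-Shannon divergence between the spot-normalized predicted and
true maps. JSD is reported in bits (base 2) so it is bounded by 1; the
normalization axis is over spots, giving one scalar per cell type (a
per-spot axis would give one value per spot instead). A companion analysis
correlates each type's ground-truth Moran's I with its prediction accuracy.

**Super-resolution.** Because the model predicts from a patch and its
spatial context, it can be queried on a denser lattice: sub-spot centers at
spacing/f (f ∈ {2,4,8,16}), same patch size, k-NN graph rebuilt on the
dense grid. `direct_predict` uses frozen parameters; `impute_finetune`
first fine-tunes on a given low-resolution abundance map (all parameters,
one tenth of the standard learning rate, 5 epochs by default — the
schedule is a free choice and configurable).

**Survival.** Slide-level features (averaged or attention-pooled spot
predictions) enter a discrete-time hazard model. Follow-up is cut at the
quartiles (type-7, linear interpolation) of *uncensored* survival times
into R = 4 intervals; subject labels are 0-based with times beyond the last
cut in the last interval. The head produces one sigmoid hazard per
interval, `z_r = b_r + x'v` with a shared slope v — the shared slope keeps
the model a single risk score whose weights are directly comparable to a
generating linear risk. The loss is the discrete-survival negative
log-likelihood; labels map to 1-based hazard indices u = Y + 1, so a
censored subject (c = 1) contributes −log S(u) and an uncensored one
−log S(u−1) − log h_u, with S(r) = Π_{u≤r}(1 − h_u), S(0) = 1. The
uncensored-only part is mixed in with weight β (default 0.5, the neutral
midpoint of its range); since the two terms coincide for uncensored
subjects, β effectively down-weights censored cases by (1 − β).
Probabilities inside logs are clamped at 1e-7.

The concordance index follows the printed survival-time-ordering form: the
fraction of admissible pairs whose score order matches time order, scores
being survival-time surrogates (risk scores are negated before the call).
Admissible pairs require the earlier time to be an observed event — the
standard censored restriction — and score ties count ½ (Harrell). Risk
stratification splits at the median score; Kaplan-Meier curves come from
`survival::survfit` and the separation test from `survival::survdiff`.
Attribution uses integrated gradients (right-Riemann path integral from a
baseline), which is exact for linear models and satisfies completeness up
to the Riemann error; per-interval hazard attributions are averaged over
slides for the cell-type × interval heatmap.

## Synthetic data: what it emulates and what it does not

`generate_synthetic_slide()` produces a hex or square lattice of spots
(hex rows offset by half a spacing so 6-NN is the hex neighborhood),
spatially autocorrelated latent abundance fields (white noise on the spot
grid, Gaussian-smoothed at length `field_smoothness` in spot units,
standardized, rectified at 0 and capped at 2), and an image whose patches
encode abundance as color stipples: each cell type has a fixed saturated
hue, and the number of stippled pixels is proportional to abundance
(`px_per_unit` pixels per abundance unit) on a tissue-pink background.
Abundance is quantized to the stipple resolution, so at `noise_sd = 0` the
abundance vector is *exactly* recoverable from a patch by counting colors
(`decode_patch_abundance()`); stipple positions are a fixed function of the
patch size, shared by all slides, so the morphology-to-abundance encoding
is slide-invariant — the property the prediction task presumes of real
tissue. Pixel noise is i.i.d. Gaussian with sd `noise_sd` on the
normalized [0,1] intensity scale, applied to the whole canvas before
patches are cropped from it, keeping canvas and patches consistent.

Default study conditions used by the end-to-end experiments: 20 × 20 hex
spots, 32 px spacing and patches, 8 cell types, smoothness 2 (which yields
univariate Moran's I well above 0.2), noise 0.05; two training slides and
one held-out slide; 30 epochs. These sizes were chosen as the smallest at
which the spatial structure, the multi-slide generalization question, and
the evaluation statistics are all non-trivial.

What the generator deliberately does not emulate: nucleus/stain texture,
staining batch effects, pyramidal WSI formats, segmentation errors, and any
nonlinear or many-to-one morphology–abundance relationship. Passing the
recovery experiment therefore shows that the architecture, training loop,
and inference path are correct and that the model generalizes across
fields drawn from the same process — not that histology morphology
predicts cell abundance in real tissue at any particular accuracy.

`generate_survival_cohort()` draws i.i.d. standard-normal features and
exponential event times with rate `exp(x'w)` (proportional hazards — the
simplest model under which both the discrete hazard fit and C-index
recovery are well-posed). A `censor_frac` fraction of subjects draws an
independent Exp(1) censoring time, and is censored when it precedes the
event; realized censoring is therefore below `censor_frac`.

## Numerical choices and degenerate inputs

* Crop windows are half-open, 0-based, `[c − floor(s/2), c − floor(s/2) + s)`
  per axis; non-integer centers round half-to-even. Background pixels are
  those with channel mean ≥ 220; a patch is discarded only when its
  background fraction strictly exceeds 0.75; slides need ≥ 100 valid
  patches.
* The color normalizer matches per-channel mean/SD in log-intensity space
  (a Reinhard-style stage); stain-separation methods can be plugged in via
  the same patch-to-patch interface. A zero-variance channel maps to a
  constant at the reference mean, with a warning.
* k-NN ties: (distance, index) lexicographic. Supergrid spacing is inferred
  as the modal nearest-neighbor distance; coordinates must share one
  lattice phase modulo the dense spacing (tolerance min(0.5 px, pitch/4)),
  otherwise an explicit spacing is required.
* Attention softmaxes subtract the row maximum; GAT and Transformer row
  sums are asserted to be within 1e-6 of 1 on every forward pass.
* Constant abundance columns are excluded (with a warning) from
  colocalization matrices and flagged NA in Pearson vectors rather than
  failing a slide; constant fields are hard errors in Moran statistics
  (zero denominator).
* Seeds make everything bit-reproducible on one platform: the generators,
  batch order, and weight initialization all flow from explicit seeds.

## Known limitations

Pure-R training is CPU-minutes at desk scale but does not extend to real
WSI cohorts; the architecture and tests are scale-faithful, not
throughput-faithful. The ResNet-18 configuration of the original design is
reachable only through the plugin interface (no pretrained weights ship
with this package). Transformer memory grows quadratically in the closure
size, which caps practical minibatch closures on CPU. The C-index
denominator question (whether inadmissible censored pairs were counted) is
resolved in favor of the standard censored restriction; both conventions
coincide on uncensored data.
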