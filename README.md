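# spotglass

Predicts fine-grained cell-type abundance at every spot of a spatial
transcriptomics slide **directly from the H&E histology image**, and runs the
companion analyses that make such predictions useful: cell–cell
colocalization, accuracy metrics, super-resolved cellular maps, and
survival modeling on slide-level cellular composition.

It is written for computational biologists who have paired
(histology, deconvolved abundance) training data — e.g. Visium slides with
Cell2location labels — and want to infer cellular architecture on H&E-only
slides, at desk scale and fully reproducibly.

## The model

A slide is abstracted as an undirected spatial graph `G = {V, E}`: nodes are
spots carrying square image patches centered on them, edges connect each
spot to its k nearest neighbors (k = 6 for hexagonal Visium lattices, k = 8
for square ST grids), symmetrized by union. The working unit is the k-hop
subgraph `B^k = B ∪ N_1(B) ∪ … ∪ N_k(B)` around a minibatch of center spots
`B` (k = 2 throughout).

One forward pass composes:

* a convolutional **patch encoder** `I_emb = I(patches)` (a compact
  multi-scale CNN by default; any embedding function can be plugged in),
* **GATv2 message passing** over subgraph edges — edge scores
  `e(h_i, h_j) = aᵀ LeakyReLU(W_l h_i + W_r h_j)`, softmax-normalized over
  each neighborhood into coefficients `α_ij`, update
  `h'_i = elu(Σ_j α_ij W_r h_j)` — capturing short-range spatial context,
* **Transformer self-attention** over all nodes of `B^k` (scaled
  dot-product, multi-head, post-norm), capturing long-range similarity
  without positional encoding,
* **multi-scale fusion** `X_fuse = w_i I_emb + w_g X_GAT + w_t X_Trans`
  and an MLP head with softplus output, trained with MSE over all nodes of
  `B^k`.

Inference slides a window over the slide: every spot becomes the center of
its own 2-hop subgraph and only the center prediction is kept. Predicting
on a denser lattice of sub-spot centers (same patch size, spacing divided
by 2–16) yields super-resolved cellular maps, optionally after fine-tuning
on a low-resolution abundance map.

Downstream, cell-type pairs are scored for colocalization with bivariate
Moran's R under RBF spatial weights (`w⁰_ij = exp(−d²_ij/2l²)`, zero
diagonal, normalized to total sum n), predictions are evaluated by
per-cell-type Pearson R and Jensen–Shannon divergence (bits), and
slide-level pooled abundances feed a discrete-time survival model: quartile
time intervals, sigmoid hazards, censoring-aware log-likelihood with
uncensored up-weighting β, Harrell-style concordance index, Kaplan–Meier
risk stratification, and integrated-gradients attribution of cell types to
interval-specific mortality risk.

The neural network — forward passes *and* analytic backpropagation — is
implemented in vectorized base R and verified against finite differences
and explicit-loop oracles in the test suite; no deep-learning runtime is
required.

## Worked example

Everything runs on synthetic slides whose patches deterministically encode
the local cell-type abundances, so the full pipeline is testable without
downloads (see the methods vignette for what the generator does and does
not emulate):

```r
library(spotglass)

# three slides: train on two, hold out the third
mk <- function(s) generate_synthetic_slide(synthetic_slide_config(
  n_rows = 20, n_cols = 20, n_cell_types = 8, patch_size_px = 32,
  spot_spacing_px = 32, noise_sd = 0.05, seed = s))
slides <- lapply(1:3, mk)

bundles <- lapply(slides[1:2], function(s)
  slide_bundle(build_knn_graph(s$spots, 6), s$patches, s$abundance))

model <- init_model(model_config(n_cell_types = 8, patch_size = 32), seed = 1)
fit <- train_model(model, bundles, train_config(
  epochs = 30, batch_centers = 48, learning_rate = 4e-3,
  warmup_epochs = 6, seed = 1))

held <- slides[[3]]
g <- build_knn_graph(held$spots, 6)
pred <- predict_slide(fit$model, g, held$patches)
evaluate_predictions(pred, held$abundance)
#> eval_report: mean Pearson 0.931, mean JSD 0.084 bits over 8 cell types
```

A mean Pearson of ~0.93 across the eight cell types means the spatial
abundance maps of the held-out slide are recovered almost exactly from
imagery alone; JSD near zero confirms the predicted spatial distributions
match the true ones. Colocalization structure carries over too:

```r
w  <- rbf_spatial_weights(held$spots)
cm_true <- colocalization_matrix(held$abundance, w)
cm_pred <- colocalization_matrix(pred, w)
round(unlist(compare_colocalization(cm_true, cm_pred)), 3)
#>  cosine pearson
#>   0.856   0.858
```

And the survival arm recovers planted risk structure:

```r
co  <- generate_survival_cohort(500, 5, c(1.2, .8, -.8, .8, -.8),
                                censor_frac = 0.3, seed = 1)
hm  <- fit_hazard_model(co, seed = 1)
new <- generate_survival_cohort(500, 5, c(1.2, .8, -.8, .8, -.8),
                                censor_frac = 0.3, seed = 2)
concordance_index(-predict(hm, new$features), new$time, new$censor)
#> [1] 0.8254124
```

A thin CLI for the shell-shaped stages (patch cropping/filtering,
colocalization, evaluation, survival utilities) is installed at
`inst/cli/spotglass`.

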