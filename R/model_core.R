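#' Patch-encoder specification
#'
#' `small_cnn` is a compact two-branch convolutional encoder trained
#' end-to-end with the rest of the model. The color branch applies a
#' pointwise (1x1) ReLU layer to raw pixels and pools the activations at
#' count scale (sum over positions divided by sqrt(P)): color composition
#' survives pooling exactly and arrives at unit scale, so the downstream
#' readout stays well-conditioned. The texture branch applies strided 3x3
#' ReLU convolutions (stride 4 then 2) to the raw pixels and mean-pools the
#' deepest features. Both pooled vectors are concatenated and projected
#' linearly to `d_emb`. It is the default so the full pipeline trains in
#' minutes on one CPU. `plugin` wraps any user function
#' mapping an n x s x s x 3 patch array to an n x `d_emb` embedding matrix
#' (e.g. features from a pathology foundation model); plugin encoders are
#' treated as frozen.
#'
#' @param kind `"small_cnn"` or `"plugin"`.
#' @param d_emb Embedding dimension (must be divisible by the Transformer head
#'   count).
#' @param fn For `plugin`: the embedding function.
#' @param conv_channels For `small_cnn`: the first entry is the width of the
#'   pointwise color branch, the rest are successive texture-branch blocks
#'   (stacked only while the spatial size supports a 3x3 kernel).
#' @return An `encoder_spec`.
#' @export
encoder_spec <- function(kind = c("small_cnn", "plugin"), d_emb = 64L,
                         fn = NULL, conv_channels = c(32L, 16L, 32L)) {
  kind <- match.arg(kind)
  stop_if(!is_count(d_emb) || d_emb < 1, "d_emb must be a positive integer")
  stop_if(kind == "plugin" && !is.function(fn),
          "plugin encoder needs an embedding function")
  structure(list(kind = kind, d_emb = as.integer(d_emb), fn = fn,
                 conv_channels = as.integer(conv_channels)),
            class = "encoder_spec")
}

#' Model configuration
#'
#' Defaults follow the reference configuration at test scale: 2 GATv2 layers
#' (ELU nonlinearity, LeakyReLU attention slope 0.2), 2 post-norm Transformer
#' layers with 4 heads and scaled dot-product attention, fusion weights
#' (1, 1, 1) (a pure residual sum), and a 2-layer MLP head with a final
#' softplus so predicted abundances are non-negative. All of these are
#' configurable.
#'
#' @param n_cell_types Number of output cell types.
#' @param patch_size Input patch side in pixels.
#' @param encoder An [encoder_spec()].
#' @param n_gat_layers,n_tf_layers Depth of the GAT and Transformer stacks.
#' @param n_heads Transformer attention heads (must divide `d_emb`).
#' @param d_ff Transformer feed-forward width.
#' @param leaky_slope LeakyReLU slope of the GATv2 scoring function.
#' @param fusion_weights Length-3 numeric `(w_i, w_g, w_t)` weighting the
#'   encoder, GAT and Transformer branches; at least one must be non-zero.
#' @param head_hidden Hidden width of the MLP prediction head.
#' @return A `model_config`.
#' @export
model_config <- function(n_cell_types, patch_size,
                         encoder = encoder_spec(), n_gat_layers = 2L,
                         n_tf_layers = 2L, n_heads = 4L, d_ff = 128L,
                         leaky_slope = 0.2, fusion_weights = c(1, 1, 1),
                         head_hidden = 128L) {
  stop_if(!is_count(n_cell_types) || n_cell_types < 1,
          "n_cell_types must be a positive integer")
  stop_if(encoder$d_emb %% n_heads != 0, "d_emb must be divisible by n_heads")
  stop_if(length(fusion_weights) != 3 || !all(is.finite(fusion_weights)),
          "fusion_weights must be 3 finite numbers")
  stop_if(all(fusion_weights == 0), "at least one fusion weight must be non-zero")
  stop_if(leaky_slope <= 0, "leaky_slope must be positive")
  structure(list(n_cell_types = as.integer(n_cell_types),
                 patch_size = as.integer(patch_size), encoder = encoder,
                 n_gat_layers = as.integer(n_gat_layers),
                 n_tf_layers = as.integer(n_tf_layers),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 leaky_slope = leaky_slope,
                 fusion_weights = as.numeric(fusion_weights),
                 head_hidden = as.integer(head_hidden)),
            class = "model_config")
}

# Two-branch geometry for the small_cnn encoder at a given patch size.
# The color branch is a single pointwise (1x1) layer over raw pixels whose
# activations are sum-pooled at count scale (divisor sqrt(P)): color
# composition survives pooling exactly and arrives at unit scale, so the
# readout needs only O(1) weights. The texture branch applies strided 3x3
# convolutions to the raw pixels (stride 4 then 2 - a coarse summary is
# enough, the composition is already carried by the color branch) and is
# mean-pooled at the deepest level.
small_cnn_metas <- function(patch_size, conv_channels) {
  stop_if(length(conv_channels) < 2, "need color + at least one texture block")
  color <- conv_meta(patch_size, patch_size, 3L, k = 1L, stride = 1L)
  color$c_out <- conv_channels[1]
  tex <- list()
  H <- patch_size; C <- 3L
  for (b in seq_along(conv_channels)[-1]) {
    stride <- if (b == 2L) 4L else 2L
    if (H < 3L) break
    m <- conv_meta(H, H, C, k = 3L, stride = stride)
    m$c_out <- conv_channels[b]
    tex[[length(tex) + 1L]] <- m
    H <- m$oh; C <- m$c_out
  }
  stop_if(length(tex) == 0, "patch_size too small for the texture branch")
  list(color = color, tex = tex)
}

#' Initialize a model
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `spotglass_model`: `config`, `params` (nested list of numeric
#'   arrays), plus cached conv geometry.
#' @export
init_model <- function(config, seed = 1L) {
  stop_if(!inherits(config, "model_config"), "config must be a model_config")
  d <- config$encoder$d_emb
  with_seed(seed, {
    params <- list()
    metas <- NULL
    if (config$encoder$kind == "small_cnn") {
      metas <- small_cnn_metas(config$patch_size, config$encoder$conv_channels)
      # color basis: spread weights and offsets so the ReLU kinks cut between
      # color clusters and the pooled features form a well-conditioned basis
      cc <- metas$color$c_out
      color <- list(W = matrix(stats::rnorm(3 * cc, sd = 1.5), 3, cc),
                    b = stats::runif(cc, -0.4, 0.4))
      tex <- lapply(metas$tex, function(m) init_conv(m, m$c_out))
      d_pool <- cc + metas$tex[[length(metas$tex)]]$c_out
      # embedding LayerNorm keeps the scale entering the attention stacks
      # bounded whatever the pooled-feature offsets are
      params$enc <- list(color = color, tex = tex,
                         fc = init_linear(d_pool, d), ln = init_layernorm(d))
    }
    # Context branches start small: the GAT stack's final message transform
    # and the last Transformer block's output LayerNorm gain are initialized
    # at one tenth of their usual scale, so the fused representation begins
    # as essentially the encoder embedding and the context branches grow in
    # as they reduce the loss. This residual-friendly initialization
    # markedly speeds up end-to-end convergence in a fixed epoch budget
    # while avoiding the degenerate all-zero activations of an exact
    # zero-init.
    params$gat <- lapply(seq_len(config$n_gat_layers), function(l) {
      sc <- if (l == config$n_gat_layers) 0.1 else 1
      list(Wl = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
           Wr = matrix(stats::rnorm(d * d, sd = sc * sqrt(1 / d)), d, d),
           a = stats::rnorm(d, sd = sqrt(1 / d)))
    })
    params$tf <- lapply(seq_len(config$n_tf_layers), function(l) {
      ln2 <- init_layernorm(d)
      if (l == config$n_tf_layers) ln2$gamma <- rep(0.1, d)
      list(Wq = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
           Wk = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
           Wv = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
           Wo = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
           ln1 = init_layernorm(d), ln2 = ln2,
           ff1 = init_linear(d, config$d_ff), ff2 = init_linear(config$d_ff, d))
    })
    params$head <- list(l1 = init_linear(d, config$head_hidden),
                        l2 = init_linear(config$head_hidden, config$n_cell_types))
    structure(list(config = config, params = params, enc_metas = metas),
              class = "spotglass_model")
  })
}

#' @export
print.spotglass_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "spotglass_model: %s encoder (d_emb=%d), %d GAT + %d Transformer layers, %d cell types\n",
    cfg$encoder$kind, cfg$encoder$d_emb, cfg$n_gat_layers, cfg$n_tf_layers,
    cfg$n_cell_types))
  cat(sprintf("  parameters: %d\n", length(tree_flatten(x$params))))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints hold every parameter tensor plus the configuration.
#' @param model A `spotglass_model`.
#' @param path Checkpoint path (RDS).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

## ---- encoder ----------------------------------------------------------

as_patch_array <- function(patches) {
  if (inherits(patches, "patch_stack")) return(patches$pixels)
  stop_if(length(dim(patches)) != 4L, "patches must be an n x s x s x 3 array")
  patches
}

# Pre-flatten a patch array into the encoder's channels-last working layout:
# rows (position, image) with position fastest, one column per channel,
# intensities normalized to [-0.5, 0.5]. `flat_patch_rows` gathers the rows
# of a node subset.
flatten_patches <- function(px) {
  structure(list(mat = matrix(aperm(px, c(2, 3, 1, 4)), ncol = 3) / 255 - 0.5,
                 P = dim(px)[2] * dim(px)[3], n = dim(px)[1],
                 raw = px),
            class = "flat_patches")
}

flat_patch_subset <- function(fp, nodes) {
  rows <- rep(seq_len(fp$P), times = length(nodes)) +
    rep((nodes - 1L) * fp$P, each = fp$P)
  structure(list(mat = fp$mat[rows, , drop = FALSE], P = fp$P,
                 n = length(nodes), raw = NULL),
            class = "flat_patches")
}

enc_fwd <- function(patches, model) {
  if (inherits(patches, "flat_patches")) {
    if (model$config$encoder$kind == "plugin") {
      stop_if(is.null(patches$raw), "plugin encoders need raw patch arrays")
      return(list(out = model$config$encoder$fn(patches$raw), cache = NULL))
    }
    x <- patches$mat
    n <- patches$n
  } else {
    px <- as_patch_array(patches)
    n <- dim(px)[1]
    if (model$config$encoder$kind == "plugin") {
      return(list(out = model$config$encoder$fn(px), cache = NULL))
    }
    x <- flatten_patches(px)$mat
  }
  metas <- model$enc_metas
  # color branch: pointwise features, count-scale pooled (sum / sqrt(P))
  ccv <- conv_fwd(x, model$params$enc$color, metas$color, n)
  cac <- act_relu(ccv$out)
  P <- metas$color$P
  grp <- rep(seq_len(n), each = P)
  color_pool <- rowsum(cac$out, grp, reorder = FALSE) / sqrt(P)
  # texture branch: strided convs over the raw pixels, mean-pooled
  tx <- x
  tcaches <- vector("list", length(metas$tex))
  for (l in seq_along(metas$tex)) {
    cv <- conv_fwd(tx, model$params$enc$tex[[l]], metas$tex[[l]], n)
    ac <- act_relu(cv$out)
    tcaches[[l]] <- list(cv = cv$cache, ac = ac$cache)
    tx <- ac$out
  }
  last <- metas$tex[[length(metas$tex)]]
  tpool <- global_pool_fwd(tx, last$P, last$c_out, n)
  fc <- linear_fwd(cbind(color_pool, tpool$out), model$params$enc$fc)
  ln <- layernorm_fwd(fc$out, model$params$enc$ln)
  list(out = ln$out,
       cache = list(ccv = ccv$cache, cac = cac$cache, grp = grp, P = P,
                    n_color = metas$color$c_out, tex = tcaches,
                    tpool = tpool$cache, fc = fc$cache, ln = ln$cache))
}

enc_bwd <- function(cache, d_out, model) {
  if (is.null(cache)) return(NULL) # plugin encoder is frozen
  lnb <- layernorm_bwd(cache$ln, d_out)
  fcb <- linear_bwd(cache$fc, lnb$dx)
  cc <- cache$n_color
  d_cpool <- fcb$dx[, seq_len(cc), drop = FALSE]
  d_tpool <- fcb$dx[, -seq_len(cc), drop = FALSE]
  # color branch
  d_cact <- d_cpool[cache$grp, , drop = FALSE] / sqrt(cache$P)
  ccb <- conv_bwd(cache$ccv, act_relu_bwd(cache$cac, d_cact))
  # texture branch
  dx <- global_pool_bwd(cache$tpool, d_tpool)
  tex_grads <- vector("list", length(cache$tex))
  for (l in rev(seq_along(cache$tex))) {
    d_pre <- act_relu_bwd(cache$tex[[l]]$ac, dx)
    cb <- conv_bwd(cache$tex[[l]]$cv, d_pre)
    tex_grads[[l]] <- cb$grads
    dx <- cb$dx
  }
  list(color = ccb$grads, tex = tex_grads, fc = fcb$grads, ln = lnb$grads)
}

#' Encode patches into node embeddings
#'
#' Runs the model's patch encoder in evaluation mode: one embedding row per
#' patch, order-aligned with the input, deterministic.
#'
#' @param patches A `patch_stack` or n x s x s x 3 array in \[0,255\].
#' @param model A `spotglass_model`.
#' @return n x d_emb embedding matrix.
#' @export
encode_patches <- function(patches, model) {
  px <- as_patch_array(patches)
  stop_if(dim(px)[2] != model$config$patch_size,
          "patch size does not match the encoder (expected ",
          model$config$patch_size, ")")
  enc_fwd(px, model)$out
}

## ---- GATv2 layer ------------------------------------------------------

# Directed edge bookkeeping for a set of undirected edges on n nodes.
build_edge_index <- function(edges, n) {
  if (nrow(edges) == 0) {
    return(list(tgt = integer(0), src = integer(0), gid = integer(0),
                groups = list(), present = integer(0),
                isolated = seq_len(n), n = n))
  }
  tgt <- c(edges[, 1], edges[, 2])
  src <- c(edges[, 2], edges[, 1])
  groups <- split(seq_along(tgt), tgt)
  present <- as.integer(names(groups))
  gid <- match(tgt, present)
  list(tgt = tgt, src = src, gid = gid, groups = groups, present = present,
       isolated = setdiff(seq_len(n), present), n = n)
}

gat_fwd <- function(H, ei, p, slope) {
  n <- nrow(H)
  U <- H %*% p$Wl
  V <- H %*% p$Wr
  if (length(ei$tgt) > 0) {
    G <- U[ei$tgt, , drop = FALSE] + V[ei$src, , drop = FALSE]
    lr <- act_leakyrelu(G, slope)
    s <- as.vector(lr$out %*% p$a)
    mx <- vapply(ei$groups, function(ix) max(s[ix]), numeric(1))
    es <- exp(s - mx[ei$gid])
    den <- vapply(ei$groups, function(ix) sum(es[ix]), numeric(1))
    alpha <- es / den[ei$gid]
    rs <- vapply(ei$groups, function(ix) sum(alpha[ix]), numeric(1))
    stop_if(any(abs(rs - 1) > 1e-6),
            "internal: GAT attention rows do not sum to 1")
    Opre <- segment_sum(alpha * V[ei$src, , drop = FALSE], ei$tgt, n)
  } else {
    G <- NULL; lr <- NULL; alpha <- numeric(0)
    Opre <- matrix(0, n, ncol(V))
  }
  # nodes without neighbors fall back to their own transformed features
  if (length(ei$isolated) > 0) {
    Opre[ei$isolated, ] <- V[ei$isolated, , drop = FALSE]
  }
  ac <- act_elu(Opre)
  list(out = ac$out,
       cache = list(H = H, V = V, G = G, lrG = if (!is.null(lr)) lr$cache,
                    alpha = alpha, ei = ei, Opre = Opre, p = p,
                    slope = slope))
}

gat_bwd <- function(cache, d_out) {
  ei <- cache$ei
  n <- ei$n
  p <- cache$p
  dO <- act_elu_bwd(cache$Opre, d_out)
  dV <- matrix(0, n, ncol(cache$V))
  if (length(ei$isolated) > 0) {
    dV[ei$isolated, ] <- dO[ei$isolated, , drop = FALSE]
  }
  dU <- matrix(0, n, ncol(cache$V))
  da <- numeric(length(p$a))
  if (length(ei$tgt) > 0) {
    alpha <- cache$alpha
    Vsrc <- cache$V[ei$src, , drop = FALSE]
    dOt <- dO[ei$tgt, , drop = FALSE]
    dalpha <- rowSums(dOt * Vsrc)
    dV <- dV + segment_sum(alpha * dOt, ei$src, n)
    ssum <- segment_sum(alpha * dalpha, ei$tgt, n)
    ds <- alpha * (dalpha - ssum[ei$tgt, 1])
    lr <- act_leakyrelu(cache$G, cache$slope) # recompute activation output
    da <- as.vector(crossprod(lr$out, ds))
    dG <- act_leakyrelu_bwd(cache$lrG, outer(ds, p$a), cache$slope)
    dU <- dU + segment_sum(dG, ei$tgt, n)
    dV <- dV + segment_sum(dG, ei$src, n)
  }
  dH <- dU %*% t(p$Wl) + dV %*% t(p$Wr)
  list(dx = dH,
       grads = list(Wl = crossprod(cache$H, dU),
                    Wr = crossprod(cache$H, dV), a = da))
}

#' Apply one GATv2 message-passing layer
#'
#' For each node i with neighbors N_i, edge scores are
#' `e(h_i, h_j) = a' LeakyReLU(W_l h_i + W_r h_j)`, normalized with a softmax
#' over N_i into attention coefficients `alpha_ij`, and the new representation
#' is `elu(sum_j alpha_ij W_r h_j)`. Nodes with no neighbors pass through as
#' `elu(W_r h_i)` (self-message), since the aggregation is undefined for an
#' empty neighborhood.
#'
#' @param h n x d node embedding matrix.
#' @param edges m x 2 matrix of undirected edges (node indices).
#' @param params List with `Wl`, `Wr` (d x d') and `a` (length d');
#'   see [init_model()] for the trained versions.
#' @param leaky_slope LeakyReLU slope of the scoring function.
#' @param return_attention Also return the per-edge attention coefficients.
#' @return n x d' matrix, or (with attention) a list `h`, `attention`
#'   (data.frame `target`, `source`, `alpha`).
#' @export
gatv2_layer <- function(h, edges, params, leaky_slope = 0.2,
                        return_attention = FALSE) {
  h <- as.matrix(h)
  edges <- matrix(as.integer(edges), ncol = 2)
  stop_if(nrow(edges) > 0 && any(edges < 1 | edges > nrow(h)),
          "edges reference unknown nodes")
  stop_if(ncol(params$Wl) != length(params$a) ||
            !all(dim(params$Wl) == dim(params$Wr)) ||
            nrow(params$Wl) != ncol(h), "parameter shapes are inconsistent")
  ei <- build_edge_index(edges, nrow(h))
  fw <- gat_fwd(h, ei, params, leaky_slope)
  if (!return_attention) return(fw$out)
  list(h = fw$out,
       attention = data.frame(target = ei$tgt, source = ei$src,
                              alpha = fw$cache$alpha))
}

## ---- Transformer layer ------------------------------------------------

tf_fwd <- function(H, p, n_heads) {
  n <- nrow(H); d <- ncol(H)
  dk <- d %/% n_heads
  sc <- 1 / sqrt(dk)
  Q <- H %*% p$Wq; K <- H %*% p$Wk; V <- H %*% p$Wv
  A <- vector("list", n_heads)
  O <- matrix(0, n, d)
  for (h in seq_len(n_heads)) {
    ix <- ((h - 1) * dk + 1):(h * dk)
    S <- Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) * sc
    A[[h]] <- row_softmax(S)
    stop_if(any(abs(rowSums(A[[h]]) - 1) > 1e-6),
            "internal: attention rows do not sum to 1")
    O[, ix] <- A[[h]] %*% V[, ix, drop = FALSE]
  }
  M <- O %*% p$Wo
  ln1 <- layernorm_fwd(H + M, p$ln1)
  f1 <- linear_fwd(ln1$out, p$ff1)
  r <- act_relu(f1$out)
  f2 <- linear_fwd(r$out, p$ff2)
  ln2 <- layernorm_fwd(ln1$out + f2$out, p$ln2)
  list(out = ln2$out,
       cache = list(H = H, Q = Q, K = K, V = V, A = A, O = O, p = p,
                    n_heads = n_heads, dk = dk, sc = sc,
                    ln1 = ln1$cache, f1 = f1$cache, r = r$cache,
                    f2 = f2$cache, ln2 = ln2$cache))
}

tf_bwd <- function(cache, d_out) {
  p <- cache$p
  b2 <- layernorm_bwd(cache$ln2, d_out)
  f2b <- linear_bwd(cache$f2, b2$dx)
  drelu <- act_relu_bwd(cache$r, f2b$dx)
  f1b <- linear_bwd(cache$f1, drelu)
  dZ <- b2$dx + f1b$dx # residual around the feed-forward block
  b1 <- layernorm_bwd(cache$ln1, dZ)
  dM <- b1$dx
  dH <- b1$dx # residual around attention
  dO <- dM %*% t(p$Wo)
  dWo <- crossprod(cache$O, dM)
  n <- nrow(cache$H); d <- ncol(cache$H)
  dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
  for (h in seq_len(cache$n_heads)) {
    ix <- ((h - 1) * cache$dk + 1):(h * cache$dk)
    A <- cache$A[[h]]
    dOh <- dO[, ix, drop = FALSE]
    Vh <- cache$V[, ix, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, ix] <- crossprod(A, dOh)
    dS <- row_softmax_bwd(A, dA)
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE] * cache$sc
    dK[, ix] <- crossprod(dS, cache$Q[, ix, drop = FALSE]) * cache$sc
  }
  dH <- dH + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dx = dH,
       grads = list(Wq = crossprod(cache$H, dQ), Wk = crossprod(cache$H, dK),
                    Wv = crossprod(cache$H, dV), Wo = dWo,
                    ln1 = b1$grads, ln2 = b2$grads,
                    ff1 = f1b$grads, ff2 = f2b$grads))
}

#' Apply one Transformer layer over a token set
#'
#' Post-norm Transformer block: scaled dot-product multi-head self-attention
#' over all tokens, residual + LayerNorm, then a row-wise feed-forward block
#' with residual + LayerNorm. There is no positional encoding, so the layer
#' is permutation-equivariant: tokens are graph nodes and long-range
#' correlations are carried entirely by feature similarity.
#'
#' @param H n x d token matrix (nodes currently in scope).
#' @param params Transformer layer parameters (see [init_model()]).
#' @param n_heads Number of attention heads (must divide d).
#' @param return_attention Also return the per-head attention matrices.
#' @return n x d matrix, or a list `h`, `attention` (list of n x n matrices).
#' @export
transformer_layer <- function(H, params, n_heads = 4L,
                              return_attention = FALSE) {
  H <- as.matrix(H)
  stop_if(nrow(H) == 0, "empty token set")
  stop_if(ncol(H) %% n_heads != 0, "token width must be divisible by n_heads")
  fw <- tf_fwd(H, params, n_heads)
  if (!return_attention) return(fw$out)
  list(h = fw$out, attention = fw$cache$A)
}

## ---- fusion + head ----------------------------------------------------

head_fwd <- function(X, p) {
  f1 <- linear_fwd(X, p$l1)
  r <- act_relu(f1$out)
  f2 <- linear_fwd(r$out, p$l2)
  sp <- act_softplus(f2$out)
  list(out = sp$out,
       cache = list(f1 = f1$cache, r = r$cache, f2 = f2$cache, sp = sp$cache))
}

head_bwd <- function(cache, d_out) {
  d2 <- act_softplus_bwd(cache$sp, d_out)
  f2b <- linear_bwd(cache$f2, d2)
  d1 <- act_relu_bwd(cache$r, f2b$dx)
  f1b <- linear_bwd(cache$f1, d1)
  list(dx = f1b$dx, grads = list(l1 = f1b$grads, l2 = f2b$grads))
}

#' Fuse multi-scale features and predict abundances
#'
#' The fused representation is the weighted residual sum
#' `X_fuse = w_i * I_fuse + w_g * X_GAT + w_t * X_Trans`; the MLP head (ReLU
#' hidden layer, softplus output) maps each node's fused features to
#' non-negative cell-type abundances.
#'
#' @param I_fuse,X_GAT,X_Trans n x d feature matrices from the encoder, GAT
#'   and Transformer branches (shapes must match).
#' @param weights Length-3 numeric `(w_i, w_g, w_t)`, not all zero.
#' @param head_params Head parameters (`l1`, `l2` linear layers, see
#'   [init_model()]).
#' @return List with `prediction` (n x n_cell_types, non-negative) and
#'   `fused` (X_fuse).
#' @export
fuse_and_predict <- function(I_fuse, X_GAT, X_Trans, weights, head_params) {
  stop_if(!all(dim(I_fuse) == dim(X_GAT)) || !all(dim(I_fuse) == dim(X_Trans)),
          "feature matrices must share a shape")
  stop_if(length(weights) != 3 || all(weights == 0),
          "weights must be 3 values with at least one non-zero")
  fused <- weights[1] * I_fuse + weights[2] * X_GAT + weights[3] * X_Trans
  list(prediction = head_fwd(fused, head_params)$out, fused = fused)
}

#' Mean squared error over all nodes and cell types
#'
#' @param pred,truth Equal-shaped numeric matrices.
#' @return Scalar mean of squared element-wise differences.
#' @export
mse_loss <- function(pred, truth) {
  stop_if(!all(dim(pred) == dim(truth)), "shape mismatch")
  stop_if(anyNA(pred) || anyNA(truth), "NaN in loss inputs")
  mean((pred - truth)^2)
}

## ---- full model forward/backward -------------------------------------

# Forward pass on one subgraph's nodes. `edges` are local undirected indices.
model_fwd <- function(model, patches, edges, need_cache = FALSE) {
  cfg <- model$config
  enc <- enc_fwd(patches, model)
  ei <- build_edge_index(matrix(as.integer(edges), ncol = 2), nrow(enc$out))
  H <- enc$out
  gat_caches <- vector("list", cfg$n_gat_layers)
  for (l in seq_len(cfg$n_gat_layers)) {
    fw <- gat_fwd(H, ei, model$params$gat[[l]], cfg$leaky_slope)
    gat_caches[[l]] <- fw$cache
    H <- fw$out
  }
  X_gat <- H
  Z <- X_gat
  tf_caches <- vector("list", cfg$n_tf_layers)
  for (l in seq_len(cfg$n_tf_layers)) {
    fw <- tf_fwd(Z, model$params$tf[[l]], cfg$n_heads)
    tf_caches[[l]] <- fw$cache
    Z <- fw$out
  }
  w <- cfg$fusion_weights
  fused <- w[1] * enc$out + w[2] * X_gat + w[3] * Z
  hd <- head_fwd(fused, model$params$head)
  out <- list(prediction = hd$out)
  if (need_cache) {
    out$cache <- list(enc = enc$cache, gat = gat_caches, tf = tf_caches,
                      head = hd$cache, w = w)
  }
  out
}

# Backward pass; returns gradients in the same shape as model$params.
model_bwd <- function(model, cache, d_pred) {
  hb <- head_bwd(cache$head, d_pred)
  w <- cache$w
  d_enc <- w[1] * hb$dx
  d_gat_out <- w[2] * hb$dx
  d_tf <- w[3] * hb$dx
  tf_grads <- vector("list", length(cache$tf))
  for (l in rev(seq_along(cache$tf))) {
    tb <- tf_bwd(cache$tf[[l]], d_tf)
    tf_grads[[l]] <- tb$grads
    d_tf <- tb$dx
  }
  d_gat_out <- d_gat_out + d_tf # Transformer consumes the GAT output
  gat_grads <- vector("list", length(cache$gat))
  for (l in rev(seq_along(cache$gat))) {
    gb <- gat_bwd(cache$gat[[l]], d_gat_out)
    gat_grads[[l]] <- gb$grads
    d_gat_out <- gb$dx
  }
  d_enc <- d_enc + d_gat_out
  grads <- list()
  eg <- enc_bwd(cache$enc, d_enc, model)
  if (!is.null(eg)) grads$enc <- eg
  grads$gat <- gat_grads
  grads$tf <- tf_grads
  grads$head <- hb$grads
  grads
}
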