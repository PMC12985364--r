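#' Training configuration
#'
#' @param epochs Number of passes over all center nodes (>= 1).
#' @param batch_centers Center nodes per minibatch.
#' @param hops Subgraph radius used for training (default 2).
#' @param learning_rate Optimizer step size (> 0 for training to progress;
#'   0 is allowed and leaves parameters untouched, useful for dry runs).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param lr_schedule `"constant"` (default, appropriate when fine-tuning) or
#'   `"cosine"` (decay to zero over the epoch budget).
#' @param warmup_epochs Epochs of linear learning-rate warmup (default 0);
#'   a few warmup epochs stabilize from-scratch training of the attention
#'   stacks at larger step sizes.
#' @param seed Integer seed controlling minibatch order and any other
#'   randomness; fixed seeds give bit-reproducible runs on one platform.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_centers = 64L, hops = 2L,
                         learning_rate = 1e-4,
                         optimizer = c("adam", "sgd"),
                         lr_schedule = c("constant", "cosine"),
                         warmup_epochs = 0L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  lr_schedule <- match.arg(lr_schedule)
  stop_if(!is_count(epochs) || epochs < 1, "epochs must be >= 1")
  stop_if(!is.numeric(learning_rate) || learning_rate < 0,
          "learning_rate must be >= 0")
  structure(list(epochs = as.integer(epochs),
                 batch_centers = as.integer(batch_centers),
                 hops = as.integer(hops), learning_rate = learning_rate,
                 optimizer = optimizer, lr_schedule = lr_schedule,
                 warmup_epochs = as.integer(warmup_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Bundle one slide's training inputs
#'
#' @param graph A `slide_graph` over the slide's spots.
#' @param patches A `patch_stack` or n x s x s x 3 array, row-aligned with the
#'   graph's nodes.
#' @param labels n x n_cell_types non-negative abundance matrix (the training
#'   target), row-aligned with the graph's nodes.
#' @return A `slide_bundle`.
#' @export
slide_bundle <- function(graph, patches, labels) {
  px <- as_patch_array(patches)
  n <- nrow(graph$coords)
  stop_if(dim(px)[1] != n, "patch count does not match graph nodes")
  stop_if(nrow(labels) != n, "label rows do not match graph nodes")
  if (!is.null(rownames(labels)) && !is.null(graph$node_ids)) {
    stop_if(!identical(rownames(labels), graph$node_ids),
            "label rownames do not align with graph node ids")
  }
  structure(list(graph = graph, patches = px, labels = as.matrix(labels)),
            class = "slide_bundle")
}

batch_patch_input <- function(b, nodes) {
  if (!is.null(b$flat)) {
    flat_patch_subset(b$flat, nodes)
  } else {
    b$patches[nodes, , , , drop = FALSE]
  }
}

# loss of one epoch partition without updating parameters
epoch_loss <- function(model, bundles, cfg) {
  losses <- c()
  for (b in bundles) {
    subs <- sample_training_batch(b$graph, cfg$batch_centers, cfg$hops)
    for (sg in subs) {
      fw <- model_fwd(model, batch_patch_input(b, sg$nodes), sg$edges)
      losses <- c(losses, mse_loss(fw$prediction,
                                   b$labels[sg$nodes, , drop = FALSE]))
    }
  }
  mean(losses)
}

#' Train a model end-to-end on subgraph minibatches
#'
#' Each epoch permutes every slide's spots into center minibatches, expands
#' each to its k-hop subgraph, and minimizes the MSE between predicted and
#' labelled abundances over *all* subgraph nodes, backpropagating jointly
#' through the head, Transformer, GAT layers and patch encoder. The loss
#' trace records the mean minibatch loss per epoch, with epoch 0 the loss of
#' the initial parameters.
#'
#' @param model A `spotglass_model` from [init_model()].
#' @param slides A `slide_bundle` or list of them.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` (trained), `trace` (data.frame `epoch`, `loss`).
#' @export
train_model <- function(model, slides, cfg = train_config(), verbose = FALSE) {
  if (inherits(slides, "slide_bundle")) slides <- list(slides)
  stop_if(length(slides) == 0, "no training slides")
  for (b in slides) {
    stop_if(!inherits(b, "slide_bundle"), "slides must be slide_bundle objects")
    stop_if(ncol(b$labels) != model$config$n_cell_types,
            "label columns do not match the model's n_cell_types")
  }
  cell_types <- colnames(slides[[1]]$labels)
  if (model$config$encoder$kind == "small_cnn") {
    # pre-flatten every slide's patches into the encoder's working layout
    slides <- lapply(slides, function(b) {
      b$flat <- flatten_patches(b$patches)
      b
    })
  }
  with_seed(cfg$seed, {
    st <- adam_state(model$params)
    trace <- data.frame(epoch = 0L, loss = epoch_loss(model, slides, cfg))
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- if ((cfg$lr_schedule %||% "constant") == "cosine") {
        cfg$learning_rate * 0.5 * (1 + cos(pi * (ep - 1) / cfg$epochs))
      } else {
        cfg$learning_rate
      }
      wu <- cfg$warmup_epochs %||% 0L
      if (wu > 0 && ep <= wu) lr_ep <- lr_ep * ep / (wu + 1)
      losses <- c()
      for (b in slides) {
        subs <- sample_training_batch(b$graph, cfg$batch_centers, cfg$hops)
        for (sg in subs) {
          fw <- model_fwd(model, batch_patch_input(b, sg$nodes),
                          sg$edges, need_cache = TRUE)
          y <- b$labels[sg$nodes, , drop = FALSE]
          losses <- c(losses, mse_loss(fw$prediction, y))
          d_pred <- 2 * (fw$prediction - y) / length(y)
          dimnames(d_pred) <- NULL # keep parameter trees free of label names
          grads <- model_bwd(model, fw$cache, d_pred)
          if (cfg$optimizer == "adam") {
            up <- adam_step(model$params, grads, st, lr_ep)
            model$params <- up$params
            st <- up$state
          } else {
            model$params <- tree_map2(model$params, grads, function(p, g) {
              p - lr_ep * g
            })
          }
        }
      }
      trace <- rbind(trace, data.frame(epoch = ep, loss = mean(losses)))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.6f", ep, mean(losses)))
      }
    }
    model$cell_types <- cell_types
    list(model = model, trace = trace)
  })
}

#' Predict a whole slide by center-node sliding-window inference
#'
#' Every spot is sampled once as the center of its own k-hop subgraph; the
#' model runs on that subgraph and only the center node's prediction is kept,
#' so results are independent of how centers are grouped and deterministic in
#' evaluation mode. Patch embeddings are computed once for all spots (they do
#' not depend on the graph) and reused across subgraphs.
#'
#' @param model A trained `spotglass_model`.
#' @param graph `slide_graph` over the slide's spots.
#' @param patches `patch_stack` or array, row-aligned with the graph.
#' @param hops Subgraph radius (default 2, matching training).
#' @param chunk Patch-encoding chunk size (memory knob; no effect on values).
#' @return Spots x cell-types abundance matrix (non-negative), rownames the
#'   graph's node ids.
#' @export
predict_slide <- function(model, graph, patches, hops = 2L, chunk = 256L) {
  px <- as_patch_array(patches)
  n <- nrow(graph$coords)
  stop_if(dim(px)[1] != n, "patch count does not match graph nodes")
  cfg <- model$config
  emb <- matrix(0, n, cfg$encoder$d_emb)
  fp <- if (cfg$encoder$kind == "small_cnn") flatten_patches(px)
  for (s in seq(1L, n, by = chunk)) {
    ix <- s:min(s + chunk - 1L, n)
    input <- if (is.null(fp)) px[ix, , , , drop = FALSE] else
      flat_patch_subset(fp, ix)
    emb[ix, ] <- enc_fwd(input, model)$out
  }
  w <- cfg$fusion_weights
  fused <- matrix(0, n, cfg$encoder$d_emb)
  for (c_i in seq_len(n)) {
    sg <- sample_subgraph(graph, c_i, hops)
    loc <- match(c_i, sg$nodes)
    ei <- build_edge_index(sg$edges, length(sg$nodes))
    H <- emb[sg$nodes, , drop = FALSE]
    for (l in seq_len(cfg$n_gat_layers)) {
      H <- gat_fwd(H, ei, model$params$gat[[l]], cfg$leaky_slope)$out
    }
    Z <- H
    for (l in seq_len(cfg$n_tf_layers)) {
      Z <- tf_fwd(Z, model$params$tf[[l]], cfg$n_heads)$out
    }
    fused[c_i, ] <- w[1] * emb[c_i, ] + w[2] * H[loc, ] + w[3] * Z[loc, ]
  }
  pred <- head_fwd(fused, model$params$head)$out
  rownames(pred) <- graph$node_ids
  colnames(pred) <- model$cell_types %||%
    sprintf("type_%02d", seq_len(cfg$n_cell_types))
  pred
}

#' Super-resolution request
#'
#' @param factor Densification factor (1, 2, 4, 8 or 16).
#' @param mode `"direct_predict"` (frozen parameters) or `"impute_finetune"`
#'   (first fine-tune on a low-resolution abundance map, then predict on the
#'   dense grid).
#' @param low_res_labels For `impute_finetune`: abundance matrix aligned with
#'   the original spots.
#' @return A `super_resolution_request`.
#' @export
super_resolution_request <- function(factor,
                                     mode = c("direct_predict",
                                              "impute_finetune"),
                                     low_res_labels = NULL) {
  mode <- match.arg(mode)
  stop_if(mode == "impute_finetune" && is.null(low_res_labels),
          "impute_finetune requires low_res_labels")
  structure(list(factor = as.integer(factor), mode = mode,
                 low_res_labels = low_res_labels),
            class = "super_resolution_request")
}

#' Predict a super-resolved cellular map
#'
#' Densifies the spot lattice by `req$factor` (sub-spot centers at spacing
#' `spacing / factor`), crops patches of the *same* size at the sub-spot
#' centers (the sliding-window radius halves per 2x of resolution but the
#' model input size is unchanged), rebuilds the spatial k-NN graph on the
#' dense grid, and runs center-node inference. In `impute_finetune` mode the
#' model is first fine-tuned on the supplied low-resolution (coordinate,
#' label) pairs at a reduced learning rate; in `direct_predict` mode the
#' parameters stay frozen.
#'
#' @param model A trained `spotglass_model`.
#' @param image H x W x 3 slide raster in \[0,255\].
#' @param spots [spot_table()] of the original spot centers.
#' @param req A [super_resolution_request()].
#' @param k_neighbors k for the dense (and fine-tuning) graph.
#' @param hops Subgraph radius.
#' @param finetune_cfg [train_config()] for `impute_finetune`; default 5
#'   epochs at one tenth of the standard learning rate.
#' @return List with `abundance` (dense spots x cell types), `spots` (the
#'   dense spot table), `spacing`, `model` (fine-tuned or original).
#' @export
super_resolve <- function(model, image, spots, req, k_neighbors = 6L,
                          hops = 2L,
                          finetune_cfg = train_config(epochs = 5L,
                                                      learning_rate = 1e-5)) {
  stop_if(!inherits(req, "super_resolution_request"),
          "req must be a super_resolution_request")
  ps <- model$config$patch_size
  if (req$mode == "impute_finetune") {
    stop_if(is.null(req$low_res_labels), "impute_finetune requires labels")
    orig_graph <- build_knn_graph(spots, k_neighbors)
    orig_patches <- crop_patches(image, spots, ps, pad = TRUE)
    lab <- req$low_res_labels
    stop_if(nrow(lab) != nrow(spots),
            "low_res_labels do not align with the original spots")
    fit <- train_model(model,
                       slide_bundle(orig_graph, orig_patches, lab),
                       finetune_cfg)
    model <- fit$model
  }
  grid <- make_supergrid(spots, req$factor)
  dense_patches <- crop_patches(image, grid$spots, ps, pad = TRUE)
  dense_graph <- build_knn_graph(grid$spots, k_neighbors)
  abundance <- predict_slide(model, dense_graph, dense_patches, hops)
  list(abundance = abundance, spots = grid$spots, spacing = grid$spacing,
       model = model)
}
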