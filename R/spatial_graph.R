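#' Build the slide-level spatial k-NN graph
#'
#' Each spot selects its `k_neighbors` nearest spots by Euclidean distance;
#' the directed selections are symmetrized by union (an undirected edge exists
#' if either endpoint selected the other), the standard construction for GNN
#' message passing. Distance ties are broken by (distance, node index)
#' lexicographic order so graphs are identical across platforms. With k = 6 on
#' a hexagonal (Visium-style) lattice interior spots get exactly their six hex
#' neighbors; k = 8 pairs with square (ST-style) lattices.
#'
#' @param coords n x 2 matrix of spot coordinates (pixels), or a
#'   [spot_table()].
#' @param k_neighbors Neighbors selected per node (clamped to n - 1 with a
#'   warning when too large).
#' @param node_ids Optional character ids (taken from a spot table
#'   automatically).
#' @return A `slide_graph`: `node_ids`, `coords`, `edges` (m x 2 integer
#'   matrix, each undirected pair stored once with i < j), `adj` (neighbor
#'   index list), `k_neighbors`.
#' @export
build_knn_graph <- function(coords, k_neighbors, node_ids = NULL) {
  if (inherits(coords, "spot_table") ||
      (is.data.frame(coords) && all(c("x_px", "y_px") %in% names(coords)))) {
    if (is.null(node_ids)) node_ids <- coords$spot_id
    coords <- cbind(coords$x_px, coords$y_px)
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stop_if(n < 2, "need at least 2 nodes to build a graph")
  stop_if(!is_count(k_neighbors) || k_neighbors < 1,
          "k_neighbors must be a positive integer")
  k <- as.integer(k_neighbors)
  if (k >= n) {
    warning("k_neighbors >= number of nodes; clamping to n - 1")
    k <- n - 1L
  }
  if (is.null(node_ids)) node_ids <- sprintf("spot_%04d", seq_len(n))
  D <- as.matrix(stats::dist(coords))
  sel_i <- integer(0)
  sel_j <- integer(0)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    sel_i <- c(sel_i, rep.int(i, k))
    sel_j <- c(sel_j, nb)
  }
  a <- pmin(sel_i, sel_j)
  b <- pmax(sel_i, sel_j)
  key <- unique((a - 1) * n + b)
  edges <- cbind(as.integer((key - 1) %/% n) + 1L,
                 as.integer((key - 1) %% n) + 1L)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  new_slide_graph(node_ids, coords, edges, k)
}

#' Construct a slide graph from explicit parts
#'
#' Low-level constructor used by [build_knn_graph()]; also handy for
#' degenerate cases (e.g. a single-spot slide with no edges).
#'
#' @param node_ids Character node ids.
#' @param coords n x 2 coordinate matrix.
#' @param edges m x 2 integer matrix of undirected pairs (self-loops
#'   rejected).
#' @param k_neighbors The k used to build the edges (metadata).
#' @return A `slide_graph`.
#' @export
new_slide_graph <- function(node_ids, coords, edges, k_neighbors = NA_integer_) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    stop_if(any(edges < 1 | edges > n), "edge endpoint out of range")
    stop_if(any(edges[, 1] == edges[, 2]), "self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[!duplicated(edges), , drop = FALSE]
  }
  adj <- rep(list(integer(0)), n)
  if (nrow(edges) > 0) {
    tgt <- c(edges[, 1], edges[, 2])
    src <- c(edges[, 2], edges[, 1])
    o <- order(tgt, src)
    adj <- unname(split(src[o], factor(tgt[o], levels = seq_len(n))))
  }
  structure(list(node_ids = as.character(node_ids), coords = coords,
                 edges = edges, adj = adj,
                 k_neighbors = as.integer(k_neighbors)),
            class = "slide_graph")
}

#' @export
print.slide_graph <- function(x, ...) {
  cat(sprintf("slide_graph: %d nodes, %d undirected edges (k = %s)\n",
              nrow(x$coords), nrow(x$edges), x$k_neighbors))
  invisible(x)
}

#' Neighbors of a node
#' @param graph A `slide_graph`.
#' @param i Node index.
#' @return Integer vector of neighbor indices (sorted).
#' @export
graph_neighbors <- function(graph, i) graph$adj[[i]]

#' Sample the k-hop subgraph around a set of center nodes
#'
#' Breadth-first closure: the node set is every node within `hops` graph
#' steps of any center, `hop_of` records the exact BFS distance to the
#' nearest center, and the edge set is the full subset of graph edges with
#' both endpoints inside the closure.
#'
#' @param graph A `slide_graph`.
#' @param centers Integer node indices (or character node ids).
#' @param hops Number of hops k >= 0 (default 2, the unit used for both
#'   training and inference).
#' @return A `subgraph`: `centers`, `nodes` (sorted global indices),
#'   `hop_of` (aligned with `nodes`), `edges` (local indices into `nodes`),
#'   `center_local`, `hops`.
#' @export
sample_subgraph <- function(graph, centers, hops = 2L) {
  if (is.character(centers)) {
    centers <- match(centers, graph$node_ids)
  }
  centers <- as.integer(centers)
  n <- nrow(graph$coords)
  stop_if(length(centers) == 0, "centers must be non-empty")
  stop_if(anyNA(centers) || any(centers < 1 | centers > n),
          "unknown center id")
  stop_if(!is_count(hops) || hops < 0, "hops must be a non-negative integer")
  hop <- rep(NA_integer_, n)
  hop[centers] <- 0L
  frontier <- unique(centers)
  h <- 0L
  while (h < hops && length(frontier) > 0) {
    nxt <- unique(unlist(graph$adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(hop[nxt])]
    hop[nxt] <- h + 1L
    frontier <- nxt
    h <- h + 1L
  }
  nodes <- which(!is.na(hop))
  loc <- match(seq_len(n), nodes)
  e <- graph$edges
  keep <- !is.na(loc[e[, 1]]) & !is.na(loc[e[, 2]])
  edges_local <- cbind(loc[e[keep, 1]], loc[e[keep, 2]])
  structure(list(centers = sort(unique(centers)), nodes = nodes,
                 hop_of = hop[nodes], edges = edges_local,
                 center_local = loc[sort(unique(centers))],
                 hops = as.integer(hops)),
            class = "subgraph")
}

#' @export
print.subgraph <- function(x, ...) {
  cat(sprintf("subgraph: %d centers, %d nodes within %d hops, %d edges\n",
              length(x$centers), length(x$nodes), x$hops, nrow(x$edges)))
  invisible(x)
}

#' Partition the slide into one epoch of center minibatches
#'
#' Permutes all nodes (uniform, without replacement) and splits them into
#' consecutive center sets of size `batch_size`, so that over one epoch every
#' node is a center exactly once; each set is expanded to its k-hop subgraph.
#' Deterministic under `seed`; pass `seed = NULL` to consume the current RNG
#' stream (as [train_model()] does across epochs).
#'
#' @param graph A `slide_graph`.
#' @param batch_size Number of centers per minibatch.
#' @param hops Subgraph radius.
#' @param seed Optional integer seed.
#' @return List of `subgraph` objects covering all nodes as centers.
#' @export
sample_training_batch <- function(graph, batch_size, hops = 2L, seed = NULL) {
  stop_if(!is_count(batch_size) || batch_size < 1,
          "batch_size must be a positive integer")
  n <- nrow(graph$coords)
  perm <- with_seed(seed, sample.int(n))
  starts <- seq(1L, n, by = as.integer(batch_size))
  lapply(starts, function(s) {
    centers <- perm[s:min(s + batch_size - 1L, n)]
    sample_subgraph(graph, centers, hops)
  })
}

#' Densify a spot lattice for super-resolved inference
#'
#' Returns sub-spot centers on a lattice with spacing `spacing / factor`
#' covering the bounding region of the original spots; the original
#' coordinates are a subset of the returned set. The grid spacing is inferred
#' as the modal nearest-neighbor distance (robust to edge spots) unless given
#' explicitly. Spot radius scales as `spot_radius_px / factor`, mirroring the
#' halving of the crop radius per 2x of resolution.
#'
#' @param coords n x 2 coordinate matrix or [spot_table()].
#' @param factor Densification factor: 1 (identity) or 2, 4, 8, 16.
#' @param spot_radius_px Original spot radius in pixels (default half the
#'   inferred spacing).
#' @param spacing Optional explicit lattice spacing override.
#' @return List with `spots` (a [spot_table()] of sub-spot centers),
#'   `spacing` (the dense spacing), `radius` (the dense spot radius).
#' @export
make_supergrid <- function(coords, factor, spot_radius_px = NULL,
                           spacing = NULL) {
  if (inherits(coords, "spot_table") || is.data.frame(coords)) {
    ids <- coords$spot_id
    coords <- cbind(coords$x_px, coords$y_px)
  } else {
    ids <- NULL
  }
  coords <- as.matrix(coords)
  stop_if(!factor %in% c(1L, 2L, 4L, 8L, 16L),
          "factor must be one of 1, 2, 4, 8, 16")
  if (is.null(spacing)) spacing <- infer_grid_spacing(coords)
  if (is.null(spot_radius_px)) spot_radius_px <- spacing / 2
  if (factor == 1L) {
    sp <- spot_table(if (is.null(ids)) sprintf("spot_%04d", seq_len(nrow(coords))) else ids,
                     coords[, 1], coords[, 2])
    return(list(spots = sp, spacing = spacing, radius = spot_radius_px))
  }
  ns <- spacing / factor
  anchor <- function(v) {
    # all coordinates must share one lattice phase modulo ns (circularly);
    # tolerance shrinks with the pitch so tiny inferred spacings still fail
    x0 <- v[1] %% ns
    dd <- abs(((v %% ns - x0 + ns / 2) %% ns) - ns / 2)
    stop_if(any(dd > min(0.5, ns / 4)),
            "coords do not sit on a lattice commensurate with spacing/",
            factor, "; pass an explicit `spacing`")
    x0
  }
  x0 <- anchor(coords[, 1]); y0 <- anchor(coords[, 2])
  lattice_axis <- function(v, phase) {
    start <- phase + ns * ceiling((min(v) - phase - 1e-9) / ns)
    seq(start, max(v) + 1e-9, by = ns)
  }
  g <- expand.grid(x = lattice_axis(coords[, 1], x0),
                   y = lattice_axis(coords[, 2], y0))
  sp <- spot_table(sprintf("sub_%05d", seq_len(nrow(g))), g$x, g$y)
  list(spots = sp, spacing = ns, radius = spot_radius_px / factor)
}

# Modal nearest-neighbor distance of a point set (0.1 px resolution).
infer_grid_spacing <- function(coords) {
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  tab <- table(round(nn, 1))
  as.numeric(names(tab)[which.max(tab)])
}

#' Dump a subgraph as JSON (debugging aid)
#' @param sg A `subgraph`.
#' @param path Output path.
#' @export
write_subgraph_json <- function(sg, path) {
  stop_if(!requireNamespace("jsonlite", quietly = TRUE),
          "writing JSON requires the 'jsonlite' package")
  jsonlite::write_json(list(centers = sg$centers, nodes = sg$nodes,
                            hop_of = sg$hop_of, hops = sg$hops,
                            edges = sg$edges),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' Export the edge list of a slide graph as CSV
#' @param graph A `slide_graph`.
#' @param path Output path; columns `src`, `dst` (node ids).
#' @export
write_edge_list <- function(graph, path) {
  df <- data.frame(src = graph$node_ids[graph$edges[, 1]],
                   dst = graph$node_ids[graph$edges[, 2]],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
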