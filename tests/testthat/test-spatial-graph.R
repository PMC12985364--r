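test_that("k-NN neighbor sets equal the brute-force all-pairs oracle", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    k <- sample(1:6, 1)
    coords <- matrix(runif(2 * n, 0, 100), n, 2)
    g <- build_knn_graph(coords, k)
    oracle <- oracle_knn_sets(coords, k)
    # union symmetrization: edge iff either endpoint selected the other
    expected <- matrix(0L, 0, 2)
    for (i in seq_len(n)) {
      for (j in oracle[[i]]) {
        expected <- rbind(expected, c(min(i, j), max(i, j)))
      }
    }
    expected <- unique(expected)
    expected <- expected[order(expected[, 1], expected[, 2]), , drop = FALSE]
    expect_equal(unname(g$edges), unname(expected))
  }
})

test_that("interior nodes of a Visium-style hex lattice have exactly 6 hex neighbors at k = 6", {
  sl <- make_test_slide(seed = 1, n_rows = 12, n_cols = 12)
  g <- build_knn_graph(sl$spots, 6)
  coords <- cbind(sl$spots$x_px, sl$spots$y_px)
  sp <- sl$config$spot_spacing_px
  # union symmetrization lets border spots (whose own 6-NN sets are not hex)
  # attach edges up to ~2.3 spacings inward, so "interior" starts beyond that
  interior <- which(coords[, 1] > min(coords[, 1]) + 2.6 * sp &
                      coords[, 1] < max(coords[, 1]) - 2.6 * sp &
                      coords[, 2] > min(coords[, 2]) + 2.6 * sp &
                      coords[, 2] < max(coords[, 2]) - 2.6 * sp)
  expect_gt(length(interior), 5)
  for (i in interior) {
    nb <- graph_neighbors(g, i)
    expect_length(nb, 6)
    d <- sqrt(rowSums((coords[nb, , drop = FALSE] -
                         matrix(coords[i, ], 6, 2, byrow = TRUE))^2))
    # 2 same-row neighbors at spacing, 4 diagonal at sqrt(1.25) * spacing
    expect_equal(sort(round(d / sp, 3)), c(1, 1, rep(1.118, 4)))
  }
})

test_that("two nodes with k = 1 give a single edge; degenerate sizes error or clamp", {
  g <- build_knn_graph(rbind(c(0, 0), c(1, 1)), 1)
  expect_equal(unname(g$edges), matrix(c(1L, 2L), 1))
  expect_error(build_knn_graph(rbind(c(0, 0)), 1), "at least 2")
  expect_warning(g2 <- build_knn_graph(matrix(runif(10), 5, 2), 7), "clamp")
  expect_equal(g2$k_neighbors, 4L)
})

test_that("graph symmetry: neighbor lookup is symmetric for all pairs", {
  set.seed(5)
  g <- build_knn_graph(matrix(runif(80), 40, 2), 3)
  for (i in seq_len(40)) {
    for (j in graph_neighbors(g, i)) {
      expect_true(i %in% graph_neighbors(g, j))
    }
  }
})

test_that("subgraph closure equals an independent BFS oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(15:50, 1)
    coords <- matrix(runif(2 * n), n, 2)
    g <- build_knn_graph(coords, 3)
    centers <- sample(n, sample(1:4, 1))
    hops <- sample(0:3, 1)
    sg <- sample_subgraph(g, centers, hops)
    oracle <- oracle_bfs_closure(n, g$edges, centers, hops)
    expect_equal(sg$nodes, oracle$nodes)
    expect_equal(sg$hop_of, unname(oracle$dist))
    # induced edges: every graph edge inside the closure, and nothing else
    inside <- g$edges[, 1] %in% oracle$nodes & g$edges[, 2] %in% oracle$nodes
    expect_equal(nrow(sg$edges), sum(inside))
    remapped <- cbind(oracle$nodes[sg$edges[, 1]], oracle$nodes[sg$edges[, 2]])
    expect_equal(unname(remapped),
                 unname(g$edges[inside, , drop = FALSE]))
  }
})

test_that("hops = 0 keeps exactly the centers with their induced edges", {
  g <- build_knn_graph(rbind(c(0, 0), c(1, 0), c(2, 0), c(10, 10)), 1)
  sg <- sample_subgraph(g, c(1, 2), 0)
  expect_equal(sg$nodes, c(1L, 2L))
  expect_equal(nrow(sg$edges), 1)
  # isolated single center: one node, no edges
  g1 <- new_slide_graph("a", rbind(c(0, 0), c(5, 5)), matrix(0L, 0, 2))
  sg1 <- sample_subgraph(g1, 1, 2)
  expect_equal(sg1$nodes, 1L)
  expect_equal(nrow(sg1$edges), 0)
  expect_error(sample_subgraph(g, 99, 1), "unknown")
})

test_that("subgraph closure is idempotent", {
  set.seed(33)
  g <- build_knn_graph(matrix(runif(60), 30, 2), 3)
  sg <- sample_subgraph(g, c(3, 14), 2)
  again <- sample_subgraph(g, sg$nodes, 0)
  expect_equal(again$nodes, sg$nodes)
})

test_that("one epoch of training batches partitions all nodes as centers", {
  set.seed(2)
  g <- build_knn_graph(matrix(runif(100), 50, 2), 4)
  batches <- sample_training_batch(g, 8, hops = 2, seed = 99)
  centers <- sort(unlist(lapply(batches, function(b) b$centers)))
  expect_equal(centers, 1:50)
  expect_equal(length(batches), ceiling(50 / 8))
  # full-slide batch
  one <- sample_training_batch(g, 50, hops = 1, seed = 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$centers, 1:50)
  # determinism under seed
  b2 <- sample_training_batch(g, 8, hops = 2, seed = 99)
  expect_identical(lapply(batches, `[[`, "centers"),
                   lapply(b2, `[[`, "centers"))
})

test_that("supergrid halves spacing, contains the original lattice, and counts match", {
  sl <- make_test_slide(seed = 6, n_rows = 6, n_cols = 6)
  sg <- make_supergrid(sl$spots, 2L)
  expect_equal(sg$spacing, sl$config$spot_spacing_px / 2)
  # all original coordinates appear in the dense set
  key_dense <- paste(round(sg$spots$x_px, 6), round(sg$spots$y_px, 6))
  key_orig <- paste(round(sl$spots$x_px, 6), round(sl$spots$y_px, 6))
  expect_true(all(key_orig %in% key_dense))

  # factor 4 on a square 10x10 grid: closed-form lattice count
  grid <- expand.grid(x = (0:9) * 50, y = (0:9) * 50)
  st <- spot_table(sprintf("g%03d", 1:100), grid$x, grid$y)
  sg4 <- make_supergrid(st, 4L)
  expect_equal(nrow(sg4$spots), (9 * 4 + 1)^2)
  expect_equal(sg4$spacing, 12.5)

  # factor 1 is the identity
  sg1 <- make_supergrid(st, 1L)
  expect_equal(sg1$spots$x_px, st$x_px)
  expect_equal(nrow(sg1$spots), 100)
})

test_that("non-lattice coordinates are rejected with a spacing hint", {
  set.seed(8)
  coords <- matrix(runif(40, 0, 100), 20, 2)
  expect_error(make_supergrid(coords, 2L), "spacing")
})
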