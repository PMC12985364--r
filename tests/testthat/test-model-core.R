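test_that("GATv2 layer matches a literal loop transcription on random graphs", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    d <- sample(2:5, 1)
    h <- matrix(rnorm(n * d), n, d)
    edges <- random_edges(n, 0.4)
    p <- random_gat_params(d)
    got <- gatv2_layer(h, edges, p)
    want <- oracle_gat_layer(h, edges, p$Wl, p$Wr, p$a)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("GAT attention collapses correctly for single or identical neighbors", {
  d <- 3
  set.seed(2)
  p <- random_gat_params(d)
  h <- matrix(rnorm(3 * d), 3, d)
  # node 1 has a single neighbor (node 2): alpha = 1, h' = elu(Wr h_2)
  out <- gatv2_layer(h, rbind(c(1, 2)), p, return_attention = TRUE)
  expect_equal(out$attention$alpha, c(1, 1))
  elu <- function(v) ifelse(v > 0, v, exp(v) - 1)
  expect_equal(out$h[1, ], elu(as.vector(h[2, ] %*% p$Wr)), tolerance = 1e-12)
  # two neighbors with identical features: alpha = (1/2, 1/2)
  h2 <- rbind(h[1, ], h[2, ], h[2, ])
  out2 <- gatv2_layer(h2, rbind(c(1, 2), c(1, 3)), p, return_attention = TRUE)
  a1 <- out2$attention$alpha[out2$attention$target == 1]
  expect_equal(a1, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("GAT attention rows sum to one on every forward pass", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    h <- matrix(rnorm(n * 4), n, 4)
    out <- gatv2_layer(h, random_edges(n, 0.5), random_gat_params(4),
                       return_attention = TRUE)
    if (nrow(out$attention) > 0) {
      sums <- tapply(out$attention$alpha, out$attention$target, sum)
      expect_true(all(abs(sums - 1) < 1e-6))
    }
  }
})

test_that("Transformer layer matches the loop oracle and its softmax rows sum to 1", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    n_heads <- sample(c(1, 2), 1)
    d <- n_heads * sample(2:3, 1)
    H <- matrix(rnorm(n * d), n, d)
    p <- random_tf_params(d)
    got <- transformer_layer(H, p, n_heads, return_attention = TRUE)
    want <- oracle_transformer_layer(H, p, n_heads)
    expect_equal(got$h, want, tolerance = 1e-6)
    for (A in got$attention) {
      expect_true(all(abs(rowSums(A) - 1) < 1e-6))
    }
  }
})

test_that("Transformer on one token reduces attention to its value projection", {
  set.seed(4)
  d <- 4
  p <- random_tf_params(d)
  H <- matrix(rnorm(d), 1, d)
  out <- transformer_layer(H, p, 2, return_attention = TRUE)
  for (A in out$attention) expect_equal(as.vector(A), 1)
  expect_error(transformer_layer(matrix(0, 0, 4), p, 2), "empty")
})

test_that("Transformer is permutation-equivariant (no positional encoding)", {
  set.seed(9)
  d <- 6
  H <- matrix(rnorm(5 * d), 5, d)
  p <- random_tf_params(d)
  out <- transformer_layer(H, p, 3)
  perm <- c(3, 1, 5, 2, 4)
  out_p <- transformer_layer(H[perm, ], p, 3)
  expect_equal(out_p, out[perm, ], tolerance = 1e-10)
})

test_that("fusion is the stated weighted sum and rejects all-zero weights", {
  set.seed(6)
  m <- make_tiny_model()
  I <- matrix(rnorm(4 * 8), 4, 8)
  G <- matrix(rnorm(4 * 8), 4, 8)
  Tr <- matrix(rnorm(4 * 8), 4, 8)
  hp <- m$params$head
  r1 <- fuse_and_predict(I, G, Tr, c(1, 0, 0), hp)
  expect_equal(r1$fused, I)
  r2 <- fuse_and_predict(I, G, Tr, c(1, 1, 1), hp)
  expect_equal(r2$fused, I + G + Tr, tolerance = 1e-12)
  expect_error(fuse_and_predict(I, G, Tr, c(0, 0, 0), hp), "non-zero")
  expect_error(fuse_and_predict(I[1:2, ], G, Tr, c(1, 1, 1), hp), "shape")
  expect_true(all(r2$prediction >= 0)) # softplus head
})

test_that("MSE matches a two-loop oracle and its closed cases", {
  set.seed(41)
  a <- matrix(rnorm(30), 5, 6)
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a + 1, a), 1)
  b <- matrix(rnorm(30), 5, 6)
  expect_equal(mse_loss(a, b), oracle_mse(a, b), tolerance = 1e-12)
  a[1, 1] <- NaN
  expect_error(mse_loss(a, b), "NaN")
})

test_that("patch encoding is deterministic and input-pure; plugin encoders pass through", {
  m <- make_tiny_model()
  set.seed(5)
  patches <- array(runif(3 * 8 * 8 * 3, 0, 255), dim = c(3, 8, 8, 3))
  patches[2, , , ] <- patches[1, , , ]
  e1 <- encode_patches(patches, m)
  expect_equal(e1[1, ], e1[2, ], tolerance = 0) # identical patches, identical rows
  expect_identical(e1, encode_patches(patches, m))
  zero_enc <- init_model(model_config(
    n_cell_types = 2, patch_size = 8,
    encoder = encoder_spec("plugin", d_emb = 4L,
                           fn = function(px) matrix(0, dim(px)[1], 4)),
    n_heads = 2, d_ff = 8, head_hidden = 6), seed = 1)
  expect_equal(encode_patches(patches, zero_enc), matrix(0, 3, 4))
  expect_error(encode_patches(array(0, dim = c(2, 16, 16, 3)), m), "size")
})

test_that("analytic gradients of the full model agree with central differences", {
  set.seed(42)
  m <- make_tiny_model()
  n <- 6
  patches <- array(runif(n * 8 * 8 * 3, 0, 255), dim = c(n, 8, 8, 3))
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 3)) # node 6 isolated
  y <- matrix(runif(n * 2), n, 2)
  fw <- spotglass:::model_fwd(m, patches, edges, need_cache = TRUE)
  d_pred <- 2 * (fw$prediction - y) / length(y)
  grads <- spotglass:::model_bwd(m, fw$cache, d_pred)
  gv <- spotglass:::tree_flatten(grads)
  pv <- spotglass:::tree_flatten(m$params)
  idx <- sort(sample(length(pv), 80))
  num <- vapply(idx, function(k) {
    h <- 1e-5
    mp <- m
    v <- pv; v[k] <- v[k] + h
    mp$params <- spotglass:::tree_unflatten(m$params, v)
    lp <- mse_loss(spotglass:::model_fwd(mp, patches, edges)$prediction, y)
    v[k] <- pv[k] - h
    mp$params <- spotglass:::tree_unflatten(m$params, v)
    lm <- mse_loss(spotglass:::model_fwd(mp, patches, edges)$prediction, y)
    (lp - lm) / (2 * h)
  }, numeric(1))
  denom <- pmax(abs(num) + abs(gv[idx]), 1e-6)
  expect_lt(max(abs(num - gv[idx]) / denom), 1e-3)
})
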