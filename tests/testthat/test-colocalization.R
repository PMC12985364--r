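test_that("RBF weights: kernel, zero diagonal, and sum-to-n normalization", {
  set.seed(51)
  coords <- matrix(runif(40, 0, 10), 20, 2)
  w <- rbf_spatial_weights(coords, 1.5)
  expect_equal(sum(w$w), 20, tolerance = 1e-10)
  expect_true(all(diag(w$w) == 0))
  expect_equal(w$w, t(w$w), tolerance = 1e-12)
  expect_equal(w$w, oracle_rbf_weights(coords, 1.5), tolerance = 1e-12)
  # coincident points: pre-normalization off-diagonal weight is exp(0) = 1
  cdup <- rbind(c(0, 0), c(0, 0), c(3, 3))
  d2 <- as.matrix(dist(cdup))^2
  w0 <- exp(-d2 / (2 * 1^2)); diag(w0) <- 0
  expect_equal(w0[1, 2], 1)
  w2 <- rbf_spatial_weights(cdup, 1)
  expect_equal(sum(w2$w), 3, tolerance = 1e-12)
  expect_error(rbf_spatial_weights(coords, -1), "positive")
})

test_that("bivariate Moran's R matches the loop oracle and its closed cases", {
  # hand case: x = (1,-1), y = (-1,1), w12 = w21 = 1 -> R = 1
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(bivariate_moran_R(c(1, -1), c(-1, 1), w), 1)
  set.seed(52)
  for (rep in 1:10) {
    n <- 30
    coords <- matrix(runif(2 * n, 0, 5), n, 2)
    w <- rbf_spatial_weights(coords, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(bivariate_moran_R(x, y, w), oracle_moran_R(x, y, w$w),
                 tolerance = 1e-12)
    # symmetry under symmetric weights
    expect_equal(bivariate_moran_R(x, y, w), bivariate_moran_R(y, x, w),
                 tolerance = 1e-12)
    # collapse to univariate Moran's I
    expect_equal(bivariate_moran_R(x, x, w), univariate_moran_I(x, w),
                 tolerance = 1e-12)
    # affine invariance (shift + positive scale of either argument)
    expect_equal(bivariate_moran_R(2.5 * x + 3, y, w),
                 bivariate_moran_R(x, 0.2 * y - 7, w), tolerance = 1e-10)
    # empirical bound on normalized symmetric weights
    expect_lte(abs(bivariate_moran_R(x, y, w)), 1 + 1e-12)
  }
  expect_error(bivariate_moran_R(rep(1, 5), rnorm(5),
                                 rbf_spatial_weights(matrix(runif(10), 5, 2), 1)),
               "constant")
})

test_that("Moran's I signs: checkerboards negative, gradients positive", {
  grid <- expand.grid(x = 0:5, y = 0:5)
  # rook adjacency weights
  d <- as.matrix(dist(grid))
  w <- (abs(d - 1) < 1e-9) * 1
  checker <- (-1)^(grid$x + grid$y)
  expect_lt(univariate_moran_I(checker, w), 0)
  gradient <- grid$x + grid$y
  expect_gt(univariate_moran_I(gradient, w), 0)
})

test_that("univariate Moran's I agrees with ape's implementation", {
  set.seed(53)
  coords <- matrix(runif(60, 0, 8), 30, 2)
  x <- rnorm(30)
  w <- rbf_spatial_weights(coords, 2)
  # ape row-normalizes the weight matrix internally; feed our statistic the
  # same row-normalized matrix for an apples-to-apples comparison
  w_row <- w$w / rowSums(w$w)
  got <- univariate_moran_I(x, w_row)
  want <- ape::Moran.I(x, w$w, scaled = FALSE)$observed
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("colocalization matrix: diagonal is Moran's I, constant columns skipped", {
  sl <- make_test_slide(seed = 18, types = 4)
  w <- rbf_spatial_weights(sl$spots)
  cm <- colocalization_matrix(sl$abundance, w)
  expect_equal(unname(diag(cm)),
               vapply(seq_len(ncol(sl$abundance)), function(j) {
                 univariate_moran_I(sl$abundance[, j], w)
               }, numeric(1)), tolerance = 1e-12)
  expect_equal(unclass(cm), t(unclass(cm)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(cm) <= 1 + 1e-12))
  ab2 <- cbind(sl$abundance, flat = rep(1, nrow(sl$abundance)))
  expect_warning(cm2 <- colocalization_matrix(ab2, w), "constant")
  expect_equal(dim(cm2), c(4, 4))
})

test_that("colocalization comparison: self gives (1,1), negation gives (-1,-1)", {
  sl <- make_test_slide(seed = 19, types = 4)
  w <- rbf_spatial_weights(sl$spots)
  cm <- colocalization_matrix(sl$abundance, w)
  self <- compare_colocalization(cm, cm)
  expect_equal(self$cosine, 1, tolerance = 1e-12)
  expect_equal(self$pearson, 1, tolerance = 1e-12)
  neg <- cm; neg[] <- -cm
  flipped <- compare_colocalization(cm, neg)
  expect_equal(flipped$cosine, -1, tolerance = 1e-12)
  expect_equal(flipped$pearson, -1, tolerance = 1e-12)
  # direct vector-algebra oracle on the upper triangles
  sl2 <- make_test_slide(seed = 20, types = 4)
  cmB <- colocalization_matrix(sl2$abundance, rbf_spatial_weights(sl2$spots))
  got <- compare_colocalization(cm, cmB)
  va <- cm[upper.tri(cm)]; vb <- cmB[upper.tri(cmB)]
  expect_equal(got$cosine, sum(va * vb) / sqrt(sum(va^2) * sum(vb^2)),
               tolerance = 1e-12)
  expect_equal(got$pearson, oracle_pearson(va, vb), tolerance = 1e-12)
  bad <- cmB
  dimnames(bad) <- list(letters[1:4], letters[1:4])
  expect_error(compare_colocalization(cm, bad), "names")
})

test_that("consensus colocalization averages and counts high-R pairs", {
  mats <- lapply(1:5, function(s) {
    sl <- make_test_slide(seed = s + 30, types = 3)
    colocalization_matrix(sl$abundance, rbf_spatial_weights(sl$spots))
  })
  cons <- consensus_colocalization(mats, high_R_threshold = 0.2)
  expect_equal(cons$mean, Reduce(`+`, lapply(mats, unclass)) / 5,
               tolerance = 1e-12, ignore_attr = TRUE)
  # loop oracle for the count matrix
  cnt <- matrix(0L, 3, 3)
  for (m in mats) {
    for (i in 1:3) for (j in 1:3) if (m[i, j] > 0.2) cnt[i, j] <- cnt[i, j] + 1L
  }
  expect_equal(unname(unclass(cons$count)), cnt)
  one <- consensus_colocalization(mats[1])
  expect_equal(one$mean, unclass(mats[[1]]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(one$count %in% c(0L, 1L)))
  # two slides with R and -R average to zero
  neg <- mats[[1]]; neg[] <- -unclass(mats[[1]])
  zero <- consensus_colocalization(list(mats[[1]], neg))
  expect_equal(max(abs(zero$mean)), 0, tolerance = 1e-12)
  expect_error(consensus_colocalization(list()), "empty")
})
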