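# Independent brute-force oracles: literal transcriptions of the defining
# formulas with explicit loops, deliberately sharing no code with the package.

oracle_gat_layer <- function(h, edges, Wl, Wr, a, slope = 0.2) {
  n <- nrow(h)
  nbrs <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      nbrs[[i]] <- c(nbrs[[i]], j)
      nbrs[[j]] <- c(nbrs[[j]], i)
    }
  }
  lrelu <- function(v) ifelse(v > 0, v, slope * v)
  elu <- function(v) ifelse(v > 0, v, exp(v) - 1)
  out <- matrix(0, n, ncol(Wr))
  for (i in seq_len(n)) {
    Ni <- sort(unique(nbrs[[i]]))
    if (length(Ni) == 0) {
      out[i, ] <- elu(as.vector(h[i, ] %*% Wr))
      next
    }
    scores <- sapply(Ni, function(j) {
      sum(a * lrelu(as.vector(h[i, ] %*% Wl) + as.vector(h[j, ] %*% Wr)))
    })
    alpha <- exp(scores - max(scores))
    alpha <- alpha / sum(alpha)
    agg <- numeric(ncol(Wr))
    for (k in seq_along(Ni)) {
      agg <- agg + alpha[k] * as.vector(h[Ni[k], ] %*% Wr)
    }
    out[i, ] <- elu(agg)
  }
  out
}

oracle_transformer_layer <- function(H, p, n_heads) {
  n <- nrow(H); d <- ncol(H)
  dk <- d / n_heads
  layernorm <- function(x, gamma, beta, eps = 1e-5) {
    t(apply(x, 1, function(r) {
      gamma * (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) + beta
    }))
  }
  Q <- H %*% p$Wq; K <- H %*% p$Wk; V <- H %*% p$Wv
  O <- matrix(0, n, d)
  for (h in seq_len(n_heads)) {
    ix <- ((h - 1) * dk + 1):(h * dk)
    for (i in seq_len(n)) {
      s <- sapply(seq_len(n), function(j) {
        sum(Q[i, ix] * K[j, ix]) / sqrt(dk)
      })
      al <- exp(s - max(s)); al <- al / sum(al)
      for (j in seq_len(n)) O[i, ix] <- O[i, ix] + al[j] * V[j, ix]
    }
  }
  Z <- layernorm(H + O %*% p$Wo, p$ln1$gamma, p$ln1$beta)
  ff <- pmax(sweep(Z %*% p$ff1$W, 2, p$ff1$b, "+"), 0)
  FF <- sweep(ff %*% p$ff2$W, 2, p$ff2$b, "+")
  layernorm(Z + FF, p$ln2$gamma, p$ln2$beta)
}

oracle_moran_R <- function(x, y, w) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (x[i] - xb) * (y[j] - yb)
    }
  }
  num / (sqrt(sum((x - xb)^2)) * sqrt(sum((y - yb)^2)))
}

oracle_rbf_weights <- function(coords, l) {
  n <- nrow(coords)
  w0 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        d2 <- sum((coords[i, ] - coords[j, ])^2)
        w0[i, j] <- exp(-d2 / (2 * l^2))
      }
    }
  }
  n * w0 / sum(w0)
}

oracle_knn_sets <- function(coords, k) {
  n <- nrow(coords)
  lapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    sort(ord[seq_len(k)])
  })
}

oracle_bfs_closure <- function(n, edges, centers, hops) {
  nbrs <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    nbrs[[i]] <- c(nbrs[[i]], j)
    nbrs[[j]] <- c(nbrs[[j]], i)
  }
  dist <- rep(Inf, n)
  dist[centers] <- 0
  queue <- centers
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (dist[v] >= hops) next
    for (u in nbrs[[v]]) {
      if (dist[u] > dist[v] + 1) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  list(nodes = which(is.finite(dist)), dist = dist[is.finite(dist)])
}

oracle_cindex <- function(scores, times, censor) {
  num <- 0; den <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (times[i] < times[j] && censor[i] == 0) {
        den <- den + 1
        if (scores[i] < scores[j]) num <- num + 1
        else if (scores[i] == scores[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

oracle_jsd_bits <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  term <- function(a) {
    s <- 0
    for (k in seq_along(a)) if (a[k] > 0) s <- s + a[k] * log2(a[k] / m[k])
    s
  }
  term(p) / 2 + term(q) / 2
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sum((x - xb) * (y - yb)) /
    (sqrt(sum((x - xb)^2)) * sqrt(sum((y - yb)^2)))
}

oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) s <- s + (a[i, j] - b[i, j])^2
  }
  s / (nrow(a) * ncol(a))
}

# product-limit estimator at observed event times, no ties assumed handled
oracle_km <- function(times, events) {
  o <- order(times)
  times <- times[o]; events <- events[o]
  at_risk <- length(times)
  surv <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      surv <- surv * (1 - 1 / at_risk)
      out <- rbind(out, data.frame(time = times[i], surv = surv))
    }
    at_risk <- at_risk - 1
  }
  out
}

# random GAT / transformer parameter sets at width d
random_gat_params <- function(d, dprime = d) {
  list(Wl = matrix(rnorm(d * dprime), d, dprime),
       Wr = matrix(rnorm(d * dprime), d, dprime),
       a = rnorm(dprime))
}

random_tf_params <- function(d, d_ff = 2 * d) {
  list(Wq = matrix(rnorm(d * d, sd = 0.5), d, d),
       Wk = matrix(rnorm(d * d, sd = 0.5), d, d),
       Wv = matrix(rnorm(d * d, sd = 0.5), d, d),
       Wo = matrix(rnorm(d * d, sd = 0.5), d, d),
       ln1 = list(gamma = runif(d, 0.5, 1.5), beta = rnorm(d, sd = 0.1)),
       ln2 = list(gamma = runif(d, 0.5, 1.5), beta = rnorm(d, sd = 0.1)),
       ff1 = list(W = matrix(rnorm(d * d_ff, sd = 0.5), d, d_ff), b = rnorm(d_ff, sd = 0.1)),
       ff2 = list(W = matrix(rnorm(d_ff * d, sd = 0.5), d_ff, d), b = rnorm(d, sd = 0.1)))
}

# random connected-ish undirected edge list on n nodes
random_edges <- function(n, p = 0.3) {
  e <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(e)) < p
  e[keep, , drop = FALSE]
}

# small synthetic slide shared across tests
make_test_slide <- function(seed = 1, n_rows = 6, n_cols = 6, types = 3,
                            noise = 0, smooth = 2, patch = 16) {
  generate_synthetic_slide(synthetic_slide_config(
    n_rows = n_rows, n_cols = n_cols, patch_size_px = patch,
    spot_spacing_px = patch, n_cell_types = types,
    field_smoothness = smooth, noise_sd = noise, seed = seed))
}

# tiny model for fast structural tests
make_tiny_model <- function(types = 2, patch = 8, seed = 7) {
  init_model(model_config(
    n_cell_types = types, patch_size = patch,
    encoder = encoder_spec("small_cnn", d_emb = 8L, conv_channels = c(4L, 6L)),
    n_gat_layers = 2L, n_tf_layers = 2L, n_heads = 2L, d_ff = 12L,
    head_hidden = 10L), seed = seed)
}
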