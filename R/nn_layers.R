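# Vectorized neural-network primitives with analytic backward passes.
#
# All layers are pure functions: forward returns list(out, cache); backward
# takes (cache, d_out) and returns the input gradient plus parameter
# gradients. Parameters live in plain named lists of numeric arrays, so the
# whole model is an ordinary R object and gradient checking against central
# differences is straightforward (see the test suite).

## ---- activations ------------------------------------------------------

act_relu <- function(x) list(out = pmax(x, 0), cache = x)
act_relu_bwd <- function(cache, d) d * (cache > 0)

act_elu <- function(x) {
  out <- x
  neg <- which(x <= 0)
  out[neg] <- exp(x[neg]) - 1
  list(out = out, cache = x)
}
act_elu_bwd <- function(cache, d) {
  g <- d
  neg <- which(cache <= 0)
  g[neg] <- g[neg] * exp(cache[neg])
  g
}

act_leakyrelu <- function(x, slope) {
  out <- x
  neg <- which(x < 0)
  out[neg] <- slope * x[neg]
  list(out = out, cache = x)
}
act_leakyrelu_bwd <- function(cache, d, slope) {
  g <- d
  neg <- which(cache < 0)
  g[neg] <- g[neg] * slope
  g
}

act_softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- log1p(exp(pmin(x, 30)))
  big <- which(x > 30)
  out[big] <- x[big]
  list(out = out, cache = x)
}
act_softplus_bwd <- function(cache, d) d * stats::plogis(cache)

# in-place-style bias add over columns (cheaper than sweep for tall matrices)
add_bias <- function(y, b) {
  for (j in seq_along(b)) if (b[j] != 0) y[, j] <- y[, j] + b[j]
  y
}

row_softmax <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}
# dS given A = row_softmax(S) and upstream dA
row_softmax_bwd <- function(A, dA) A * (dA - rowSums(dA * A))

## ---- dense layer ------------------------------------------------------

init_linear <- function(d_in, d_out, gain = 2) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(gain / d_in)),
                  d_in, d_out),
       b = numeric(d_out))
}

linear_fwd <- function(x, p) {
  out <- add_bias(x %*% p$W, p$b)
  list(out = out, cache = list(x = x, p = p))
}

linear_bwd <- function(cache, d) {
  list(dx = d %*% t(cache$p$W),
       grads = list(W = crossprod(cache$x, d), b = colSums(d)))
}

## ---- 2-D convolution (flattened channels-last layout) -----------------

# Activations are (P * n) x C matrices: row (p, img) with spatial position p
# (column-major over the H x W grid) fastest, one column per channel. This
# layout makes a convolution a set of k^2 row gathers plus one matmul and
# needs no transposes anywhere in the stack.
#
# `idx_sp[q, p_out]` maps kernel spatial offset q = (ky, kx) and output
# position p_out to the 1-based input position.
conv_meta <- function(H, W, C, k, stride) {
  oh <- (H - k) %/% stride + 1L
  ow <- (W - k) %/% stride + 1L
  stop_if(oh < 1 || ow < 1, "patch too small for this conv layer")
  ky <- rep(0:(k - 1), times = k)
  kx <- rep(0:(k - 1), each = k)
  oy <- rep(0:(oh - 1), times = ow)
  ox <- rep(0:(ow - 1), each = oh)
  idx_sp <- outer(ky, oy * stride, "+") + outer(kx * H, ox * stride * H, "+") + 1L
  list(idx_sp = idx_sp, H = H, W = W, C = C, k = k, stride = stride,
       oh = oh, ow = ow, kk = k * k, kkc = k * k * C, P = oh * ow,
       P_in = H * W, pointwise = (k == 1L && stride == 1L))
}

init_conv <- function(meta, c_out) {
  # weight rows ordered (spatial offset q, channel c), c fastest within q
  list(W = matrix(stats::rnorm(meta$kkc * c_out, sd = sqrt(2 / meta$kkc)),
                  meta$kkc, c_out),
       b = numeric(c_out))
}

# row indices of the gather for offset q, for a batch of n images
conv_rows <- function(meta, q, n) {
  rep(meta$idx_sp[q, ], times = n) +
    rep((0:(n - 1)) * meta$P_in, each = meta$P)
}

conv_fwd <- function(x, p, meta, n) {
  rows_q <- NULL
  if (meta$pointwise) {
    cols <- x
  } else {
    rows_q <- lapply(seq_len(meta$kk), function(q) conv_rows(meta, q, n))
    cols <- matrix(0, meta$P * n, meta$kkc)
    for (q in seq_len(meta$kk)) {
      cols[, ((q - 1) * meta$C + 1):(q * meta$C)] <-
        x[rows_q[[q]], , drop = FALSE]
    }
  }
  y <- add_bias(cols %*% p$W, p$b)
  list(out = y,
       cache = list(cols = cols, p = p, meta = meta, n = n, rows_q = rows_q))
}

conv_bwd <- function(cache, d_out) {
  meta <- cache$meta
  n <- cache$n
  dW <- crossprod(cache$cols, d_out)
  db <- colSums(d_out)
  dcols <- d_out %*% t(cache$p$W)
  if (meta$pointwise) {
    return(list(dx = dcols, grads = list(W = dW, b = db)))
  }
  dx <- matrix(0, meta$P_in * n, meta$C)
  for (q in seq_len(meta$kk)) {
    rows <- cache$rows_q[[q]]
    # for a fixed kernel offset the p -> pixel map is injective
    dx[rows, ] <- dx[rows, ] +
      dcols[, ((q - 1) * meta$C + 1):(q * meta$C), drop = FALSE]
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

# global mean pool over spatial positions: x is (P * n) x C
global_pool_fwd <- function(x, P, C, n) {
  grp <- rep(seq_len(n), each = P)
  list(out = rowsum(x, grp, reorder = FALSE) / P,
       cache = list(P = P, C = C, n = n, grp = grp))
}
global_pool_bwd <- function(cache, d) {
  d[cache$grp, , drop = FALSE] / cache$P
}

## ---- layer normalization ---------------------------------------------

layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv, p = p))
}

layernorm_bwd <- function(cache, d) {
  xhat <- cache$xhat
  gamma <- cache$p$gamma
  dgamma <- colSums(d * xhat)
  dbeta <- colSums(d)
  dxhat <- sweep(d, 2, gamma, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

init_layernorm <- function(d) list(gamma = rep(1, d), beta = numeric(d))

## ---- parameter-tree utilities ----------------------------------------

# Apply f leaf-wise over parallel nested lists of arrays.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(x, y, f), a, b)
    return(out)
  }
  f(a, b)
}

tree_map <- function(a, f) {
  if (is.list(a)) return(lapply(a, tree_map, f))
  f(a)
}

tree_zeros_like <- function(a) tree_map(a, function(x) { x[] <- 0; x })

`%||%` <- function(x, y) if (is.null(x)) y else x

# Flatten a parameter tree to a single numeric vector and back (used by the
# gradient checker and checkpoint round-trips).
tree_flatten <- function(a) {
  if (is.list(a)) return(unlist(lapply(a, tree_flatten), use.names = FALSE))
  as.numeric(a)
}

tree_unflatten <- function(template, v) {
  pos <- 0L
  rec <- function(a) {
    if (is.list(a)) return(lapply(a, rec))
    n <- length(a)
    out <- a
    out[] <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  rec(template)
}

## ---- Adam optimizer ---------------------------------------------------

adam_state <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / c1) / (sqrt(v / c2) + eps)
  })
  params <- tree_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
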