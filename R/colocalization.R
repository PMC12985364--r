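#' RBF spatial weights for Moran statistics
#'
#' Off-diagonal weights are a Gaussian kernel of the inter-spot Euclidean
#' distance, `w0_ij = exp(-d_ij^2 / (2 l^2))`; the diagonal is zeroed
#' (standard Moran practice) and the matrix is normalized element-wise so
#' that its total sum equals the number of spots:
#' `w_ij = (n / W) w0_ij` with `W = sum(w0)`.
#'
#' @param coords n x 2 coordinate matrix or [spot_table()].
#' @param length_scale Kernel length scale `l` (> 0), in coordinate units.
#'   `NULL` (default) uses 1.2 x the modal nearest-neighbor distance.
#' @return A `spatial_weights` object: `w` (n x n, symmetric, zero diagonal,
#'   `sum(w) == n`), `length_scale`, `normalized = TRUE`.
#' @export
rbf_spatial_weights <- function(coords, length_scale = NULL) {
  if (inherits(coords, "spot_table") || is.data.frame(coords)) {
    coords <- cbind(coords$x_px, coords$y_px)
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stop_if(n < 2, "need at least 2 spots")
  if (is.null(length_scale)) length_scale <- 1.2 * infer_grid_spacing(coords)
  stop_if(!is.numeric(length_scale) || length_scale <= 0,
          "length_scale must be positive")
  d2 <- unname(as.matrix(stats::dist(coords)))^2
  w0 <- exp(-d2 / (2 * length_scale^2))
  diag(w0) <- 0
  w <- n * w0 / sum(w0)
  structure(list(w = w, length_scale = length_scale, normalized = TRUE),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d spots, l = %.3g, sum(w) = %.6g\n",
              nrow(x$w), x$length_scale, sum(x$w)))
  invisible(x)
}

as_weight_matrix <- function(weights) {
  if (inherits(weights, "spatial_weights")) return(weights$w)
  as.matrix(weights)
}

#' Bivariate Moran's R between two spatial fields
#'
#' The spatial cross-correlation
#' `R = sum_ij w_ij (x_i - xbar)(y_j - ybar) /
#'  (sqrt(sum_i (x_i - xbar)^2) * sqrt(sum_i (y_i - ybar)^2))`.
#' With `y = x` and weights normalized so `sum(w) = n`, it collapses to the
#' univariate Moran's I. Values lie in \[-1, 1\] for normalized symmetric
#' weights; the statistic is invariant to positive affine rescaling of
#' either field.
#'
#' @param x,y Equal-length numeric vectors (each non-constant).
#' @param weights A [rbf_spatial_weights()] result or plain n x n matrix.
#' @return Scalar Moran's R.
#' @export
bivariate_moran_R <- function(x, y, weights) {
  w <- as_weight_matrix(weights)
  n <- length(x)
  stop_if(length(y) != n || nrow(w) != n, "x, y and weights sizes disagree")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  stop_if(sx == 0 || sy == 0,
          "Moran's R undefined for a constant field (zero denominator)")
  as.numeric(xc %*% w %*% yc) / (sx * sy)
}

#' Univariate Moran's I (spatial autocorrelation)
#'
#' Standard Moran's I, `(n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2` with `W` the total weight sum. Under the element-wise
#' normalization of [rbf_spatial_weights()] this equals
#' `bivariate_moran_R(x, x, weights)`.
#'
#' @param x Non-constant numeric vector.
#' @param weights Spatial weights (any non-negative matrix accepted).
#' @return Scalar Moran's I.
#' @export
univariate_moran_I <- function(x, weights) {
  w <- as_weight_matrix(weights)
  n <- length(x)
  stop_if(nrow(w) != n, "x and weights sizes disagree")
  xc <- x - mean(x)
  s2 <- sum(xc^2)
  stop_if(s2 == 0, "Moran's I undefined for a constant field")
  (n / sum(w)) * as.numeric(xc %*% w %*% xc) / s2
}

#' Cell-type colocalization matrix
#'
#' `R[s, t]` is the bivariate Moran's R between the abundance maps of cell
#' types `s` and `t`; the diagonal is each type's univariate Moran's I.
#' Constant abundance columns cannot be scored and are excluded with a
#' warning rather than failing the slide.
#'
#' @param abundance Spots x cell-types matrix with colnames.
#' @param weights Spatial weights over the same spots.
#' @return A `colocalization_matrix`: square symmetric matrix of Moran's R
#'   with cell-type dimnames.
#' @export
colocalization_matrix <- function(abundance, weights) {
  abundance <- as.matrix(abundance)
  stop_if(ncol(abundance) < 2, "need at least 2 cell types")
  w <- as_weight_matrix(weights)
  usable <- apply(abundance, 2, function(v) stats::sd(v) > 0)
  if (any(!usable)) {
    warning("skipping constant cell-type column(s): ",
            paste(colnames(abundance)[!usable], collapse = ", "))
  }
  a <- abundance[, usable, drop = FALSE]
  k <- ncol(a)
  xc <- sweep(a, 2, colMeans(a))
  den <- sqrt(colSums(xc^2))
  num <- t(xc) %*% w %*% xc
  R <- num / (den %o% den)
  dimnames(R) <- list(colnames(a), colnames(a))
  structure(R, class = c("colocalization_matrix", "matrix"))
}

#' Compare two colocalization matrices
#'
#' Flattens the upper triangles (diagonal excluded) of both matrices and
#' returns the cosine similarity and Pearson correlation between the two
#' vectors — the agreement summary used to compare predicted against
#' ground-truth colocalization structure.
#'
#' @param A,B `colocalization_matrix` objects over identical cell types.
#' @return Named list `cosine`, `pearson`.
#' @export
compare_colocalization <- function(A, B) {
  stop_if(!identical(dimnames(A), dimnames(B)),
          "cell-type names of A and B do not match")
  va <- A[upper.tri(A)]
  vb <- B[upper.tri(B)]
  stop_if(length(va) < 2, "need at least 3 shared cell types to compare")
  list(cosine = sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2))),
       pearson = stats::cor(va, vb))
}

#' Consensus colocalization across slides
#'
#' Element-wise mean of per-slide colocalization matrices plus, for each
#' cell-type pair, the number of slides in which Moran's R exceeds
#' `high_R_threshold` (default 0.20) — the support count used to call
#' consistently colocalized pairs.
#'
#' @param per_slide Non-empty list of `colocalization_matrix` objects sharing
#'   cell-type names.
#' @param high_R_threshold Threshold defining a "high" Moran's R.
#' @return List with `mean` (matrix) and `count` (integer matrix).
#' @export
consensus_colocalization <- function(per_slide, high_R_threshold = 0.20) {
  stop_if(length(per_slide) == 0, "empty slide list")
  dn <- dimnames(per_slide[[1]])
  for (m in per_slide) {
    stop_if(!identical(dimnames(m), dn), "cell-type names differ across slides")
  }
  mean_m <- Reduce(`+`, lapply(per_slide, unclass)) / length(per_slide)
  count_m <- Reduce(`+`, lapply(per_slide, function(m) {
    (unclass(m) > high_R_threshold) * 1L
  }))
  storage.mode(count_m) <- "integer"
  list(mean = mean_m, count = count_m)
}
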