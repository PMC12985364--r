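#' Per-cell-type Pearson correlation between predicted and true abundance
#'
#' One correlation per cell type, computed across spots. Constant columns
#' (zero variance in either matrix) yield `NA` with a warning rather than an
#' error, and are excluded from `mean_pearson` summaries downstream.
#'
#' @param pred,truth Spots x cell-types matrices, aligned by dimension (and
#'   by dimnames when both are named).
#' @return Named numeric vector of Pearson correlations (may contain NA for
#'   degenerate columns).
#' @export
per_celltype_pearson <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  stop_if(!all(dim(pred) == dim(truth)), "pred and truth shapes disagree")
  stop_if(nrow(pred) < 3, "need at least 3 spots")
  if (!is.null(colnames(pred)) && !is.null(colnames(truth))) {
    stop_if(!identical(colnames(pred), colnames(truth)),
            "cell-type names of pred and truth do not match")
  }
  out <- vapply(seq_len(ncol(pred)), function(j) {
    if (stats::sd(pred[, j]) == 0 || stats::sd(truth[, j]) == 0) {
      return(NA_real_)
    }
    stats::cor(pred[, j], truth[, j])
  }, numeric(1))
  names(out) <- colnames(truth)
  if (anyNA(out)) warning("constant column(s) yield undefined correlations")
  out
}

#' Jensen-Shannon divergence between two spatial abundance maps
#'
#' Each non-negative map is normalized to a probability distribution over
#' spots; the divergence `JSD = KL(p||m)/2 + KL(q||m)/2` with `m = (p+q)/2`
#' and the convention `0 log 0 = 0` is reported in bits (base 2), so it is
#' symmetric and bounded by 1.
#'
#' @param p_map,q_map Equal-length non-negative vectors with positive sums.
#' @return Scalar JSD in bits, in \[0, 1\].
#' @export
jensen_shannon_divergence <- function(p_map, q_map) {
  stop_if(length(p_map) != length(q_map), "maps differ in length")
  stop_if(any(p_map < 0) || any(q_map < 0), "maps must be non-negative")
  sp <- sum(p_map); sq <- sum(q_map)
  stop_if(sp <= 0 || sq <= 0, "all-zero map: JSD undefined")
  p <- p_map / sp
  q <- q_map / sq
  m <- (p + q) / 2
  kl <- function(a, b) {
    ix <- a > 0
    sum(a[ix] * log2(a[ix] / b[ix]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Per-cell-type JSD between predicted and true abundance maps
#'
#' @inheritParams per_celltype_pearson
#' @return Named vector of JSD values in bits (NA for all-zero columns).
#' @export
per_celltype_jsd <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  stop_if(!all(dim(pred) == dim(truth)), "pred and truth shapes disagree")
  out <- vapply(seq_len(ncol(pred)), function(j) {
    if (sum(pred[, j]) <= 0 || sum(truth[, j]) <= 0) return(NA_real_)
    jensen_shannon_divergence(pred[, j], truth[, j])
  }, numeric(1))
  names(out) <- colnames(truth)
  out
}

#' Relate spatial autocorrelation of cell types to prediction accuracy
#'
#' Computes the univariate Moran's I of each ground-truth abundance column
#' and pairs it with that cell type's prediction Pearson correlation; the
#' summary correlation between the two quantifies whether spatially variable
#' cell types are predicted more accurately.
#'
#' @param truth Spots x cell-types ground-truth matrix.
#' @param pearson Named per-type Pearson vector (from
#'   [per_celltype_pearson()]).
#' @param weights Spatial weights over the spots.
#' @return List with `table` (data.frame `cell_type`, `moran_I`, `pearson`)
#'   and `correlation` (Pearson between the two columns; NA with a warning
#'   when degenerate).
#' @export
moran_vs_performance <- function(truth, pearson, weights) {
  truth <- as.matrix(truth)
  usable <- apply(truth, 2, function(v) stats::sd(v) > 0) & !is.na(pearson)
  stop_if(sum(usable) < 3, "need at least 3 usable cell types")
  mi <- vapply(which(usable), function(j) {
    univariate_moran_I(truth[, j], weights)
  }, numeric(1))
  tab <- data.frame(cell_type = colnames(truth)[usable], moran_I = mi,
                    pearson = pearson[usable], stringsAsFactors = FALSE,
                    row.names = NULL)
  rho <- if (stats::sd(tab$moran_I) == 0 || stats::sd(tab$pearson) == 0) {
    warning("degenerate inputs: correlation undefined")
    NA_real_
  } else {
    stats::cor(tab$moran_I, tab$pearson)
  }
  list(table = tab, correlation = rho)
}

#' Evaluate a predicted abundance map against ground truth
#'
#' Convenience wrapper producing the standard evaluation report:
#' per-cell-type Pearson and JSD, their means over defined entries, and the
#' Moran's-I-versus-performance table when spatial weights are supplied.
#'
#' @inheritParams per_celltype_pearson
#' @param weights Optional spatial weights for the Moran analysis.
#' @return An `eval_report` list: `per_type_pearson`, `per_type_jsd`
#'   (bits), `mean_pearson`, `mean_jsd`, optionally `moran_vs_pearson`.
#' @export
evaluate_predictions <- function(pred, truth, weights = NULL) {
  pearson <- per_celltype_pearson(pred, truth)
  jsd <- per_celltype_jsd(pred, truth)
  out <- list(per_type_pearson = pearson, per_type_jsd = jsd,
              mean_pearson = mean(pearson, na.rm = TRUE),
              mean_jsd = mean(jsd, na.rm = TRUE), jsd_unit = "bits")
  if (!is.null(weights)) {
    out$moran_vs_pearson <- moran_vs_performance(truth, pearson, weights)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: mean Pearson %.3f, mean JSD %.3f bits over %d cell types\n",
              x$mean_pearson, x$mean_jsd, length(x$per_type_pearson)))
  invisible(x)
}
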