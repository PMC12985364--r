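# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}

# Segment sum: rows of `m` (or elements of a vector) accumulated by integer
# group index `idx` into an `n`-row result, absent groups zero.
segment_sum <- function(m, idx, n) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  rs <- rowsum(m, idx)
  out <- matrix(0, n, ncol(m))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Full-precision numeric CSV writer: plain write.csv truncates doubles at 15
# significant digits; tables here must round-trip at 1e-12 or better.
write_csv_full <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
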