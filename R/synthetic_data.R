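#' Configuration for a synthetic slide
#'
#' Describes a synthetic spatial-transcriptomics slide: a grid of spots, a set
#' of spatially autocorrelated latent abundance fields (one per cell type), and
#' an image whose local texture deterministically encodes those abundances.
#' Synthetic slides stand in for Visium/ST data so that the whole
#' histology-to-abundance pipeline is exercisable without downloads; they do
#' not attempt realistic H&E nucleus or stain texture.
#'
#' @param n_rows,n_cols Number of spot rows/columns on the grid.
#' @param grid `"hex"` (every other row offset by half a spacing, so 6-NN
#'   reproduces Visium adjacency) or `"square"` (pairs with k = 8).
#' @param spot_spacing_px Center-to-center spot distance in pixels.
#' @param patch_size_px Side of the square patch centered on each spot
#'   (>= 8 px). Exact abundance decoding requires
#'   `patch_size_px <= spot_spacing_px` (disjoint stipple tiles).
#' @param n_cell_types Number of cell types (abundance columns).
#' @param field_smoothness Gaussian-blur length scale of the latent abundance
#'   fields, in spot units; larger values give higher spatial autocorrelation.
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise, on the
#'   normalized \[0,1\] intensity scale (applied as `255 * noise_sd`).
#' @param seed Integer RNG seed; identical seeds give bit-identical slides.
#' @return An object of class `synthetic_slide_config`.
#' @export
synthetic_slide_config <- function(n_rows = 20L, n_cols = 20L,
                                   grid = c("hex", "square"),
                                   spot_spacing_px = 32, patch_size_px = 32L,
                                   n_cell_types = 8L, field_smoothness = 2,
                                   noise_sd = 0.05, seed = 1L) {
  grid <- match.arg(grid)
  stop_if(!is_count(n_rows) || !is_count(n_cols) || n_rows < 1 || n_cols < 1,
          "n_rows and n_cols must be positive integers")
  stop_if(!is.numeric(spot_spacing_px) || spot_spacing_px <= 0,
          "spot_spacing_px must be positive")
  stop_if(!is_count(patch_size_px) || patch_size_px < 8,
          "patch_size_px must be an integer >= 8")
  stop_if(!is_count(n_cell_types) || n_cell_types < 1,
          "n_cell_types must be a positive integer")
  stop_if(!is.numeric(field_smoothness) || field_smoothness <= 0,
          "field_smoothness must be positive")
  stop_if(!is.numeric(noise_sd) || noise_sd < 0, "noise_sd must be >= 0")
  # stipple budget: each type can occupy at most abund_cap * px_per_unit pixels
  abund_cap <- 2
  px_per_unit <- max(1L, floor(patch_size_px^2 / (2.5 * n_cell_types)))
  stop_if(n_cell_types * abund_cap * px_per_unit > patch_size_px^2,
          "patch_size_px too small for n_cell_types (stipple budget exceeded)")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 grid = grid, spot_spacing_px = spot_spacing_px,
                 patch_size_px = as.integer(patch_size_px),
                 n_cell_types = as.integer(n_cell_types),
                 field_smoothness = field_smoothness, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 abund_cap = abund_cap, px_per_unit = px_per_unit),
            class = "synthetic_slide_config")
}

# Separable Gaussian blur on a matrix, kernel renormalized at the borders.
gaussian_smooth_2d <- function(m, sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-r, r), sd = sd)
  k <- k / sum(k)
  smooth_1d <- function(mat) {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    wsum <- numeric(n)
    for (o in seq(-r, r)) {
      w <- k[o + r + 1L]
      src <- seq_len(n) + o
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + w * mat[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + w
    }
    out / wsum
  }
  t(smooth_1d(t(smooth_1d(m))))
}

# Distinct saturated RGB colors (3 x T), all with channel mean < 220 so
# stipples always count as tissue under the background rule.
celltype_colors <- function(n) {
  grDevices::col2rgb(grDevices::hsv(h = (seq_len(n) - 1) / n, s = 1, v = 1))
}

#' Generate a synthetic slide
#'
#' Latent per-type abundance fields are white noise on the spot grid smoothed
#' with a Gaussian kernel of width `field_smoothness` (spot units),
#' standardized, rectified to non-negative and capped at 2. Each spot's patch
#' encodes its abundance vector as pixel stipples: cell type `t` is assigned a
#' fixed saturated color and `round(abundance * px_per_unit)` pixels of that
#' color, placed at fixed in-tile positions shared by all slides of a given
#' patch size (the morphology-to-abundance encoding is slide-invariant, as
#' the prediction task presumes), on an otherwise tissue-pink canvas. Abundance is quantized to the stipple resolution, so
#' with `noise_sd = 0` the abundance vector is exactly recoverable from the
#' patch (see [decode_patch_abundance()]). Gaussian pixel noise is then added
#' to the whole canvas and patches are cropped from it, so patches and canvas
#' stay mutually consistent.
#'
#' @param config A [synthetic_slide_config()].
#' @return An object of class `synthetic_slide` with elements
#'   `spots` (data.frame: `spot_id`, `x_px`, `y_px`; 0-based pixel coordinates,
#'   x = column, y = row), `patches` (n_spots x s x s x 3 array, values in
#'   \[0,255\]), `abundance` (n_spots x n_cell_types matrix, ground truth),
#'   `canvas` (H x W x 3 slide raster), `render_map` (the abundance-to-pixel
#'   encoding: colors, px_per_unit, background color) and `config`.
#' @export
generate_synthetic_slide <- function(config) {
  stop_if(!inherits(config, "synthetic_slide_config"),
          "config must be a synthetic_slide_config")
  cfg <- config
  with_seed(cfg$seed, {
    s <- cfg$patch_size_px
    sp <- cfg$spot_spacing_px
    half <- floor(s / 2)
    nr <- cfg$n_rows; nc <- cfg$n_cols; Tt <- cfg$n_cell_types
    n <- nr * nc

    row_i <- rep(seq_len(nr) - 1L, each = nc)
    col_j <- rep(seq_len(nc) - 1L, times = nr)
    x <- col_j * sp + half
    if (cfg$grid == "hex") x <- x + (row_i %% 2L) * sp / 2
    y <- row_i * sp + half
    spot_id <- sprintf("spot_%04d", seq_len(n))

    # latent fields on the (nr x nc) grid, one per type
    abund <- matrix(0, n, Tt)
    for (t in seq_len(Tt)) {
      z <- gaussian_smooth_2d(matrix(stats::rnorm(nr * nc), nr, nc),
                              cfg$field_smoothness)
      z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
      a <- pmin(pmax(z, 0), cfg$abund_cap)
      # quantize to stipple resolution so decoding is exact
      a <- round(a * cfg$px_per_unit) / cfg$px_per_unit
      # a is (nr x nc); spots are ordered row-major (col fastest)
      abund[, t] <- as.vector(t(a))
    }
    colnames(abund) <- sprintf("type_%02d", seq_len(Tt))
    rownames(abund) <- spot_id

    cols <- celltype_colors(Tt)
    bg <- c(230, 200, 215) # tissue-pink, channel mean < 220
    H <- nr * sp
    W <- nc * sp + if (cfg$grid == "hex") sp / 2 else 0
    H <- as.integer(ceiling(H)); W <- as.integer(ceiling(W))
    canvas <- array(rep(bg, each = H * W), dim = c(H, W, 3))

    npix <- s * s
    counts <- matrix(as.integer(round(abund * cfg$px_per_unit)), n, Tt)
    # one fixed pixel permutation shared by every slide of a given patch
    # size: patch content is then a deterministic function of the spot's
    # abundance vector alone (equal abundances render identical patches,
    # across slides too, mirroring a slide-invariant morphology-to-abundance
    # relationship), and stipples never overlap
    perm <- with_seed(7341L, sample.int(npix))
    for (i in seq_len(n)) {
      r0 <- as.integer(round(y[i])) - half # 0-based top row of tile
      c0 <- as.integer(round(x[i])) - half
      total <- sum(counts[i, ])
      if (total == 0L) next
      pos <- perm[seq_len(total)]
      offset <- 0L
      for (t in seq_len(Tt)) {
        ct <- counts[i, t]
        if (ct == 0L) next
        p <- pos[(offset + 1L):(offset + ct)] - 1L
        offset <- offset + ct
        py <- r0 + p %% s
        px <- c0 + p %/% s
        for (ch in 1:3) canvas[cbind(py + 1L, px + 1L, ch)] <- cols[ch, t]
      }
    }

    if (cfg$noise_sd > 0) {
      canvas <- canvas + stats::rnorm(length(canvas), sd = 255 * cfg$noise_sd)
      canvas <- pmin(pmax(canvas, 0), 255)
    }

    patches <- array(0, dim = c(n, s, s, 3))
    for (i in seq_len(n)) {
      r0 <- as.integer(round(y[i])) - half
      c0 <- as.integer(round(x[i])) - half
      patches[i, , , ] <- canvas[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), ]
    }

    structure(list(
      spots = data.frame(spot_id = spot_id, x_px = x, y_px = y,
                         stringsAsFactors = FALSE),
      patches = patches,
      abundance = abund,
      canvas = canvas,
      render_map = list(encoding = "stipple", colors = cols,
                        px_per_unit = cfg$px_per_unit, background = bg,
                        patch_size = s),
      config = cfg
    ), class = "synthetic_slide")
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "synthetic_slide: %d spots (%dx%d %s grid), %d cell types, %dpx patches\n",
    nrow(x$spots), cfg$n_rows, cfg$n_cols, cfg$grid, cfg$n_cell_types,
    cfg$patch_size_px))
  invisible(x)
}

#' Decode a spot's abundance vector from its rendered patch
#'
#' Inverts the stipple encoding by counting pixels that exactly match each
#' cell type's color. Exact for patches generated with `noise_sd = 0`.
#'
#' @param patch s x s x 3 array in \[0,255\].
#' @param render_map The `render_map` element of a [generate_synthetic_slide()]
#'   result.
#' @return Numeric vector of abundances, one per cell type.
#' @export
decode_patch_abundance <- function(patch, render_map) {
  cols <- render_map$colors
  vapply(seq_len(ncol(cols)), function(t) {
    hit <- patch[, , 1] == cols[1, t] & patch[, , 2] == cols[2, t] &
      patch[, , 3] == cols[3, t]
    sum(hit) / render_map$px_per_unit
  }, numeric(1))
}

#' Write a synthetic slide to disk
#'
#' Writes one PNG per patch (`patches/<spot_id>.png`), the whole-slide canvas
#' (`slide.png`), a spots CSV (`spot_id`, `x_px`, `y_px`) and an abundance CSV
#' (`spot_id` plus one column per cell type). PNG encoding quantizes pixel
#' values to 8 bits.
#'
#' @param slide A `synthetic_slide`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_slide <- function(slide, dir) {
  stop_if(!inherits(slide, "synthetic_slide"), "not a synthetic_slide")
  dir.create(file.path(dir, "patches"), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(slide$canvas / 255, file.path(dir, "slide.png"))
  for (i in seq_len(nrow(slide$spots))) {
    png::writePNG(slide$patches[i, , , ] / 255,
                  file.path(dir, "patches",
                            paste0(slide$spots$spot_id[i], ".png")))
  }
  write_spot_table(slide$spots, file.path(dir, "spots.csv"))
  write_abundance_csv(slide$abundance, file.path(dir, "abundance.csv"))
  invisible(dir)
}

#' Generate a synthetic survival cohort
#'
#' Subject features are i.i.d. standard normal; event times are exponential
#' with rate `exp(features %*% true_weights)` (proportional hazards, so larger
#' linear risk means shorter survival). A `censor_frac` fraction of subjects
#' draws an independent Exp(1) censoring time; a subject is censored
#' (`censor = 1`) when that time precedes the event, and the observed time is
#' the minimum of the two.
#'
#' @param n Number of subjects.
#' @param n_features Number of slide-level features.
#' @param true_weights Length-`n_features` log-hazard weights.
#' @param censor_frac Fraction of subjects exposed to censoring, in \[0,1\].
#' @param seed Integer RNG seed.
#' @return An object of class `survival_cohort`: `subject_id`, `features`
#'   (n x p matrix), `time` (observed, > 0), `censor` (1 = survives beyond
#'   follow-up, 0 = event observed) and `true_risk` (the generating linear
#'   predictor, kept for benchmarking).
#' @export
generate_survival_cohort <- function(n, n_features, true_weights,
                                     censor_frac = 0, seed = 1L) {
  stop_if(!is_count(n) || n < 1, "n must be a positive integer")
  stop_if(length(true_weights) != n_features,
          "true_weights must have length n_features")
  stop_if(!is.numeric(censor_frac) || censor_frac < 0 || censor_frac > 1,
          "censor_frac must be in [0,1]")
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * n_features), n, n_features,
                dimnames = list(NULL, sprintf("feature_%d", seq_len(n_features))))
    risk <- as.vector(X %*% true_weights)
    t_event <- stats::rexp(n, rate = exp(risk))
    exposed <- stats::runif(n) < censor_frac
    t_cens <- stats::rexp(n, rate = 1)
    censor <- as.integer(exposed & t_cens < t_event)
    time <- ifelse(censor == 1L, t_cens, t_event)
    structure(list(subject_id = sprintf("subj_%05d", seq_len(n)),
                   features = X, time = time, censor = censor,
                   true_risk = risk, true_weights = true_weights),
              class = "survival_cohort")
  })
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d subjects, %d features, %.1f%% censored\n",
              length(x$time), ncol(x$features), 100 * mean(x$censor)))
  invisible(x)
}

#' Write a survival cohort as CSV
#'
#' Columns: `subject_id`, `feature_1..k`, `time`, `censor`.
#' @param cohort A `survival_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_cohort <- function(cohort, path) {
  df <- data.frame(subject_id = cohort$subject_id, cohort$features,
                   time = cohort$time, censor = cohort$censor,
                   stringsAsFactors = FALSE)
  write_csv_full(df, path)
}

#' Read a survival cohort CSV
#' @param path CSV written by [write_survival_cohort()] (or any CSV with
#'   `subject_id`, `feature_*`, `time`, `censor` columns).
#' @return A `survival_cohort` (without generating-model metadata).
#' @export
read_survival_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feat <- grep("^feature_", names(df), value = TRUE)
  stop_if(length(feat) == 0 || !all(c("subject_id", "time", "censor") %in% names(df)),
          "cohort CSV needs subject_id, feature_*, time, censor columns")
  structure(list(subject_id = as.character(df$subject_id),
                 features = as.matrix(df[feat]),
                 time = df$time, censor = as.integer(df$censor),
                 true_risk = NULL, true_weights = NULL),
            class = "survival_cohort")
}
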