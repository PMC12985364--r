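#' Read a slide raster (PNG or TIFF)
#'
#' Returns an H x W x 3 array with values in \[0,255\]. Grayscale images are
#' expanded to three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return H x W x 3 numeric array.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      stop_if(!requireNamespace("tiff", quietly = TRUE),
              "reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported slide format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Construct / validate a spot table
#'
#' A spot table holds one row per capture spot: a unique `spot_id` and the
#' spot center's pixel coordinates. Coordinates are 0-based with `x_px` the
#' column and `y_px` the row of the slide raster.
#'
#' @param spot_id Character vector of unique ids.
#' @param x_px,y_px Finite pixel coordinates.
#' @return A `data.frame` of class `spot_table`.
#' @export
spot_table <- function(spot_id, x_px, y_px) {
  stop_if(anyDuplicated(spot_id) > 0, "spot ids must be unique")
  stop_if(!all(is.finite(x_px)) || !all(is.finite(y_px)),
          "spot coordinates must be finite")
  stop_if(length(spot_id) != length(x_px) || length(x_px) != length(y_px),
          "spot_id, x_px, y_px must have equal length")
  structure(data.frame(spot_id = as.character(spot_id), x_px = x_px,
                       y_px = y_px, stringsAsFactors = FALSE),
            class = c("spot_table", "data.frame"))
}

#' @rdname spot_table
#' @param path CSV path with columns `spot_id`, `x_px`, `y_px`.
#' @export
read_spot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("spot_id", "x_px", "y_px") %in% names(df)),
          "spots CSV needs columns spot_id, x_px, y_px")
  spot_table(df$spot_id, df$x_px, df$y_px)
}

#' @rdname spot_table
#' @param spots A spot table to write.
#' @export
write_spot_table <- function(spots, path) {
  write_csv_full(as.data.frame(spots)[c("spot_id", "x_px", "y_px")], path)
}

#' Read / write a spot x cell-type abundance matrix as CSV
#'
#' The CSV has a `spot_id` column followed by one numeric column per cell
#' type. Values are written at full double precision, so a write/read
#' round-trip is lossless to better than 1e-12.
#'
#' @param path CSV path.
#' @return `read_abundance_csv`: a numeric matrix with spot ids as rownames
#'   and cell-type names as colnames.
#' @export
read_abundance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stop_if(names(df)[1] != "spot_id", "abundance CSV must start with spot_id")
  m <- as.matrix(df[-1])
  rownames(m) <- df$spot_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_abundance_csv
#' @param abundance Numeric matrix (spots x cell types) with dimnames.
#' @export
write_abundance_csv <- function(abundance, path) {
  stop_if(is.null(rownames(abundance)) || is.null(colnames(abundance)),
          "abundance matrix needs spot rownames and cell-type colnames")
  df <- data.frame(spot_id = rownames(abundance), abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv_full(df, path)
}

#' Crop spot-centered patches from a slide image
#'
#' Patch `i` covers the axis-aligned square of side `patch_size` centered on
#' spot `i`: per axis, the half-open 0-based pixel window
#' `[c - floor(s/2), c - floor(s/2) + s)` where `c` is the (half-to-even
#' rounded) spot center. Spots whose window leaves the image raise an error
#' listing the offending ids unless `pad = TRUE`, in which case out-of-image
#' pixels are filled with `pad_value`.
#'
#' @param image H x W x 3 array in \[0,255\] (see [read_slide_image()]).
#' @param spots A [spot_table()].
#' @param patch_size Patch side in pixels (default 224).
#' @param pad Enable edge padding.
#' @param pad_value Fill value for padded pixels.
#' @param source_slide Identifier stored with the stack.
#' @return A `patch_stack`: list with `pixels` (n x s x s x 3 array),
#'   `spot_id`, `patch_size`, `source_slide`.
#' @export
crop_patches <- function(image, spots, patch_size = 224L, pad = FALSE,
                         pad_value = 255, source_slide = "slide") {
  stop_if(length(dim(image)) != 3L, "image must be an H x W x 3 array")
  s <- as.integer(patch_size)
  stop_if(s < 1, "patch_size must be positive")
  H <- dim(image)[1]; W <- dim(image)[2]
  half <- s %/% 2L
  cx <- round(spots$x_px); cy <- round(spots$y_px) # round half to even
  r0 <- as.integer(cy) - half # 0-based first row
  c0 <- as.integer(cx) - half
  out_of_image <- r0 < 0L | c0 < 0L | (r0 + s) > H | (c0 + s) > W
  if (any(out_of_image) && !pad) {
    stop("spots outside image (enable pad = TRUE): ",
         paste(spots$spot_id[out_of_image], collapse = ", "), call. = FALSE)
  }
  n <- nrow(spots)
  px <- array(pad_value, dim = c(n, s, s, 3))
  for (i in seq_len(n)) {
    rr <- (r0[i] + 1L):(r0[i] + s)
    cc <- (c0[i] + 1L):(c0[i] + s)
    rok <- rr >= 1L & rr <= H
    cok <- cc >= 1L & cc <= W
    if (any(rok) && any(cok)) {
      px[i, rok, cok, ] <- image[rr[rok], cc[cok], , drop = FALSE]
    }
  }
  structure(list(pixels = px, spot_id = spots$spot_id, patch_size = s,
                 source_slide = source_slide),
            class = "patch_stack")
}

#' @export
print.patch_stack <- function(x, ...) {
  cat(sprintf("patch_stack: %d patches of %dx%d px (source: %s)\n",
              dim(x$pixels)[1], x$patch_size, x$patch_size, x$source_slide))
  invisible(x)
}

#' Background classification of pixels and patches
#'
#' A pixel counts as background when its channel mean is >= 220 (a color close
#' to white); a patch is kept when its background fraction does not exceed
#' `max_bg_frac`, i.e. it is discarded only when the fraction strictly
#' exceeds the threshold.
#'
#' @param rgb Length-3 vector or n x 3 matrix of RGB values in \[0,255\].
#' @return `is_background_pixel`: logical; `patch_background_fraction`: a
#'   fraction in \[0,1\]; `keep_patch`: logical.
#' @export
is_background_pixel <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  rowMeans(rgb) >= 220
}

#' @rdname is_background_pixel
#' @param patch s x s x 3 array in \[0,255\].
#' @export
patch_background_fraction <- function(patch) {
  mean((patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3 >= 220)
}

#' @rdname is_background_pixel
#' @param max_bg_frac Maximum tolerated background fraction (default 0.75).
#' @export
keep_patch <- function(patch, max_bg_frac = 0.75) {
  patch_background_fraction(patch) <= max_bg_frac
}

#' Filter a patch stack and decide slide admissibility
#'
#' Applies [keep_patch()] per patch and flags the slide as rejected when
#' fewer than `min_valid` patches survive.
#'
#' @param patches A `patch_stack`.
#' @param max_bg_frac Per-patch background tolerance.
#' @param min_valid Minimum number of valid patches for the slide (default
#'   100).
#' @return List with `patches` (the kept `patch_stack`), `kept` (logical per
#'   input patch), `n_valid`, and `rejected` (TRUE when `n_valid < min_valid`).
#' @export
filter_slide <- function(patches, max_bg_frac = 0.75, min_valid = 100L) {
  stop_if(!inherits(patches, "patch_stack"), "patches must be a patch_stack")
  n <- dim(patches$pixels)[1]
  kept <- vapply(seq_len(n), function(i) {
    keep_patch(patches$pixels[i, , , ], max_bg_frac)
  }, logical(1))
  out <- patches
  out$pixels <- patches$pixels[kept, , , , drop = FALSE]
  out$spot_id <- patches$spot_id[kept]
  list(patches = out, kept = kept, n_valid = sum(kept),
       rejected = sum(kept) < min_valid)
}

#' Match a patch's color statistics to a reference patch
#'
#' A structure-preserving but deliberately simple color normalizer: each
#' channel is mapped to log intensity space `log(I + 1)`, standardized, and
#' rescaled to the reference channel's log-space mean and standard deviation.
#' Output channel means/SDs match the reference exactly in that working space
#' (before the final clamp to \[0,255\]). A zero-variance source channel
#' cannot be rescaled; it is mapped, with a warning, to a constant at the
#' reference channel's working-space mean. Alternative normalizers can be
#' substituted anywhere a patch-to-patch function is accepted.
#'
#' @param patch,reference_patch s x s x 3 arrays in \[0,255\].
#' @return Normalized patch, same shape, values in \[0,255\].
#' @export
normalize_color <- function(patch, reference_patch) {
  out <- patch
  for (ch in 1:3) {
    src <- log(patch[, , ch] + 1)
    ref <- log(reference_patch[, , ch] + 1)
    s_sd <- stats::sd(as.vector(src))
    if (!is.finite(s_sd) || s_sd < 1e-12) {
      warning("zero-variance source channel ", ch,
              "; mapping to reference mean")
      mapped <- array(mean(ref), dim = dim(src))
    } else {
      mapped <- (src - mean(src)) / s_sd * stats::sd(as.vector(ref)) + mean(ref)
    }
    out[, , ch] <- pmin(pmax(exp(mapped) - 1, 0), 255)
  }
  out
}
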