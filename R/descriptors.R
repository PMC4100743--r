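# Per-patch appearance descriptors: local binary patterns, intensity and LBP
# histograms, the 512-dimensional intensity+texture descriptor, per-dimension
# min-max normalization, and the chi-squared histogram distance.

#' LBP code map of a grayscale raster
#'
#' The basic 8-point local binary pattern: every pixel with a complete 3 x 3
#' neighbourhood receives an 8-bit code built by thresholding its eight
#' neighbours against the centre value. A neighbour greater than *or equal to*
#' the centre contributes a 1 bit; bits are ordered clockwise starting from the
#' top-left neighbour, most significant bit first, so a constant image codes to
#' 255 everywhere. Border pixels carry no code (`NA`).
#'
#' Codes are computed on the full face and then histogrammed per patch; this
#' avoids artificial texture edges at patch borders.
#'
#' @param img Grayscale matrix, at least 3 x 3.
#' @return Integer matrix of the same size; interior pixels hold codes in
#'   0..255, the one-pixel border is `NA`.
#' @export
lbp_code_map <- function(img) {
  if (inherits(img, "normalized_face")) img <- img$pixels
  if (!is.matrix(img) || nrow(img) < 3L || ncol(img) < 3L)
    stop_invalid("LBP needs a grayscale raster of at least 3 x 3")
  h <- nrow(img); w <- ncol(img)
  ri <- 2:(h - 1L); ci <- 2:(w - 1L)
  centre <- img[ri, ci, drop = FALSE]
  # clockwise from top-left: TL, T, TR, R, BR, B, BL, L ; MSB first
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
               c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  codes <- matrix(0L, h - 2L, w - 2L)
  bit <- 128L
  for (o in offs) {
    nb <- img[ri + o[1], ci + o[2], drop = FALSE]
    codes <- codes + bit * (nb >= centre)
    bit <- bit %/% 2L
  }
  out <- matrix(NA_integer_, h, w)
  out[ri, ci] <- as.integer(codes)
  out
}

#' 256-bin LBP histogram of the codes inside a patch
#'
#' @param codes Integer code map from [lbp_code_map()] (full-face).
#' @param rows,cols 1-based pixel index ranges of the patch within the face,
#'   e.g. from the grid geometry; `NA` codes (border pixels) are ignored.
#' @return Numeric length-256 count vector (bin k holds the count of code
#'   k-1).
#' @export
lbp_histogram <- function(codes, rows = seq_len(nrow(codes)),
                          cols = seq_len(ncol(codes))) {
  sub <- codes[rows, cols, drop = FALSE]
  v <- sub[!is.na(sub)]
  if (length(v) == 0L) {
    warning("patch contains no LBP codes; returning all-zero histogram")
    return(numeric(256))
  }
  tabulate(v + 1L, nbins = 256L)
}

#' 256-bin intensity histogram of a patch
#'
#' @param patch Patch list (from [tessellate()]) or a raster matrix with 8-bit
#'   values.
#' @return Numeric length-256 count vector (bin k holds the count of pixels
#'   rounding to value k-1).
#' @export
intensity_histogram <- function(patch) {
  px <- if (is.list(patch)) patch$pixels else patch
  check_raster8(px, "patch")
  tabulate(as.integer(round(px)) + 1L, nbins = 256L)
}

#' Intensity + texture descriptor of a patch
#'
#' Concatenates the patch's 256-bin intensity histogram and its 256-bin LBP
#' histogram into a 512-vector; each block is L1-normalized (sums to 1) before
#' concatenation so the descriptor is independent of patch pixel count, and
#' per-dimension min-max scaling over a training set is applied afterwards via
#' [minmax_fit()]/[minmax_apply()].
#'
#' @param patch Patch list with `row_index`, `col_index`, `pixels` (from
#'   [tessellate()]).
#' @param codes Full-face LBP code map covering this patch.
#' @param grid The [patch_grid()] the patch indices refer to.
#' @return Numeric length-512 vector: intensity block (1..256) then LBP block
#'   (257..512).
#' @export
ite_descriptor <- function(patch, codes, grid = patch_grid()) {
  b <- patch_bounds(grid, patch$row_index, patch$col_index)
  hi <- intensity_histogram(patch)
  hl <- lbp_histogram(codes, b$rows, b$cols)
  c(l1_normalize(hi), l1_normalize(hl))
}

l1_normalize <- function(h) {
  s <- sum(h)
  if (s > 0) h / s else h
}

#' Min-max normalization over a training descriptor set
#'
#' `minmax_fit` records per-dimension minima and maxima of the training
#' descriptors; `minmax_apply` maps each dimension through
#' `(x - min) / (max - min)` and clamps to \[0, 1\]. Dimensions constant on
#' the training set map to 0.
#'
#' @param x Numeric matrix of training descriptors (rows = patches).
#' @return `minmax_fit`: a `minmax_model` with vectors `min` and `max`.
#' @rdname minmax
#' @export
minmax_fit <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (nrow(x) < 1L) stop_invalid("minmax_fit needs at least one descriptor")
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "minmax_model")
}

#' @param model A `minmax_model`.
#' @param d Descriptor vector or matrix (rows = descriptors) to rescale.
#' @return `minmax_apply`: rescaled descriptor(s), all values in \[0, 1\].
#' @rdname minmax
#' @export
minmax_apply <- function(model, d) {
  rng <- model$max - model$min
  scale_one <- function(v) {
    out <- ifelse(rng > 0, (v - model$min) / rng, 0)
    clamp01(out)
  }
  if (is.matrix(d)) t(apply(d, 1, scale_one)) else scale_one(d)
}

#' Chi-squared histogram distance
#'
#' `sum((h1 - h2)^2 / (h1 + h2 + eps))` with `eps = 1e-10` guarding empty
#' bins. Symmetric, non-negative, zero iff the histograms are identical.
#'
#' @param h1,h2 Equal-length non-negative numeric vectors.
#' @param eps Denominator guard.
#' @return Non-negative scalar.
#' @export
chi2_distance <- function(h1, h2, eps = 1e-10) {
  if (length(h1) != length(h2))
    stop_invalid("chi2_distance: histogram lengths differ (",
                 length(h1), " vs ", length(h2), ")")
  sum((h1 - h2)^2 / (h1 + h2 + eps))
}

#' All per-patch ITE descriptors of one face
#'
#' @param face `normalized_face` or canonical raster.
#' @param grid The [patch_grid()].
#' @param per_patch If `TRUE`, LBP codes are computed inside each patch in
#'   isolation instead of on the full face (sensitivity-check mode; the
#'   default full-face computation avoids artificial patch-border texture).
#' @return Numeric (m*n) x 512 matrix, patches in row-major order.
#' @export
face_descriptors <- function(face, grid = patch_grid(), per_patch = FALSE) {
  px <- if (inherits(face, "normalized_face")) face$pixels else face
  patches <- tessellate(px, grid)
  ite <- matrix(0, length(patches), 512L)
  if (per_patch) {
    for (k in seq_along(patches)) {
      p <- patches[[k]]
      pc <- lbp_code_map(p$pixels)
      ite[k, ] <- c(l1_normalize(intensity_histogram(p)),
                    l1_normalize(lbp_histogram(pc)))
    }
  } else {
    codes <- lbp_code_map(px)
    for (k in seq_along(patches))
      ite[k, ] <- ite_descriptor(patches[[k]], codes, grid)
  }
  ite
}
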