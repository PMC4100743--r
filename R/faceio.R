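# Image input/output, face normalization, and patch-grid tessellation.
#
# Images are numeric matrices of 8-bit values in [0, 255]; row i is the i-th
# raster line from the top, column j the j-th pixel from the left. Colour
# images are height x width x 3 arrays. Continuous coordinates used for eye
# positions are 0-based (x, y) with x growing rightwards and y downwards, so
# pixel [i, j] has its centre at (x = j - 1, y = i - 1).

#' Patch-grid geometry
#'
#' Describes the non-overlapping rectangular tessellation of a normalized
#' face: `m` patch rows by `n` patch columns of `patch_width` x `patch_height`
#' pixels. The canonical face raster is therefore
#' `n * patch_width` wide and `m * patch_height` tall. The default 5 x 5 grid
#' of 26 x 30 patches gives a 130 x 150 face.
#'
#' @param m Number of patch rows (vertical patch count).
#' @param n Number of patch columns (horizontal patch count).
#' @param patch_width Patch width in pixels.
#' @param patch_height Patch height in pixels.
#' @return An object of class `patch_grid` with fields `m`, `n`,
#'   `patch_width`, `patch_height`, `face_width`, `face_height`.
#' @export
#' @examples
#' g <- patch_grid()
#' g$face_width  # 130
#' g$face_height # 150
patch_grid <- function(m = 5L, n = 5L, patch_width = 26L, patch_height = 30L) {
  m <- as.integer(m); n <- as.integer(n)
  patch_width <- as.integer(patch_width); patch_height <- as.integer(patch_height)
  if (m < 1L || n < 1L || patch_width < 1L || patch_height < 1L)
    stop_invalid("patch_grid dimensions must be positive")
  structure(list(m = m, n = n,
                 patch_width = patch_width, patch_height = patch_height,
                 face_width = n * patch_width, face_height = m * patch_height),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("patch_grid: %d x %d patches of %d x %d px (face %d x %d)\n",
              x$m, x$n, x$patch_width, x$patch_height,
              x$face_width, x$face_height))
  invisible(x)
}

#' Convert an image to grayscale
#'
#' Colour rasters (height x width x 3) are reduced with the ITU-R BT.601 luma
#' weights (0.299, 0.587, 0.114); grayscale matrices pass through unchanged.
#'
#' @param img Numeric matrix or height x width x 3 array, values in \[0, 255\].
#' @return Numeric matrix of the same height/width, values in \[0, 255\].
#' @export
to_grayscale <- function(img) {
  check_raster8(img, "image")
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L && dim(img)[3] == 3L) {
    w <- c(0.299, 0.587, 0.114)
    return(img[, , 1] * w[1] + img[, , 2] * w[2] + img[, , 3] * w[3])
  }
  stop_invalid("image must be a matrix or a height x width x 3 array")
}

canonical_eye_positions <- function(grid) {
  # eyes at 30% / 70% of the width, 30% of the height (within the eye band of
  # the default 5-row grid)
  w <- grid$face_width; h <- grid$face_height
  list(left = c(x = 0.3 * w, y = 0.3 * h),
       right = c(x = 0.7 * w, y = 0.3 * h))
}

#' Geometrically normalize a face by its eye coordinates
#'
#' Applies the similarity transform (rotation + isotropic scale + translation)
#' that maps the given eye centres onto fixed canonical positions, resampling
#' with bilinear interpolation onto the canonical raster implied by `grid`.
#' This is a deliberately simple two-point alignment: it standardizes in-plane
#' rotation, scale and translation, which is all the downstream patch logic
#' needs; no photometric correction is applied.
#'
#' @param img Grayscale raster (matrix, values in \[0, 255\]).
#' @param eye_left,eye_right Numeric `c(x, y)` eye centres in 0-based image
#'   coordinates; `eye_right` must lie strictly to the right of `eye_left`.
#' @param grid A [patch_grid()] defining the canonical geometry.
#' @return A `normalized_face`: list with `pixels` (canonical raster,
#'   out-of-frame samples filled with 0), `subject_id`, `image_id`,
#'   `is_neutral` (filled from the ... metadata arguments, default `NA`).
#' @param subject_id,image_id,is_neutral Optional metadata carried along.
#' @export
normalize_face <- function(img, eye_left, eye_right, grid = patch_grid(),
                           subject_id = NA_character_,
                           image_id = NA_character_, is_neutral = NA) {
  check_raster8(img, "image")
  if (!is.matrix(img)) stop_invalid("normalize_face expects a grayscale matrix")
  if (length(eye_left) != 2L || length(eye_right) != 2L)
    stop_invalid("eye coordinates must be length-2 (x, y)")
  if (all(eye_left == eye_right))
    stop_invalid("degenerate geometry: coincident eye points")
  if (eye_right[1] <= eye_left[1])
    stop_invalid("eye_right must lie strictly to the right of eye_left")
  can <- canonical_eye_positions(grid)
  # input = A %*% canonical + b, A = s * rotation
  d_in <- c(eye_right[1] - eye_left[1], eye_right[2] - eye_left[2])
  d_can <- c(can$right["x"] - can$left["x"], can$right["y"] - can$left["y"])
  s <- sqrt(sum(d_in^2)) / sqrt(sum(d_can^2))
  th <- atan2(d_in[2], d_in[1]) - atan2(d_can[2], d_can[1])
  A <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2, byrow = FALSE)
  b <- c(eye_left[1], eye_left[2]) - A %*% c(can$left["x"], can$left["y"])
  w <- grid$face_width; h <- grid$face_height
  xo <- rep(0:(w - 1L), each = h)
  yo <- rep(0:(h - 1L), times = w)
  xs <- A[1, 1] * xo + A[1, 2] * yo + b[1]
  ys <- A[2, 1] * xo + A[2, 2] * yo + b[2]
  pixels <- matrix(bilinear_sample(img, xs, ys), nrow = h, ncol = w)
  new_normalized_face(pixels, grid, subject_id, image_id, is_neutral)
}

new_normalized_face <- function(pixels, grid, subject_id = NA_character_,
                                image_id = NA_character_, is_neutral = NA) {
  if (!identical(dim(pixels), c(grid$face_height, grid$face_width)))
    stop_invalid("face raster is not canonical size")
  structure(list(pixels = pixels, subject_id = subject_id,
                 image_id = image_id, is_neutral = is_neutral, grid = grid),
            class = "normalized_face")
}

#' @export
print.normalized_face <- function(x, ...) {
  cat(sprintf("normalized_face %s (subject %s, %s): %d x %d px\n",
              x$image_id, x$subject_id,
              if (isTRUE(x$is_neutral)) "neutral" else "disguised",
              ncol(x$pixels), nrow(x$pixels)))
  invisible(x)
}

# Bilinear sampling at continuous 0-based (x, y); outside the frame -> 0.
bilinear_sample <- function(img, xs, ys) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- function(xi, yi) {
    inside <- xi >= 0 & xi <= (w - 1L) & yi >= 0 & yi <= (h - 1L)
    out <- numeric(length(xi))
    idx <- which(inside)
    out[idx] <- img[cbind(yi[idx] + 1L, xi[idx] + 1L)]
    out
  }
  v00 <- val(x0, y0);     v10 <- val(x0 + 1, y0)
  v01 <- val(x0, y0 + 1); v11 <- val(x0 + 1, y0 + 1)
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Zero out pixels outside the inscribed ellipse
#'
#' Evaluation/stimulus utility: pixels whose centres fall outside the
#' axis-aligned ellipse inscribed in the raster are set to 0. Off by default
#' in the matching pipeline.
#'
#' @param face A `normalized_face` or a plain raster matrix.
#' @return Same type as the input, masked.
#' @export
apply_elliptical_mask <- function(face) {
  px <- if (inherits(face, "normalized_face")) face$pixels else face
  h <- nrow(px); w <- ncol(px)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  a <- w / 2; b <- h / 2
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  inside <- ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
  px[!inside] <- 0
  if (inherits(face, "normalized_face")) { face$pixels <- px; face } else px
}

#' Tessellate a face into the patch grid
#'
#' Splits the canonical raster into `m * n` non-overlapping rectangular
#' patches in row-major order (patch (0,0) top-left). Concatenating the patch
#' rasters back reconstructs the face exactly.
#'
#' @param face A `normalized_face` or raster matrix whose size the grid
#'   divides exactly.
#' @param grid A [patch_grid()].
#' @return List of `m * n` patches; each has `row_index`, `col_index`
#'   (0-based) and `pixels`.
#' @export
tessellate <- function(face, grid = patch_grid()) {
  px <- if (inherits(face, "normalized_face")) face$pixels else face
  if (nrow(px) != grid$face_height || ncol(px) != grid$face_width)
    stop_invalid("grid mismatch: ", nrow(px), " x ", ncol(px),
                 " raster does not match grid face size ",
                 grid$face_height, " x ", grid$face_width)
  patches <- vector("list", grid$m * grid$n)
  k <- 1L
  for (i in 0:(grid$m - 1L)) {
    rows <- (i * grid$patch_height + 1L):((i + 1L) * grid$patch_height)
    for (j in 0:(grid$n - 1L)) {
      cols <- (j * grid$patch_width + 1L):((j + 1L) * grid$patch_width)
      patches[[k]] <- list(row_index = i, col_index = j,
                           pixels = px[rows, cols, drop = FALSE])
      k <- k + 1L
    }
  }
  patches
}

# 1-based row/col pixel ranges of patch (i, j) (0-based indices)
patch_bounds <- function(grid, i, j) {
  list(rows = (i * grid$patch_height + 1L):((i + 1L) * grid$patch_height),
       cols = (j * grid$patch_width + 1L):((j + 1L) * grid$patch_width))
}

## ---- file formats -----------------------------------------------------

#' Read and write PGM images
#'
#' Plain (P2) and raw (P5) 8-bit PGM are supported for reading; writing emits
#' plain P2 so generated fixtures stay text. Values are kept on the
#' \[0, 255\] scale.
#'
#' @param path File path.
#' @rdname pgm
#' @return `read_pgm`: a numeric matrix. `write_pgm`: `path`, invisibly.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop_invalid("not a PGM file: ", path)
  tok <- character(0)
  # header tokens: width height maxval (comments start with #)
  buf <- ""
  while (length(tok) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0 || ch == "") stop_invalid("truncated PGM header")
    if (ch == "#") { repeat { c2 <- readChar(con, 1L); if (c2 == "\n") break } ; next }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { tok <- c(tok, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  w <- as.integer(tok[1]); h <- as.integer(tok[2]); mx <- as.integer(tok[3])
  if (mx > 255L) stop_invalid("only 8-bit PGM supported")
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    if (length(vals) < w * h) stop_invalid("truncated PGM data")
    vals <- vals[seq_len(w * h)]
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @param img Numeric matrix, values in \[0, 255\] (rounded on write).
#' @rdname pgm
#' @export
write_pgm <- function(img, path) {
  check_raster8(img, "image")
  v <- round(t(img))  # row-major scan lines
  lines <- c("P2", paste(ncol(img), nrow(img)), "255",
             apply(matrix(as.integer(v), nrow = ncol(img)), 2, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read an image file (PNG or PGM) as an 8-bit matrix
#'
#' PNG input may be grayscale or colour (converted with [to_grayscale()]);
#' values are rescaled from the png package's \[0, 1\] to \[0, 255\].
#'
#' @param path File path ending in `.png` or `.pgm`.
#' @return Numeric grayscale matrix in \[0, 255\].
#' @export
read_face_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    a <- png::readPNG(path) * 255
    if (length(dim(a)) == 3L && dim(a)[3] >= 3L)
      return(to_grayscale(a[, , 1:3]))
    if (length(dim(a)) == 3L) a <- a[, , 1]
    return(a)
  }
  stop_invalid("unsupported image format: ", path)
}

#' Write an 8-bit matrix as PNG or PGM
#' @param img Numeric matrix in \[0, 255\].
#' @param path Output path ending in `.png` or `.pgm`.
#' @export
write_face_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(write_pgm(img, path))
  if (ext == "png") {
    png::writePNG(clamp01(img / 255), path)
    return(invisible(path))
  }
  stop_invalid("unsupported image format: ", path)
}

#' Read or write a dataset manifest
#'
#' The manifest is a CSV with one row per image and columns `image_id`,
#' `subject_id`, `path`, `is_neutral` (logical), `split`
#' (`"train"`/`"test"`).
#'
#' @param path CSV path.
#' @rdname manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "subject_id", "path", "is_neutral", "split")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_invalid("manifest missing columns: ", paste(missing, collapse = ", "))
  df$is_neutral <- as.logical(df$is_neutral)
  df$subject_id <- as.character(df$subject_id)
  df$image_id <- as.character(df$image_id)
  df
}

#' @param manifest Data frame as returned by [read_manifest()].
#' @rdname manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
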