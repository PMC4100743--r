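# Seeded synthetic disguised-face generation. Subjects are procedural
# textures on the canonical raster (a smooth "skin" field plus a
# subject-specific oriented grating signature), disguises are accessory
# overlays that overwrite grid-aligned footprints with either a dark uniform
# fill (sunglasses/scarf/cap-like) or high-variance noise texture
# (wig/beard-like). Every pixel a disguise touches is recorded in a coverage
# map, and patch annotations follow the majority-coverage rule: a patch is
# non-biometric iff more than half of its pixels are covered.
#
# The matching method sees faces only through intensity and LBP histograms,
# so identity-as-texture-signature exercises it fully while keeping the
# package free of face imagery.

#' Accessory specification
#'
#' @param kind One of `"sunglasses_like"`, `"scarf_like"`, `"wig_like"`,
#'   `"beard_like"`, `"cap_like"`, `"mask_like"`.
#' @param footprint Named numeric `c(x, y, width, height)`: 0-based top-left
#'   corner and size, in canonical pixels; must lie within the canonical
#'   frame.
#' @param appearance `"uniform_dark"` or `"high_texture_noise"`.
#' @param value Fill intensity for `"uniform_dark"`.
#' @param noise_sd Fill jitter SD (uniform fills get slight sensor-like
#'   noise; texture fills draw uniformly from \[0, 255\] regardless).
#' @return An `accessory_spec`.
#' @export
accessory_spec <- function(kind, footprint,
                           appearance = c("uniform_dark", "high_texture_noise"),
                           value = 25, noise_sd = 2) {
  appearance <- match.arg(appearance)
  kinds <- c("sunglasses_like", "scarf_like", "wig_like",
             "beard_like", "cap_like", "mask_like")
  if (!kind %in% kinds) stop_invalid("unknown accessory kind: ", kind)
  fp <- footprint[c("x", "y", "width", "height")]
  if (anyNA(fp)) stop_invalid("footprint needs named x, y, width, height")
  structure(list(kind = kind, footprint = fp, appearance = appearance,
                 value = value, noise_sd = noise_sd),
            class = "accessory_spec")
}

#' Default accessory pool on a grid
#'
#' Footprints are aligned to grid rows so the region analysis has clean
#' ground truth: cap/wig on the forehead row, sunglasses on the eye row, a
#' light surgical-style mask on the nose row, scarf/beard on the lips/chin
#' rows. Dark accessories are near-uniform fills; wig/beard are high-variance
#' texture.
#'
#' @param grid The [patch_grid()].
#' @return Named list of `accessory_spec`s.
#' @export
default_accessory_pool <- function(grid = patch_grid()) {
  w <- grid$face_width; ph <- grid$patch_height
  row_fp <- function(r0, nrows = 1) c(x = 0, y = r0 * ph, width = w,
                                      height = nrows * ph)
  list(
    sunglasses_like = accessory_spec("sunglasses_like", row_fp(1),
                                     "uniform_dark", value = 20),
    scarf_like = accessory_spec("scarf_like", row_fp(3, 2),
                                "uniform_dark", value = 45),
    wig_like = accessory_spec("wig_like", row_fp(0), "high_texture_noise"),
    beard_like = accessory_spec("beard_like", row_fp(3, 2),
                                "high_texture_noise"),
    cap_like = accessory_spec("cap_like", row_fp(0), "uniform_dark",
                              value = 60),
    mask_like = accessory_spec("mask_like", row_fp(2, 2), "uniform_dark",
                               value = 215)
  )
}

#' Synthetic dataset specification
#'
#' Defaults reproduce the evaluation protocol's composition: 75 subjects with
#' 6-10 images each (at least 1 neutral and at least 5 disguised per
#' subject), split by subject into 35 training and 40 testing subjects with
#' 322 training and 359 testing images in total.
#'
#' @param n_subjects Total subjects.
#' @param n_train_subjects Subjects assigned to the training split.
#' @param images_per_subject Length-2 range of images per subject.
#' @param neutral_min,disguised_min Per-subject composition minima.
#' @param total_images Named `c(train =, test =)` image totals per split, or
#'   `NULL` to leave per-subject counts unconstrained.
#' @param accessory_pool Named list of `accessory_spec`s.
#' @param accessory_weights Sampling weights over the pool (default uniform).
#' @param jitter Max absolute accessory placement offset in pixels (exercises
#'   partial patch coverage around the >50% rule).
#' @param noise_sd Per-render pixel noise SD.
#' @param grid The [patch_grid()].
#' @param seed Master seed; all randomness flows from it via named substreams.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 75L, n_train_subjects = 35L,
                           images_per_subject = c(6L, 10L),
                           neutral_min = 1L, disguised_min = 5L,
                           total_images = c(train = 322L, test = 359L),
                           accessory_pool = default_accessory_pool(grid),
                           accessory_weights = NULL,
                           jitter = 3L, noise_sd = 3,
                           grid = patch_grid(), seed = 42L) {
  if (n_train_subjects >= n_subjects)
    stop_invalid("n_train_subjects must leave at least one test subject")
  lo <- images_per_subject[1]; hi <- images_per_subject[2]
  if (lo < neutral_min + disguised_min)
    stop_invalid("infeasible spec: images_per_subject minimum below ",
                 "neutral_min + disguised_min")
  if (!is.null(total_images)) {
    kt <- c(train = n_train_subjects, test = n_subjects - n_train_subjects)
    for (s in names(kt))
      if (total_images[s] < kt[s] * lo || total_images[s] > kt[s] * hi)
        stop_invalid("infeasible spec: total_images['", s,
                     "'] outside achievable range")
  }
  if (is.null(accessory_weights))
    accessory_weights <- rep(1, length(accessory_pool))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_train_subjects = as.integer(n_train_subjects),
                 images_per_subject = as.integer(images_per_subject),
                 neutral_min = as.integer(neutral_min),
                 disguised_min = as.integer(disguised_min),
                 total_images = total_images,
                 accessory_pool = accessory_pool,
                 accessory_weights = accessory_weights,
                 jitter = as.integer(jitter), noise_sd = noise_sd,
                 grid = grid, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Deterministic per-subject base appearance
#'
#' A smooth low-frequency "skin" field (bilinearly upsampled coarse noise
#' around a subject-specific base level) plus a signature of three oriented
#' sinusoidal gratings with subject-specific frequencies, orientations and
#' phases. Distinct seeds give distinct LBP statistics; the same seed is
#' pixel-reproducible.
#'
#' @param subject_seed Integer seed identifying the subject.
#' @param grid The [patch_grid()].
#' @return Canonical-size numeric matrix in \[0, 255\].
#' @export
make_subject_prototype <- function(subject_seed, grid = patch_grid()) {
  h <- grid$face_height; w <- grid$face_width
  with_substream(subject_seed, "prototype", {
    base <- stats::runif(1, 120, 180)
    coarse <- matrix(stats::rnorm(36, 0, 18), 6, 6)
    xs <- seq(0, 5, length.out = w)
    ys <- seq(0, 5, length.out = h)
    skin <- base + matrix(bilinear_sample(coarse + 128, # reuse sampler
                                          rep(xs, each = h),
                                          rep(ys, times = w)) - 128,
                          h, w)
    x <- matrix(rep(0:(w - 1), each = h), h, w)
    y <- matrix(rep(0:(h - 1), times = w), h, w)
    tex <- 0
    for (k in 1:3) {
      f <- stats::runif(1, 0.06, 0.45)
      th <- stats::runif(1, 0, pi)
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 8, 16)
      tex <- tex + amp * sin(2 * pi * f * (cos(th) * x + sin(th) * y) + ph)
    }
    matrix(pmin(255, pmax(0, skin + tex)), h, w)
  })
}

# One acquisition of a subject: prototype plus seeded sensor noise, rounded.
render_face <- function(prototype, noise_sd, render_seed) {
  px <- with_substream(render_seed, "render",
                       prototype + stats::rnorm(length(prototype), 0, noise_sd))
  matrix(round(pmin(255, pmax(0, px))), nrow(prototype), ncol(prototype))
}

#' Overlay an accessory on a face
#'
#' Overwrites the accessory footprint (shifted by a seeded jitter offset and
#' clipped to the frame) with its fill, and returns the per-pixel coverage
#' map.
#'
#' @param pixels Canonical raster matrix.
#' @param acc An `accessory_spec`.
#' @param jitter Max absolute placement offset in pixels.
#' @param jitter_seed Integer seed for the offset and fill noise.
#' @param coverage Existing coverage map to accumulate into (optional).
#' @return List `pixels` (modified raster) and `coverage` (matrix in
#'   \{0, 1\}).
#' @export
apply_accessory <- function(pixels, acc, jitter = 0L, jitter_seed = 1L,
                            coverage = NULL) {
  h <- nrow(pixels); w <- ncol(pixels)
  fp <- acc$footprint
  if (fp["x"] < 0 || fp["y"] < 0 ||
      fp["x"] + fp["width"] > w || fp["y"] + fp["height"] > h)
    stop_invalid("accessory footprint outside the canonical frame")
  if (is.null(coverage)) coverage <- matrix(0, h, w)
  res <- with_substream(jitter_seed, paste0("accessory_", acc$kind), {
    off <- if (jitter > 0) sample(seq(-jitter, jitter), 2, replace = TRUE)
           else c(0L, 0L)
    x0 <- max(0, fp["x"] + off[1]); y0 <- max(0, fp["y"] + off[2])
    x1 <- min(w, fp["x"] + fp["width"] + off[1])
    y1 <- min(h, fp["y"] + fp["height"] + off[2])
    rows <- (y0 + 1):y1; cols <- (x0 + 1):x1
    npx <- length(rows) * length(cols)
    fill <- if (acc$appearance == "uniform_dark") {
      pmin(255, pmax(0, acc$value + stats::rnorm(npx, 0, acc$noise_sd)))
    } else {
      stats::runif(npx, 0, 255)
    }
    pixels[rows, cols] <- round(matrix(fill, length(rows), length(cols)))
    coverage[rows, cols] <- 1
    list(pixels = pixels, coverage = coverage)
  })
  res
}

#' Annotate patches from a coverage map
#'
#' Per-patch mean coverage; a patch is labelled non-biometric iff strictly
#' more than half of it is covered.
#'
#' @param coverage Per-pixel coverage matrix in \[0, 1\].
#' @param grid The [patch_grid()].
#' @return An `annotation_grid`: list with `labels` (m x n character) and
#'   `coverage` (m x n mean fraction).
#' @export
annotate <- function(coverage, grid = patch_grid()) {
  if (any(coverage < 0 | coverage > 1))
    stop_invalid("coverage values must lie in [0, 1]")
  frac <- matrix(0, grid$m, grid$n)
  for (i in 0:(grid$m - 1L)) for (j in 0:(grid$n - 1L)) {
    b <- patch_bounds(grid, i, j)
    frac[i + 1L, j + 1L] <- mean(coverage[b$rows, b$cols])
  }
  labels <- ifelse(frac > 0.5, "non_biometric", "biometric")
  structure(list(labels = labels, coverage = frac), class = "annotation_grid")
}

# Allocate per-subject image counts within [lo, hi], optionally hitting an
# exact split total; seeded and deterministic.
allocate_counts <- function(k, lo, hi, total, seed, stream) {
  with_substream(seed, stream, {
    if (is.null(total)) return(sample(lo:hi, k, replace = TRUE))
    counts <- rep(lo, k)
    extra <- total - lo * k
    while (extra > 0L) {
      open <- which(counts < hi)
      pick <- open[sample.int(length(open), 1L)]
      counts[pick] <- counts[pick] + 1L
      extra <- extra - 1L
    }
    counts
  })
}

#' Generate a synthetic disguised-face dataset
#'
#' Produces rendered images, ground-truth patch annotations with coverage
#' fractions, and a manifest with a by-subject train/test split. Fully
#' deterministic given the spec's seed. When `dir` is given, writes
#' `images/*.pgm`, `annotations/*.csv` (one grid CSV per image:
#' row, col, label, coverage), `manifest.csv` and a `spec.json` echo.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory.
#' @return Invisibly (and visibly when `dir` is `NULL`): list with `manifest`
#'   (data frame), `images` (named list of rasters), `annotations` (named list
#'   of `annotation_grid`s) and `spec`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- spec$grid
  ns <- spec$n_subjects
  subj_ids <- sprintf("S%03d", seq_len(ns))
  split_order <- with_substream(spec$seed, "split", sample(ns))
  split <- rep("test", ns)
  split[split_order[seq_len(spec$n_train_subjects)]] <- "train"

  lo <- spec$images_per_subject[1]; hi <- spec$images_per_subject[2]
  counts <- integer(ns)
  for (s in c("train", "test")) {
    idx <- which(split == s)
    counts[idx] <- allocate_counts(
      length(idx), lo, hi,
      if (is.null(spec$total_images)) NULL else spec$total_images[[s]],
      spec$seed, paste0("counts_", s))
  }

  pool <- spec$accessory_pool
  images <- list(); annotations <- list()
  manifest <- vector("list", ns)
  empty_cov <- matrix(0, grid$face_height, grid$face_width)
  for (si in seq_len(ns)) {
    sid <- subj_ids[si]
    proto_seed <- substream_seed(spec$seed, paste0("subject_", sid))
    proto <- make_subject_prototype(proto_seed, grid)
    c_i <- counts[si]
    n_neutral <- with_substream(spec$seed, paste0("composition_", sid), {
      slack <- c_i - spec$disguised_min - spec$neutral_min
      spec$neutral_min + if (slack > 0)
        sample(0:slack, 1, prob = 0.5^(0:slack)) else 0L
    })
    rows <- vector("list", c_i)
    for (im in seq_len(c_i)) {
      iid <- sprintf("%s_I%02d", sid, im)
      px <- render_face(proto, spec$noise_sd,
                        substream_seed(spec$seed, paste0("render_", iid)))
      cov <- empty_cov
      neutral <- im <= n_neutral
      if (!neutral) {
        acc_seed <- substream_seed(spec$seed, paste0("accessories_", iid))
        picks <- with_substream(acc_seed, "pick", {
          n_acc <- sample(1:2, 1, prob = c(0.6, 0.4))
          sample(seq_along(pool), min(n_acc, length(pool)),
                 prob = spec$accessory_weights)
        })
        for (p in picks) {
          res <- apply_accessory(px, pool[[p]], spec$jitter,
                                 substream_seed(acc_seed, names(pool)[p]),
                                 coverage = cov)
          px <- res$pixels; cov <- res$coverage
        }
      }
      images[[iid]] <- px
      annotations[[iid]] <- annotate(cov, grid)
      rows[[im]] <- data.frame(image_id = iid, subject_id = sid,
                               path = file.path("images", paste0(iid, ".pgm")),
                               is_neutral = neutral, split = split[si],
                               stringsAsFactors = FALSE)
    }
    manifest[[si]] <- do.call(rbind, rows)
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  out <- list(manifest = manifest, images = images,
              annotations = annotations, spec = spec)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
    for (iid in names(images))
      write_pgm(images[[iid]], file.path(dir, "images", paste0(iid, ".pgm")))
    for (iid in names(annotations))
      write_annotation_grid(annotations[[iid]],
                            file.path(dir, "annotations", paste0(iid, ".csv")))
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    echo <- spec
    echo$accessory_pool <- lapply(spec$accessory_pool, unclass)
    echo$grid <- unclass(spec$grid)
    jsonlite::write_json(unclass(echo), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(out))
  }
  out
}

#' Read or write a per-image annotation grid CSV
#'
#' Long-format CSV with columns `row`, `col` (0-based), `label`, `coverage`.
#'
#' @param ann An `annotation_grid`.
#' @param path CSV path.
#' @rdname annotation_io
#' @export
write_annotation_grid <- function(ann, path) {
  m <- nrow(ann$labels); n <- ncol(ann$labels)
  df <- data.frame(row = rep(0:(m - 1L), each = n),
                   col = rep(0:(n - 1L), times = m),
                   label = as.vector(t(ann$labels)),
                   coverage = as.vector(t(ann$coverage)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_annotation_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- max(df$row) + 1L; n <- max(df$col) + 1L
  labels <- matrix(NA_character_, m, n)
  coverage <- matrix(NA_real_, m, n)
  labels[cbind(df$row + 1L, df$col + 1L)] <- df$label
  coverage[cbind(df$row + 1L, df$col + 1L)] <- df$coverage
  structure(list(labels = labels, coverage = coverage),
            class = "annotation_grid")
}

#' Gallery/probe split of the test manifest
#'
#' For every test subject, one seeded-random neutral image plus four other
#' seeded-random images form the gallery; the remaining images are probes.
#' Different `trial` values give the independent random splits used for
#' cross-validation trials.
#'
#' @param manifest Manifest data frame (only rows with `split == "test"` are
#'   used).
#' @param seed Integer seed.
#' @param trial Trial number (>= 1).
#' @return List with character vectors `gallery` and `probe` of image ids.
#' @export
gallery_probe_split <- function(manifest, seed = 1L, trial = 1L) {
  test <- manifest[manifest$split == "test", , drop = FALSE]
  gallery <- character(0)
  for (sid in unique(test$subject_id)) {
    rows <- test[test$subject_id == sid, , drop = FALSE]
    if (nrow(rows) < 5L)
      stop_invalid("subject ", sid, " has fewer than 5 test images")
    neutrals <- rows$image_id[rows$is_neutral]
    if (!length(neutrals))
      stop_invalid("subject ", sid, " has no neutral image")
    picks <- with_substream(seed, paste0("gallery_t", trial, "_", sid), {
      nsel <- neutrals[sample.int(length(neutrals), 1L)]
      others <- setdiff(rows$image_id, nsel)
      c(nsel, others[sample.int(length(others), 4L)])
    })
    gallery <- c(gallery, picks)
  }
  list(gallery = gallery,
       probe = setdiff(test$image_id, gallery))
}
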