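# Verification matching: combine the two flag matrices of a gallery-probe
# pair into a usability mask and average the per-patch chi-squared distance
# between LBP histograms over the usable patches.

#' Pair mask from two flag matrices
#'
#' A patch position is usable for a gallery-probe pair only when both images
#' flag it biometric; matching a biometric patch against an accessory patch
#' injects misleading appearance, so any disagreement excludes the position.
#'
#' @param flags_gallery,flags_probe Character m x n flag matrices (entries
#'   `"biometric"`/`"non_biometric"`) of the same dimensions, or logical
#'   matrices with `TRUE` = biometric.
#' @return Logical m x n matrix, `TRUE` = patch used.
#' @export
pair_mask <- function(flags_gallery, flags_probe) {
  bg <- as_biometric_logical(flags_gallery)
  bp <- as_biometric_logical(flags_probe)
  if (!identical(dim(bg), dim(bp)))
    stop_invalid("flag matrices have different dimensions")
  bg & bp
}

as_biometric_logical <- function(f) {
  if (is.logical(f)) return(f)
  if (is.character(f)) {
    m <- f == "biometric"
    dim(m) <- dim(f)
    return(m)
  }
  stop_invalid("flags must be character labels or logical")
}

#' Per-patch LBP histograms of a face
#'
#' Convenience used by the matcher: the full-face LBP code map histogrammed
#' over every grid patch.
#'
#' @param face `normalized_face` or canonical raster.
#' @param grid The [patch_grid()].
#' @param per_patch If `TRUE`, compute LBP codes inside each patch in
#'   isolation (see [face_descriptors()]).
#' @return Numeric (m*n) x 256 matrix, patches in row-major order.
#' @export
face_lbp_histograms <- function(face, grid = patch_grid(), per_patch = FALSE) {
  px <- if (inherits(face, "normalized_face")) face$pixels else face
  out <- matrix(0, grid$m * grid$n, 256L)
  if (per_patch) {
    patches <- tessellate(px, grid)
    for (k in seq_along(patches))
      out[k, ] <- lbp_histogram(lbp_code_map(patches[[k]]$pixels))
    return(out)
  }
  codes <- lbp_code_map(px)
  k <- 1L
  for (i in 0:(grid$m - 1L)) for (j in 0:(grid$n - 1L)) {
    b <- patch_bounds(grid, i, j)
    out[k, ] <- lbp_histogram(codes, b$rows, b$cols)
    k <- k + 1L
  }
  out
}

#' Masked verification distance between two faces
#'
#' The chi-squared distance between corresponding per-patch LBP histograms,
#' aggregated over the patches the pair mask marks usable. The default
#' aggregation is the mean over used patches, which keeps scores comparable
#' across pairs with different numbers of usable patches; `mode = "sum"` gives
#' the unnormalized total. A pair with no usable patch gets distance `Inf`
#' (always rejected) with `used_patches = 0`.
#'
#' @param gallery,probe `normalized_face` objects or canonical rasters.
#' @param mask Logical m x n pair mask from [pair_mask()]; default all-`TRUE`
#'   (plain LBP matching).
#' @param grid The [patch_grid()].
#' @param mode `"mean"` (default) or `"sum"`.
#' @param hist_gallery,hist_probe Optional precomputed (m*n) x 256 histogram
#'   matrices from [face_lbp_histograms()], to avoid recomputation in sweeps.
#' @return A `match_score`: list with `distance` and `used_patches`.
#' @export
masked_distance <- function(gallery, probe, mask = NULL, grid = patch_grid(),
                            mode = c("mean", "sum"),
                            hist_gallery = NULL, hist_probe = NULL) {
  mode <- match.arg(mode)
  if (is.null(hist_gallery)) hist_gallery <- face_lbp_histograms(gallery, grid)
  if (is.null(hist_probe)) hist_probe <- face_lbp_histograms(probe, grid)
  if (!identical(dim(hist_gallery), dim(hist_probe)))
    stop_invalid("gallery/probe histogram geometry mismatch")
  if (is.null(mask)) mask <- matrix(TRUE, grid$m, grid$n)
  if (length(mask) != nrow(hist_gallery))
    stop_invalid("mask does not match the patch grid")
  use <- as.vector(t(mask))  # row-major patch order
  k <- sum(use)
  if (k == 0L)
    return(structure(list(distance = Inf, used_patches = 0L),
                     class = "match_score"))
  d <- vapply(which(use),
              function(p) chi2_distance(hist_gallery[p, ], hist_probe[p, ]),
              numeric(1))
  total <- sum(d)
  structure(list(distance = if (mode == "mean") total / k else total,
                 used_patches = as.integer(k)),
            class = "match_score")
}

#' @export
print.match_score <- function(x, ...) {
  cat(sprintf("match_score: D = %.6g over %d patches\n",
              x$distance, x$used_patches))
  invisible(x)
}

#' Accept/reject decision at a distance threshold
#'
#' Accepts when the distance is finite and less than or equal to the
#' threshold (inclusive, for deterministic ROC construction); infinite
#' distances are rejected at every threshold.
#'
#' @param score `match_score` or numeric distance(s).
#' @param theta Decision threshold.
#' @return Logical: `TRUE` = accept (claimed identity verified).
#' @export
verify <- function(score, theta) {
  d <- if (inherits(score, "match_score")) score$distance else score
  is.finite(d) & d <= theta
}

#' All gallery x probe masked distances
#'
#' Evaluation workhorse: computes the full distance matrix between every
#' gallery and probe image from precomputed per-patch LBP histograms and
#' per-image biometric flags, sharing the per-patch chi-squared computation
#' across the three masking arms (each patch-pair distance is computed once
#' and aggregated under the supplied flags).
#'
#' @param hists_gallery,hists_probe Lists of (m*n) x 256 histogram matrices.
#' @param flags_gallery,flags_probe Lists of flag matrices (or `NULL` for
#'   all-biometric, the plain-LBP arm).
#' @param grid The [patch_grid()].
#' @param mode Aggregation, as in [masked_distance()].
#' @return List with `distance` (gallery x probe matrix, `Inf` where no patch
#'   was usable) and `used` (matching count matrix).
#' @export
match_all_pairs <- function(hists_gallery, hists_probe,
                            flags_gallery = NULL, flags_probe = NULL,
                            grid = patch_grid(), mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  ng <- length(hists_gallery); np <- length(hists_probe)
  nk <- grid$m * grid$n
  eps <- 1e-10
  bio_vec <- function(flags, nimg) {
    if (is.null(flags)) return(matrix(TRUE, nk, nimg))
    vapply(flags, function(f) as.vector(t(as_biometric_logical(f))),
           logical(nk))
  }
  bg <- bio_vec(flags_gallery, ng)  # nk x ng
  bp <- bio_vec(flags_probe, np)    # nk x np
  total <- matrix(0, ng, np)
  used <- matrix(0L, ng, np)
  probe_k <- vector("list", nk)
  for (k in seq_len(nk))
    probe_k[[k]] <- t(vapply(hists_probe, function(h) h[k, ], numeric(256)))
  for (g in seq_len(ng)) {
    hg <- hists_gallery[[g]]
    for (k in seq_len(nk)) {
      if (!bg[k, g]) next
      sel <- bp[k, ]
      if (!any(sel)) next
      P <- probe_k[[k]][sel, , drop = FALSE]
      diff <- sweep(P, 2, hg[k, ], "-")
      den <- sweep(P, 2, hg[k, ], "+") + eps
      dk <- rowSums(diff^2 / den)
      total[g, sel] <- total[g, sel] + dk
      used[g, sel] <- used[g, sel] + 1L
    }
  }
  distance <- if (mode == "mean") total / used else
    ifelse(used > 0L, total, NA_real_)
  distance[used == 0L] <- Inf
  list(distance = distance, used = used)
}
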