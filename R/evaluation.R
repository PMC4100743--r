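# Verification evaluation: FAR/GAR/Accuracy from response counts, ROC
# construction with GAR-at-FAR and EER readouts, and the disguised-region
# combination error analysis on the 5 x 5 grid.

REGIONS <- c("forehead", "eyes", "nose", "lips_chin")

#' Verification rates from response counts
#'
#' Given counts of genuine accepts (GA), false accepts (FA), genuine rejects
#' (GR) and false rejects (FR):
#' `FAR = FA / (FA + GR)`, `GAR = GA / (GA + FR)`,
#' `Accuracy = (GA + GR) / (GA + FA + GR + FR)`, all as percentages.
#'
#' @param ga,fa,gr,fr Non-negative integer counts.
#' @return Named list `far`, `gar`, `accuracy`, in percent.
#' @export
rates <- function(ga, fa, gr, fr) {
  counts <- c(ga = ga, fa = fa, gr = gr, fr = fr)
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  if (ga + fr == 0) stop_invalid("undefined rate: no genuine pairs (GA+FR=0)")
  if (fa + gr == 0) stop_invalid("undefined rate: no impostor pairs (FA+GR=0)")
  list(far = 100 * fa / (fa + gr),
       gar = 100 * ga / (ga + fr),
       accuracy = 100 * (ga + gr) / sum(counts))
}

#' Verification ROC from genuine and impostor distances
#'
#' Sweeps the acceptance threshold over every distinct finite distance
#' (acceptance is `distance <= threshold`; infinite distances are rejected at
#' every threshold but kept in the rate denominators, and their count is
#' reported). FAR and GAR are fractions in \[0, 1\] and both non-decreasing in
#' the threshold.
#'
#' @param genuine,impostor Numeric distance vectors (may contain `Inf` for
#'   pairs with no usable patch).
#' @return A `roc_curve`: data frame with columns `threshold`, `far`, `gar`,
#'   plus attributes `n_genuine`, `n_impostor`, `n_infinite`.
#' @export
roc_curve <- function(genuine, impostor) {
  if (length(genuine) == 0L || length(impostor) == 0L)
    stop_invalid("roc_curve needs at least one distance per class")
  thr <- sort(unique(c(genuine, impostor)))
  thr <- thr[is.finite(thr)]
  if (length(thr) == 0L) stop_invalid("all distances are infinite")
  gar <- vapply(thr, function(t) mean(genuine <= t), numeric(1))
  far <- vapply(thr, function(t) mean(impostor <= t), numeric(1))
  out <- data.frame(threshold = thr, far = far, gar = gar)
  attr(out, "n_genuine") <- length(genuine)
  attr(out, "n_impostor") <- length(impostor)
  attr(out, "n_infinite") <- sum(!is.finite(genuine)) + sum(!is.finite(impostor))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' GAR at a fixed FAR
#'
#' Reads the genuine accept rate off the ROC at the requested false accept
#' rate, linearly interpolating between adjacent operating points (the curve
#' is augmented with the (0, 0) endpoint; FARs beyond the last point return
#' the final GAR).
#'
#' @param curve A `roc_curve`.
#' @param far Target FAR as a fraction (e.g. `0.01` for 1%).
#' @return GAR fraction in \[0, 1\].
#' @export
gar_at_far <- function(curve, far) {
  stopifnot(inherits(curve, "roc_curve"), far >= 0, far <= 1)
  x <- c(0, curve$far)
  y <- c(0, curve$gar)
  # staircase can repeat FARs: at a given FAR the achievable GAR is the best
  stats::approx(x, y, xout = far, ties = max, rule = 2)$y
}

#' Equal error rate of a verification ROC
#'
#' The operating point where the false accept rate equals the false reject
#' rate (`1 - GAR`). Returns the midpoint `(FAR + FRR) / 2` at the sweep point
#' minimizing `|FAR - FRR|`.
#'
#' @param curve A `roc_curve`.
#' @return EER as a fraction in \[0, 1\].
#' @export
eer <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  frr <- 1 - curve$gar
  i <- which.min(abs(curve$far - frr))
  (curve$far[i] + frr[i]) / 2
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d operating points, %d genuine / %d impostor (%d infinite)\n",
              nrow(x), attr(x, "n_genuine"), attr(x, "n_impostor"),
              attr(x, "n_infinite")))
  for (f in c(0.001, 0.01, 0.1))
    cat(sprintf("  GAR @ %4.1f%% FAR: %5.1f%%\n", 100 * f,
                100 * gar_at_far(x, f)))
  cat(sprintf("  EER: %.1f%%\n", 100 * eer(x)))
  invisible(x)
}

#' Disguised regions of a 5 x 5 annotation or flag grid
#'
#' Grid rows map to face regions: row 0 forehead, row 1 eyes, row 2 nose,
#' rows 3-4 together lips and chin. A region counts as disguised when more
#' than half of its patches are non-biometric (at least 3 of 5 for a single
#' row, at least 6 of 10 for lips/chin).
#'
#' @param flags 5 x 5 character flag/annotation matrix, or logical with
#'   `TRUE` = biometric.
#' @return Character vector: subset of
#'   `c("forehead", "eyes", "nose", "lips_chin")` (possibly empty).
#' @export
region_labels <- function(flags) {
  bio <- as_biometric_logical(flags)
  if (!identical(dim(bio), c(5L, 5L)))
    stop_invalid("region analysis is defined for the 5 x 5 grid only")
  nb <- !bio
  disguised <- c(
    forehead = sum(nb[1, ]) > 2.5,
    eyes = sum(nb[2, ]) > 2.5,
    nose = sum(nb[3, ]) > 2.5,
    lips_chin = sum(nb[4:5, ]) > 5
  )
  REGIONS[disguised]
}

#' Canonical name of a region combination
#'
#' @param regions Character vector of regions (any order); empty -> `"none"`.
#' @return Single string, regions in canonical order joined by `"+"`.
#' @export
region_combo <- function(regions) {
  regions <- unique(as.character(regions))
  bad <- setdiff(regions, REGIONS)
  if (length(bad)) stop_invalid("unknown regions: ", paste(bad, collapse = ", "))
  if (!length(regions)) return("none")
  paste(REGIONS[REGIONS %in% regions], collapse = "+")
}

#' All 16 region combinations
#' @return Character vector of the 16 canonical combination names.
#' @export
all_region_combos <- function() {
  combos <- "none"
  for (k in 1:4)
    combos <- c(combos, apply(utils::combn(REGIONS, k), 2,
                              function(r) region_combo(r)))
  combos
}

#' Pair-level disguise combination
#'
#' A verification pair's combination is the union of the disguised regions of
#' its two images (an alternative `"per_image"` reading, where each image
#' contributes its own combination, is available for sensitivity checks via
#' [combo_error_table()]).
#'
#' @param flags_a,flags_b 5 x 5 flag/annotation matrices of the pair.
#' @return Canonical combination string.
#' @export
pair_region_combo <- function(flags_a, flags_b) {
  region_combo(union(region_labels(flags_a), region_labels(flags_b)))
}

#' Misclassification fraction per disguise-region combination
#'
#' Tallies, for each of the 16 region combinations, the fraction of evaluated
#' pairs assigned to it that were misclassified. Combinations with no pairs
#' are reported as absent (`NA` fraction, zero count).
#'
#' @param combos Character vector of combination names, one per pair (from
#'   [pair_region_combo()] or [region_combo()]).
#' @param correct Logical vector: was the pair classified correctly?
#' @return Data frame with columns `combo`, `n`, `errors`, `fraction`, one row
#'   per combination in canonical order.
#' @export
combo_error_table <- function(combos, correct) {
  if (length(combos) != length(correct))
    stop_invalid("combos/correct length mismatch")
  all16 <- all_region_combos()
  bad <- setdiff(unique(combos), all16)
  if (length(bad)) stop_invalid("unknown combinations: ", paste(bad, collapse = ", "))
  n <- as.integer(table(factor(combos, levels = all16)))
  errors <- as.integer(tapply(!correct, factor(combos, levels = all16), sum,
                              default = 0L))
  data.frame(combo = all16, n = n, errors = errors,
             fraction = ifelse(n > 0L, errors / n, NA_real_))
}
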