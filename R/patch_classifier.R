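# Biometric vs non-biometric patch classification: an RBF-kernel SVM over
# min-max-normalized ITE descriptors, hyper-parameters chosen by grid search
# with seeded 5-fold cross-validation, and assembly of per-face flag matrices.
#
# Polarity convention: non_biometric is the positive class, so larger SVM
# decision values mean "more non-biometric" and the decision rule reads
# naturally as: score < tau -> biometric, score >= tau -> non_biometric.

PATCH_LABELS <- c("non_biometric", "biometric")

default_cost_grid <- function() 2^seq(-3, 15, by = 2)
default_gamma_grid <- function() 2^seq(-15, 3, by = 2)

#' Train the biometric/non-biometric patch classifier
#'
#' Fits an RBF-kernel SVM on (optionally raw) ITE descriptors. Descriptors are
#' min-max normalized per dimension using ranges learned here; the
#' (cost, gamma) pair is chosen by grid search maximizing 5-fold
#' cross-validated accuracy with fold assignment drawn from a named substream
#' of `seed` (ties broken toward the first grid entry, i.e. smallest cost then
#' smallest gamma). After fitting, a decision threshold `tau` is placed at the
#' requested operating point using pooled out-of-fold CV scores (resubstitution
#' scores are margin-compressed and would misplace the operating point).
#'
#' @param descriptors Numeric matrix, one 512-dim descriptor per row.
#' @param labels Character vector, `"biometric"` / `"non_biometric"`, one per
#'   row; both classes must be present.
#' @param seed Integer seed controlling fold assignment.
#' @param cost_grid,gamma_grid Numeric grids searched; defaults
#'   `2^seq(-3, 15, 2)` and `2^seq(-15, 3, 2)`.
#' @param operating_point `"biometric_recall"` (default) or `"eer"`; see
#'   [choose_threshold()].
#' @param recall Target biometric recall for the `"biometric_recall"` point.
#' @param class_weights If `TRUE`, weight misclassification cost by inverse
#'   class frequency (off by default).
#' @param folds Number of CV folds (default 5).
#' @param groups Optional grouping vector (e.g. subject id per patch): fold
#'   assignment is then by group, never splitting a group across folds, so
#'   cross-validated accuracy and the operating point reflect performance on
#'   unseen subjects rather than unseen patches of seen subjects.
#' @return A `patch_classifier` with the fitted svm, the `minmax_model`, the
#'   chosen `cost`/`gamma`, `tau`, and the CV accuracy table (`cv_table`).
#' @export
train_patch_classifier <- function(descriptors, labels, seed = 1L,
                                   cost_grid = default_cost_grid(),
                                   gamma_grid = default_gamma_grid(),
                                   operating_point = "biometric_recall",
                                   recall = 0.95,
                                   class_weights = FALSE,
                                   folds = 5L, groups = NULL) {
  if (is.vector(descriptors)) descriptors <- matrix(descriptors, nrow = 1L)
  labels <- as.character(labels)
  if (!all(labels %in% PATCH_LABELS))
    stop_invalid("labels must be 'biometric' or 'non_biometric'")
  if (length(unique(labels)) < 2L)
    stop_invalid("training needs both patch classes")
  if (nrow(descriptors) != length(labels))
    stop_invalid("descriptor/label count mismatch")

  mm <- minmax_fit(descriptors)
  x <- minmax_apply(mm, descriptors)
  y <- factor(labels, levels = PATCH_LABELS)
  wts <- NULL
  if (class_weights) {
    tab <- table(y)
    wts <- as.numeric(sum(tab) / (length(tab) * tab))
    names(wts) <- names(tab)
  }

  n <- nrow(x)
  fold_id <- with_substream(seed, "cv_folds", {
    if (is.null(groups)) sample(rep_len(seq_len(folds), n)) else {
      g <- as.character(groups)
      if (length(g) != n) stop_invalid("groups/descriptor count mismatch")
      u <- unique(g)
      gf <- stats::setNames(sample(rep_len(seq_len(folds), length(u))), u)
      unname(gf[g])
    }
  })
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("cost", "gamma")]
  cv_acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (all(tr) || length(unique(y[tr])) < 2L) next
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        scale = FALSE, class.weights = wts)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    cv_acc[g] <- correct / n
  }
  best <- which.max(cv_acc)  # which.max takes the first maximum: ties go to
                             # the smallest cost, then smallest gamma
  fit <- e1071::svm(x, y, kernel = "radial",
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    scale = FALSE, class.weights = wts)
  # e1071 reports decision values for the class pair named in the column;
  # establish the sign making non_biometric positive.
  svm_scores <- function(fit, newx) {
    dv <- attr(stats::predict(fit, newx, decision.values = TRUE),
               "decision.values")
    sgn <- if (startsWith(colnames(dv)[1], "non_biometric")) 1 else -1
    sgn * dv[, 1]
  }
  # The threshold is placed on pooled out-of-fold scores: resubstitution
  # scores are margin-compressed near +/-1 and would put the operating point
  # in the wrong place for unseen patches.
  oof <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (all(tr)) next
    ffit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                       cost = grid$cost[best], gamma = grid$gamma[best],
                       scale = FALSE, class.weights = wts)
    oof[!tr] <- svm_scores(ffit, x[!tr, , drop = FALSE])
  }
  dv <- attr(stats::predict(fit, x[1:min(5L, n), , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  positive_first <- startsWith(colnames(dv)[1], "non_biometric")
  structure(
    list(svm = fit, minmax = mm,
         cost = grid$cost[best], gamma = grid$gamma[best],
         sign = if (positive_first) 1 else -1,
         cv_table = cbind(grid, cv_accuracy = cv_acc),
         operating_point = operating_point,
         tau = choose_threshold(oof, labels, operating_point, recall),
         oof_scores = oof),
    class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf(paste0("patch_classifier: RBF SVM (cost=%g, gamma=%g), ",
                     "tau=%.4g at '%s'\n"),
              x$cost, x$gamma, x$tau, x$operating_point))
  invisible(x)
}

#' SVM score of one or more descriptors
#'
#' Applies the model's stored min-max normalization, then returns the signed
#' SVM decision value; larger scores mean more non-biometric.
#'
#' @param model A trained `patch_classifier`.
#' @param d Raw descriptor vector, or matrix with one descriptor per row.
#' @return Numeric score(s).
#' @export
score_patch <- function(model, d) {
  if (!inherits(model, "patch_classifier") || is.null(model$svm))
    stop_invalid("score_patch needs a trained patch_classifier")
  x <- minmax_apply(model$minmax, d)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  dv <- attr(stats::predict(model$svm, x, decision.values = TRUE),
             "decision.values")
  as.numeric(model$sign * dv[, 1])
}

#' Threshold a patch score into a label
#'
#' A patch is biometric when its score is strictly below the threshold, and
#' non-biometric when the score is greater than or equal to it.
#'
#' @param s Numeric score(s).
#' @param tau Decision threshold.
#' @return Character vector of `"biometric"` / `"non_biometric"`.
#' @export
classify_patch <- function(s, tau) {
  ifelse(s < tau, "biometric", "non_biometric")
}

#' Flag matrix of a face
#'
#' Computes the ITE descriptor of every grid patch, scores it, and assembles
#' the m x n matrix of biometric/non-biometric decisions.
#'
#' @param model Trained `patch_classifier`.
#' @param face `normalized_face` or canonical raster.
#' @param grid The [patch_grid()].
#' @param tau Threshold; defaults to the model's stored operating point.
#' @return Character m x n matrix with entries `"biometric"` /
#'   `"non_biometric"`, patch (0,0) at `[1, 1]`.
#' @export
flag_matrix <- function(model, face, grid = patch_grid(), tau = model$tau) {
  d <- face_descriptors(face, grid)
  s <- score_patch(model, d)
  matrix(classify_patch(s, tau), nrow = grid$m, ncol = grid$n, byrow = TRUE)
}

#' Choose the score threshold for an operating point
#'
#' Candidate thresholds are the distinct observed scores plus one value above
#' the maximum. For `"biometric_recall"`, returns the smallest threshold whose
#' biometric recall (fraction of biometric scores strictly below it) meets the
#' target. For `"eer"`, returns the threshold minimizing the absolute gap
#' between the two error rates (biometric patches scored >= tau vs
#' non-biometric patches scored < tau), smallest threshold on ties.
#'
#' @param scores Numeric validation scores (larger = more non-biometric).
#' @param labels Matching `"biometric"`/`"non_biometric"` truth labels.
#' @param operating_point `"biometric_recall"` or `"eer"`.
#' @param recall Target recall in (0, 1\] for `"biometric_recall"`.
#' @return The threshold `tau`.
#' @export
choose_threshold <- function(scores, labels,
                             operating_point = c("biometric_recall", "eer"),
                             recall = 0.95) {
  operating_point <- match.arg(operating_point)
  labels <- as.character(labels)
  if (!any(labels == "biometric") || !any(labels == "non_biometric"))
    stop_invalid("choose_threshold needs scores from both classes")
  sb <- scores[labels == "biometric"]
  sn <- scores[labels == "non_biometric"]
  cand <- sort(unique(c(scores, max(scores) + 1)))
  if (operating_point == "biometric_recall") {
    if (!is.numeric(recall) || recall <= 0 || recall > 1)
      stop_invalid("unattainable operating point: recall must be in (0, 1]")
    rec <- vapply(cand, function(t) mean(sb < t), numeric(1))
    ok <- which(rec >= recall)
    if (!length(ok)) stop_invalid("unattainable operating point")
    return(cand[ok[1]])
  }
  fnr_b <- vapply(cand, function(t) mean(sb >= t), numeric(1))
  fpr_n <- vapply(cand, function(t) mean(sn < t), numeric(1))
  cand[which.min(abs(fnr_b - fpr_n))]
}

#' Area under the patch-classification ROC
#'
#' Probability that a randomly chosen non-biometric patch scores higher than a
#' randomly chosen biometric patch (ties count one half): the rank-statistic
#' AUC of scores oriented so that larger means non-biometric.
#'
#' @param scores Numeric scores.
#' @param labels Matching truth labels.
#' @return AUC in \[0, 1\].
#' @export
classification_auc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "non_biometric"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L)
    stop_invalid("AUC needs scores from both classes")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Persist / restore a trained patch classifier
#'
#' The model file bundles the SVM, min-max ranges, chosen hyper-parameters,
#' threshold and CV table in a single RDS file.
#'
#' @param model A `patch_classifier`.
#' @param path File path.
#' @rdname classifier_io
#' @export
save_patch_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname classifier_io
#' @export
load_patch_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "patch_classifier"))
    stop_invalid("not a patch_classifier file: ", path)
  m
}
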