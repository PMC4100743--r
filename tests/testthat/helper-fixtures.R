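# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive loops / exhaustive enumeration, never the package code paths they
# check.

# Naive per-pixel LBP oracle: explicit double loop over interior pixels,
# neighbours compared clockwise from top-left, MSB first, >= convention.
naive_lbp <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_integer_, h, w)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    code <- 0
    for (b in seq_along(offs)) {
      o <- offs[[b]]
      if (img[i + o[1], j + o[2]] >= img[i, j])
        code <- code + 2^(8 - b)
    }
    out[i, j] <- as.integer(code)
  }
  out
}

# Exhaustive-threshold ROC oracle: for every candidate threshold, count
# acceptances directly.
brute_roc <- function(genuine, impostor) {
  thr <- sort(unique(c(genuine, impostor)))
  thr <- thr[is.finite(thr)]
  data.frame(
    threshold = thr,
    far = vapply(thr, function(t) sum(impostor <= t) / length(impostor),
                 numeric(1)),
    gar = vapply(thr, function(t) sum(genuine <= t) / length(genuine),
                 numeric(1)))
}

# Exhaustive threshold-selection oracle for the biometric-recall point.
brute_recall_threshold <- function(scores, labels, recall) {
  sb <- scores[labels == "biometric"]
  cand <- sort(unique(c(scores, max(scores) + 1)))
  for (t in cand) if (sum(sb < t) / length(sb) >= recall) return(t)
  stop("unattainable")
}

# Two well-separated descriptor clouds in [0,1]^d.
separable_descriptors <- function(n_per_class = 30L, d = 512L, seed = 99L) {
  set.seed(seed)
  bio <- matrix(pmin(1, pmax(0, stats::rnorm(n_per_class * d, 0.2, 0.03))),
                n_per_class, d)
  non <- matrix(pmin(1, pmax(0, stats::rnorm(n_per_class * d, 0.8, 0.03))),
                n_per_class, d)
  list(x = rbind(bio, non),
       labels = rep(c("biometric", "non_biometric"), each = n_per_class))
}

tiny_grid_svm <- function() list(cost = 2, gamma = 2^-5)

# A small shared synthetic dataset (8 subjects), generated once per run.
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synthetic_spec(
        n_subjects = 8, n_train_subjects = 4, total_images = NULL,
        seed = 2024))
    cache
  }
})
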