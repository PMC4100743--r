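# End-to-end pipeline: configuration, the in-memory experiment helpers the
# evaluation protocol is built from, and the cmd_* stage functions the
# command-line front end (inst/scripts/maskedlbp.R) dispatches to.

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with defaults reproducing the
#' reference protocol: 5 x 5 grid of 26 x 30 patches, full-face LBP codes,
#' RBF-SVM grid search with 5-fold CV, decision threshold at the
#' 95%-biometric-recall operating point, mean-over-used-patches distance
#' aggregation, and FAR report points 0.1% / 1% / 10%.
#'
#' @param grid The [patch_grid()].
#' @param lbp_per_patch Compute LBP codes per patch instead of full-face.
#' @param cost_grid,gamma_grid SVM hyper-parameter grids.
#' @param operating_point,recall Threshold operating point (see
#'   [choose_threshold()]).
#' @param class_weights Inverse-frequency SVM class weighting.
#' @param max_train_patches Cap on training patches (seeded subsample;
#'   `Inf` = use all).
#' @param mode Distance aggregation, `"mean"` or `"sum"`.
#' @param far_points FAR fractions reported by [cmd_evaluate()].
#' @param seed Master seed.
#' @param trial Gallery/probe cross-validation trial number.
#' @param log_file Optional path; stage messages are appended there as well
#'   as sent to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(grid = patch_grid(), lbp_per_patch = FALSE,
                       cost_grid = default_cost_grid(),
                       gamma_grid = default_gamma_grid(),
                       operating_point = "biometric_recall", recall = 0.95,
                       class_weights = FALSE, max_train_patches = Inf,
                       mode = "mean", far_points = c(0.001, 0.01, 0.1),
                       seed = 1L, trial = 1L, log_file = NULL) {
  structure(list(grid = grid, lbp_per_patch = lbp_per_patch,
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 operating_point = operating_point, recall = recall,
                 class_weights = class_weights,
                 max_train_patches = max_train_patches, mode = mode,
                 far_points = far_points, seed = as.integer(seed),
                 trial = as.integer(trial), log_file = log_file),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path JSON file with any subset of the [run_config()] scalar/vector
#'   fields (grid given as `m`, `n`, `patch_width`, `patch_height`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_keys <- c("m", "n", "patch_width", "patch_height")
  cfg_keys <- setdiff(names(formals(run_config)), "grid")
  unknown <- setdiff(names(j), c(grid_keys, cfg_keys))
  if (length(unknown))
    stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
  gargs <- j[intersect(names(j), grid_keys)]
  cargs <- j[intersect(names(j), cfg_keys)]
  cargs$grid <- do.call(patch_grid, gargs)
  do.call(run_config, cargs)
}

log_msg <- function(config, ...) {
  txt <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(txt)
  if (!is.null(config$log_file))
    cat(txt, "\n", file = config$log_file, append = TRUE)
  invisible(NULL)
}

## ---- in-memory experiment helpers -------------------------------------

#' Per-patch descriptors and ground-truth labels of a dataset split
#'
#' @param dataset Dataset list from [generate_dataset()] / [load_dataset()].
#' @param split `"train"` or `"test"`.
#' @param config A [run_config()].
#' @return List: `descriptors` (N x 512 matrix), `labels` (character), and
#'   `index` (data frame image_id, row, col).
#' @export
dataset_patch_data <- function(dataset, split = "train",
                               config = run_config()) {
  grid <- config$grid
  ids <- dataset$manifest$image_id[dataset$manifest$split == split]
  nk <- grid$m * grid$n
  desc <- matrix(0, length(ids) * nk, 512L)
  labels <- character(length(ids) * nk)
  idx <- vector("list", length(ids))
  for (q in seq_along(ids)) {
    iid <- ids[q]
    rows <- ((q - 1L) * nk + 1L):(q * nk)
    desc[rows, ] <- face_descriptors(dataset$images[[iid]], grid,
                                     per_patch = config$lbp_per_patch)
    labels[rows] <- as.vector(t(dataset$annotations[[iid]]$labels))
    idx[[q]] <- data.frame(image_id = iid,
                           row = rep(0:(grid$m - 1L), each = grid$n),
                           col = rep(0:(grid$n - 1L), times = grid$m))
  }
  list(descriptors = desc, labels = labels, index = do.call(rbind, idx))
}

#' Train the patch classifier on a dataset's training split
#'
#' Computes ITE descriptors for all training patches (optionally a seeded
#' subsample of at most `config$max_train_patches`, stratified by nothing but
#' the uniform draw) and runs [train_patch_classifier()].
#'
#' @param dataset Dataset list.
#' @param config A [run_config()].
#' @return A `patch_classifier`.
#' @export
fit_dataset_classifier <- function(dataset, config = run_config()) {
  td <- dataset_patch_data(dataset, "train", config)
  n <- nrow(td$descriptors)
  keep <- seq_len(n)
  if (is.finite(config$max_train_patches) && config$max_train_patches < n)
    keep <- sort(with_substream(config$seed, "train_subsample",
                                sample.int(n, config$max_train_patches)))
  subj <- stats::setNames(dataset$manifest$subject_id,
                          dataset$manifest$image_id)
  train_patch_classifier(td$descriptors[keep, , drop = FALSE],
                         td$labels[keep], seed = config$seed,
                         cost_grid = config$cost_grid,
                         gamma_grid = config$gamma_grid,
                         operating_point = config$operating_point,
                         recall = config$recall,
                         class_weights = config$class_weights,
                         groups = unname(subj[td$index$image_id[keep]]))
}

# Flags for one arm of the masking comparison.
arm_flags <- function(dataset, ids, arm, model = NULL,
                      config = run_config()) {
  grid <- config$grid
  switch(arm,
    all = NULL,
    ground_truth = lapply(dataset$annotations[ids], `[[`, "labels"),
    predicted = {
      if (is.null(model)) stop_invalid("arm 'predicted' needs a model")
      lapply(dataset$images[ids], function(px)
        flag_matrix(model, px, grid))
    },
    stop_invalid("unknown flag arm: ", arm))
}

#' Run one verification experiment arm
#'
#' Splits the test manifest into gallery and probe, computes per-patch LBP
#' histograms, builds per-image flags according to `arm` (`"predicted"` from
#' the SVM, `"ground_truth"` from annotations, `"all"` = every patch usable,
#' i.e. the plain-LBP baseline), scores all gallery x probe pairs with the
#' masked chi-squared distance and returns the scores plus the ROC.
#'
#' @param dataset Dataset list.
#' @param arm `"predicted"`, `"ground_truth"` or `"all"`.
#' @param model `patch_classifier`, required for `"predicted"`.
#' @param config A [run_config()].
#' @param hists Optional precomputed named list of per-image histogram
#'   matrices (shared across arms).
#' @return List: `scores` (data frame gallery_id, probe_id, is_genuine,
#'   distance, used_patches), `roc` (a `roc_curve`), `split` (gallery/probe
#'   ids).
#' @export
verification_experiment <- function(dataset, arm = "ground_truth",
                                    model = NULL, config = run_config(),
                                    hists = NULL) {
  grid <- config$grid
  sp <- gallery_probe_split(dataset$manifest, config$seed, config$trial)
  ids <- c(sp$gallery, sp$probe)
  if (is.null(hists))
    hists <- lapply(dataset$images[ids], face_lbp_histograms, grid = grid,
                    per_patch = config$lbp_per_patch)
  fg <- arm_flags(dataset, sp$gallery, arm, model, config)
  fp <- arm_flags(dataset, sp$probe, arm, model, config)
  res <- match_all_pairs(hists[sp$gallery], hists[sp$probe], fg, fp,
                         grid = grid, mode = config$mode)
  subj <- stats::setNames(dataset$manifest$subject_id,
                          dataset$manifest$image_id)
  genuine <- outer(subj[sp$gallery], subj[sp$probe], "==")
  scores <- data.frame(
    gallery_id = rep(sp$gallery, times = length(sp$probe)),
    probe_id = rep(sp$probe, each = length(sp$gallery)),
    is_genuine = as.vector(genuine),
    distance = as.vector(res$distance),
    used_patches = as.vector(res$used))
  roc <- roc_curve(scores$distance[scores$is_genuine],
                   scores$distance[!scores$is_genuine])
  list(scores = scores, roc = roc, split = sp, arm = arm)
}

## ---- disk-based stage commands -----------------------------------------

#' Load a generated dataset from disk
#'
#' Reads the layout written by [generate_dataset()] / [cmd_synth()]:
#' `manifest.csv`, `images/*.pgm|png`, `annotations/*.csv`.
#'
#' @param dir Dataset directory.
#' @return Dataset list (`manifest`, `images`, `annotations`).
#' @export
load_dataset <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  images <- list(); annotations <- list()
  for (q in seq_len(nrow(manifest))) {
    iid <- manifest$image_id[q]
    images[[iid]] <- read_face_image(file.path(dir, manifest$path[q]))
    ap <- file.path(dir, "annotations", paste0(iid, ".csv"))
    if (file.exists(ap)) annotations[[iid]] <- read_annotation_grid(ap)
  }
  list(manifest = manifest, images = images, annotations = annotations)
}

#' Stage command: generate a synthetic dataset on disk
#'
#' @param out_dir Output directory.
#' @param spec A [synthetic_spec()]; alternatively `spec_file`, a JSON file
#'   whose keys are scalar [synthetic_spec()] arguments.
#' @param spec_file Optional JSON path overriding `spec`.
#' @param config A [run_config()] (for logging and grid geometry).
#' @return The dataset, invisibly.
#' @export
cmd_synth <- function(out_dir, spec = synthetic_spec(grid = config$grid),
                      spec_file = NULL, config = run_config()) {
  if (!is.null(spec_file)) {
    j <- jsonlite::read_json(spec_file, simplifyVector = TRUE)
    ok <- intersect(names(j),
                    setdiff(names(formals(synthetic_spec)),
                            c("accessory_pool", "grid")))
    if ("total_images" %in% ok && !is.null(j$total_images))
      j$total_images <- unlist(j$total_images)
    spec <- do.call(synthetic_spec, c(j[ok], list(grid = config$grid)))
  }
  log_msg(config, "synth: ", spec$n_subjects, " subjects (",
          spec$n_train_subjects, " train), seed ", spec$seed,
          " -> ", out_dir)
  ds <- generate_dataset(spec, dir = out_dir)
  log_msg(config, "synth: wrote ", nrow(ds$manifest), " images")
  invisible(ds)
}

#' Stage command: train the patch classifier
#'
#' @param data_dir Dataset directory.
#' @param model_file Output model path (single RDS bundle).
#' @param config A [run_config()].
#' @return The trained model, invisibly.
#' @export
cmd_train <- function(data_dir, model_file, config = run_config()) {
  ds <- load_dataset(data_dir)
  log_msg(config, "train: ", sum(ds$manifest$split == "train"),
          " training images, grid search ",
          length(config$cost_grid), " x ", length(config$gamma_grid),
          ", seed ", config$seed)
  model <- fit_dataset_classifier(ds, config)
  save_patch_classifier(model, model_file)
  log_msg(config, "train: cost=", model$cost, " gamma=", model$gamma,
          " tau=", signif(model$tau, 4), " -> ", model_file)
  invisible(model)
}

#' Stage command: predict flag matrices for a split
#'
#' Writes a long CSV with columns `image_id`, `row`, `col`, `flag`.
#'
#' @param data_dir Dataset directory.
#' @param model_file Trained model path.
#' @param out_file Output CSV.
#' @param split Manifest split to flag.
#' @param config A [run_config()].
#' @return The flag table, invisibly.
#' @export
cmd_flags <- function(data_dir, model_file, out_file, split = "test",
                      config = run_config()) {
  ds <- load_dataset(data_dir)
  model <- load_patch_classifier(model_file)
  grid <- config$grid
  ids <- ds$manifest$image_id[ds$manifest$split == split]
  out <- vector("list", length(ids))
  for (q in seq_along(ids)) {
    f <- flag_matrix(model, ds$images[[ids[q]]], grid)
    out[[q]] <- data.frame(image_id = ids[q],
                           row = rep(0:(grid$m - 1L), times = grid$n),
                           col = rep(0:(grid$n - 1L), each = grid$m),
                           flag = as.vector(f))
  }
  tab <- do.call(rbind, out)
  utils::write.csv(tab, out_file, row.names = FALSE)
  log_msg(config, "flags: ", length(ids), " images -> ", out_file)
  invisible(tab)
}

read_flag_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df, df$image_id) |>
    lapply(function(d) {
      m <- max(d$row) + 1L; n <- max(d$col) + 1L
      f <- matrix(NA_character_, m, n)
      f[cbind(d$row + 1L, d$col + 1L)] <- d$flag
      f
    })
}

#' Stage command: score all gallery x probe pairs
#'
#' Writes a score CSV (`gallery_id`, `probe_id`, `is_genuine`, `distance`,
#' `used_patches`); infinite distances are serialized as `Inf`.
#'
#' @param data_dir Dataset directory.
#' @param out_file Output CSV.
#' @param arm `"predicted"`, `"ground_truth"` or `"all"`.
#' @param model_file Model path (needed for `"predicted"` unless `flags_file`
#'   is given).
#' @param flags_file Optional flag CSV from [cmd_flags()]; used instead of
#'   re-scoring when `arm = "predicted"`.
#' @param config A [run_config()].
#' @return The experiment result of [verification_experiment()], invisibly.
#' @export
cmd_match <- function(data_dir, out_file, arm = "predicted",
                      model_file = NULL, flags_file = NULL,
                      config = run_config()) {
  ds <- load_dataset(data_dir)
  model <- NULL
  if (arm == "predicted" && !is.null(flags_file)) {
    flags <- read_flag_csv(flags_file)
    ds$annotations[names(flags)] <-
      lapply(flags, function(f) list(labels = f, coverage = NULL))
    arm <- "ground_truth"  # reuse the annotation path with predicted flags
  } else if (arm == "predicted") {
    if (is.null(model_file)) stop_invalid("arm 'predicted' needs model_file")
    model <- load_patch_classifier(model_file)
  }
  res <- verification_experiment(ds, arm, model, config)
  utils::write.csv(res$scores, out_file, row.names = FALSE)
  log_msg(config, "match: ", nrow(res$scores), " pairs (",
          sum(res$scores$is_genuine), " genuine) -> ", out_file)
  invisible(res)
}

#' Stage command: evaluate a score file
#'
#' Builds the verification ROC and the GAR summary at the configured FAR
#' points; when `report_file` is given, writes the full (threshold, FAR, GAR)
#' curve plus the summary as CSVs.
#'
#' @param scores_file Score CSV from [cmd_match()] (or a data frame).
#' @param report_file Optional output CSV path for the curve;
#'   `<report_file>.summary.csv` gets the operating-point table.
#' @param config A [run_config()].
#' @return List: `roc`, `summary` (data frame far_pct, gar_pct), `eer_pct`,
#'   `n_infinite`.
#' @export
cmd_evaluate <- function(scores_file, report_file = NULL,
                         config = run_config()) {
  scores <- if (is.data.frame(scores_file)) scores_file else
    utils::read.csv(scores_file, stringsAsFactors = FALSE)
  scores$distance <- as.numeric(scores$distance)
  roc <- roc_curve(scores$distance[scores$is_genuine],
                   scores$distance[!scores$is_genuine])
  summary <- data.frame(
    far_pct = 100 * config$far_points,
    gar_pct = 100 * vapply(config$far_points, gar_at_far, numeric(1),
                           curve = roc))
  out <- list(roc = roc, summary = summary, eer_pct = 100 * eer(roc),
              n_infinite = attr(roc, "n_infinite"))
  if (!is.null(report_file)) {
    utils::write.csv(as.data.frame(roc), report_file, row.names = FALSE)
    utils::write.csv(summary, paste0(report_file, ".summary.csv"),
                     row.names = FALSE)
  }
  for (q in seq_len(nrow(summary)))
    log_msg(config, sprintf("evaluate: GAR @ %.1f%% FAR = %.1f%%",
                            summary$far_pct[q], summary$gar_pct[q]))
  out
}

#' Region-combination error analysis of a score file
#'
#' Assigns every evaluated pair the union of its two images' disguised
#' regions (per-image assignment available via `assignment = "per_image"`),
#' marks pairs misclassified at the acceptance threshold achieving
#' `far_target`, and tabulates the misclassified fraction per combination.
#'
#' @param scores Score data frame (from [cmd_match()]).
#' @param annotations Named list of `annotation_grid`s (or flag matrices) for
#'   all involved images.
#' @param far_target FAR fraction at which the decision threshold is placed.
#' @param assignment `"union"` (default) or `"per_image"`.
#' @return The [combo_error_table()] data frame.
#' @export
region_error_analysis <- function(scores, annotations, far_target = 0.01,
                                  assignment = c("union", "per_image")) {
  assignment <- match.arg(assignment)
  roc <- roc_curve(scores$distance[scores$is_genuine],
                   scores$distance[!scores$is_genuine])
  thr <- roc$threshold[which(roc$far <= far_target)]
  theta <- if (length(thr)) max(thr) else -Inf
  accepted <- verify(scores$distance, theta)
  correct <- accepted == scores$is_genuine
  get_flags <- function(id) {
    a <- annotations[[id]]
    if (inherits(a, "annotation_grid")) a$labels else a
  }
  if (assignment == "union") {
    combos <- mapply(function(g, p)
      pair_region_combo(get_flags(g), get_flags(p)),
      scores$gallery_id, scores$probe_id)
    combo_error_table(combos, correct)
  } else {
    combos <- c(vapply(scores$gallery_id,
                       function(g) region_combo(region_labels(get_flags(g))),
                       character(1)),
                vapply(scores$probe_id,
                       function(p) region_combo(region_labels(get_flags(p))),
                       character(1)))
    combo_error_table(combos, c(correct, correct))
  }
}
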