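test_that("subject prototypes are deterministic and mutually distinct", {
  p1 <- make_subject_prototype(101)
  p1b <- make_subject_prototype(101)
  expect_identical(p1, p1b)
  expect_equal(dim(p1), c(150L, 130L))
  expect_true(all(p1 >= 0 & p1 <= 255))

  p2 <- make_subject_prototype(202)
  d <- masked_distance(p1, p2)
  expect_gt(d$distance, 0)
  expect_equal(d$used_patches, 25L)
})

test_that("accessories overwrite their footprint and report coverage", {
  proto <- make_subject_prototype(7)
  # no accessory: identity handled by the annotate path on a zero map
  ann0 <- annotate(matrix(0, 150, 130))
  expect_true(all(ann0$labels == "biometric"))
  expect_true(all(ann0$coverage == 0))

  one_patch <- accessory_spec("cap_like",
                              c(x = 26, y = 0, width = 26, height = 30),
                              "uniform_dark", value = 10)
  res <- apply_accessory(proto, one_patch, jitter = 0)
  ann <- annotate(res$coverage)
  expect_equal(ann$coverage[1, 2], 1)
  expect_equal(sum(ann$coverage), 1)
  expect_equal(ann$labels[1, 2], "non_biometric")
  expect_equal(sum(ann$labels == "non_biometric"), 1L)
  # pixels outside the footprint untouched
  expect_identical(res$pixels[31:150, ], proto[31:150, ])

  sung <- default_accessory_pool()$sunglasses_like
  res2 <- apply_accessory(proto, sung, jitter = 3, jitter_seed = 9)
  ann2 <- annotate(res2$coverage)
  expect_true(all(ann2$coverage[2, ] > 0.5))
  expect_true(all(ann2$labels[2, ] == "non_biometric"))

  off_frame <- accessory_spec("cap_like",
                              c(x = 120, y = 0, width = 26, height = 30))
  expect_error(apply_accessory(proto, off_frame), "outside")
})

test_that("annotation applies the strict >50% coverage rule", {
  cov <- matrix(0, 150, 130)
  cov[1:30, 1:26][seq_len(round(0.51 * 780))] <- 1     # 51% of patch (0,0)
  cov[31:60, 1:26][seq_len(390)] <- 1                  # exactly 50% of (1,0)
  ann <- annotate(cov)
  expect_equal(ann$labels[1, 1], "non_biometric")
  expect_equal(ann$labels[2, 1], "biometric")
  expect_error(annotate(matrix(2, 150, 130)), "\\[0, 1\\]")
})

test_that("annotation grids round-trip through CSV", {
  ds <- tiny_dataset()
  ann <- ds$annotations[[5]]
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotation_grid(ann, f)
  back <- read_annotation_grid(f)
  expect_equal(back$labels, ann$labels)
  expect_equal(back$coverage, ann$coverage)
})

test_that("generated datasets respect the composition contract", {
  ds <- tiny_dataset()
  man <- ds$manifest
  for (sid in unique(man$subject_id)) {
    rows <- man[man$subject_id == sid, ]
    expect_gte(nrow(rows), 6L)
    expect_lte(nrow(rows), 10L)
    expect_gte(sum(rows$is_neutral), 1L)
    expect_gte(sum(!rows$is_neutral), 5L)
  }
  # neutral images carry no coverage; disguised images carry some
  for (q in seq_len(nrow(man))) {
    cov <- ds$annotations[[man$image_id[q]]]$coverage
    if (man$is_neutral[q]) expect_equal(sum(cov), 0)
    else expect_gt(sum(cov), 0)
  }
})

test_that("dataset generation is seed-deterministic", {
  spec <- synthetic_spec(n_subjects = 4, n_train_subjects = 2,
                         total_images = NULL, seed = 31)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$images, d2$images)
  d3 <- generate_dataset(synthetic_spec(n_subjects = 4, n_train_subjects = 2,
                                        total_images = NULL, seed = 32))
  expect_false(identical(d1$manifest$is_neutral, d3$manifest$is_neutral) &&
                 identical(d1$images[[1]], d3$images[[1]]))
})

test_that("infeasible specs are rejected upfront", {
  expect_error(synthetic_spec(images_per_subject = c(5, 10)),
               "infeasible")
  expect_error(synthetic_spec(n_subjects = 10, n_train_subjects = 5,
                              total_images = c(train = 51, test = 30)),
               "infeasible")
  expect_error(synthetic_spec(n_subjects = 4, n_train_subjects = 4),
               "at least one test subject")
})

test_that("split totals hit their per-split targets exactly", {
  spec <- synthetic_spec(n_subjects = 12, n_train_subjects = 6,
                         total_images = c(train = 50, test = 49), seed = 3)
  ds <- generate_dataset(spec)
  expect_equal(sum(ds$manifest$split == "train"), 50L)
  expect_equal(sum(ds$manifest$split == "test"), 49L)
})

test_that("gallery/probe split takes 1 neutral + 4 others per subject", {
  ds <- tiny_dataset()
  sp <- gallery_probe_split(ds$manifest, seed = 5)
  man <- ds$manifest
  test_subj <- unique(man$subject_id[man$split == "test"])
  expect_length(sp$gallery, 5L * length(test_subj))
  expect_length(intersect(sp$gallery, sp$probe), 0L)
  neutral_ids <- man$image_id[man$is_neutral]
  for (sid in test_subj) {
    g <- sp$gallery[sp$gallery %in% man$image_id[man$subject_id == sid]]
    expect_length(g, 5L)
    expect_gte(length(intersect(g, neutral_ids)), 1L)
    n_im <- sum(man$subject_id == sid & man$split == "test")
    p <- sp$probe[sp$probe %in% man$image_id[man$subject_id == sid]]
    expect_length(p, n_im - 5L)
  }
  expect_identical(gallery_probe_split(ds$manifest, seed = 5), sp)
  expect_false(identical(gallery_probe_split(ds$manifest, seed = 5, trial = 2),
                         sp))
  short <- man[man$split == "test", ][1:4, ]
  expect_error(gallery_probe_split(transform(short, split = "test")),
               "fewer than 5")
})

test_that("genuine pairs score below impostor pairs under truth masks", {
  ds <- tiny_dataset()
  cfg <- run_config(seed = 9)
  ex <- verification_experiment(ds, "ground_truth", config = cfg)
  gen <- ex$scores$distance[ex$scores$is_genuine]
  imp <- ex$scores$distance[!ex$scores$is_genuine]
  expect_lt(median(gen[is.finite(gen)]), median(imp[is.finite(imp)]))
})
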