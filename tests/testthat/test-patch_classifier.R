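test_that("separable descriptor clouds train to perfect CV accuracy", {
  fx <- separable_descriptors(20)
  m <- train_patch_classifier(fx$x, fx$labels, seed = 5,
                              cost_grid = c(2, 32), gamma_grid = c(2^-7, 2^-3))
  expect_s3_class(m, "patch_classifier")
  expect_equal(max(m$cv_table$cv_accuracy), 1)
  # polarity: biometric cluster scores below tau, non-biometric at/above
  s <- score_patch(m, fx$x)
  expect_true(all(s[fx$labels == "biometric"] < m$tau))
  expect_true(all(s[fx$labels == "non_biometric"] >= m$tau))
})

test_that("training is deterministic given the seed", {
  fx <- separable_descriptors(15)
  m1 <- train_patch_classifier(fx$x, fx$labels, seed = 8,
                               cost_grid = c(2, 512), gamma_grid = c(2^-9, 2^-3))
  m2 <- train_patch_classifier(fx$x, fx$labels, seed = 8,
                               cost_grid = c(2, 512), gamma_grid = c(2^-9, 2^-3))
  expect_identical(c(m1$cost, m1$gamma, m1$tau), c(m2$cost, m2$gamma, m2$tau))
  expect_identical(m1$cv_table, m2$cv_table)
  d <- fx$x[3, ]
  expect_identical(score_patch(m1, d), score_patch(m1, d))
})

test_that("conflicting duplicate labels bound CV accuracy near chance", {
  set.seed(44)
  row <- runif(64)
  x <- matrix(rep(row, 40), nrow = 40, byrow = TRUE)
  labels <- rep(c("biometric", "non_biometric"), 20)
  m <- train_patch_classifier(x, labels, seed = 2,
                              cost_grid = 2, gamma_grid = 2^-5)
  expect_lte(max(m$cv_table$cv_accuracy), 0.55)
})

test_that("single-class input is a training error", {
  fx <- separable_descriptors(10)
  expect_error(train_patch_classifier(fx$x[1:10, ], rep("biometric", 10)),
               "both patch classes")
})

test_that("classify_patch applies the strict-inequality threshold rule", {
  tau <- 0.3
  expect_equal(classify_patch(tau - 0.001, tau), "biometric")
  expect_equal(classify_patch(tau, tau), "non_biometric")
  expect_equal(classify_patch(tau + 1, tau), "non_biometric")
  # monotone in s for fixed tau
  s <- sort(rnorm(50))
  lab <- classify_patch(s, tau)
  expect_true(all(diff(lab == "non_biometric") >= 0))
})

test_that("choose_threshold hits requested operating points", {
  scores <- c(-3, -2.5, -2, -1, 1, 1.5, 2, 3)
  labels <- rep(c("biometric", "non_biometric"), each = 4)
  t_eer <- choose_threshold(scores, labels, "eer")
  pred <- classify_patch(scores, t_eer)
  expect_equal(sum(pred != labels), 0)  # separable: EER threshold is perfect

  # recall 1.0 sits just above the maximum biometric score
  t_full <- choose_threshold(scores, labels, "biometric_recall", recall = 1)
  expect_true(t_full > -1 && all(scores[labels == "biometric"] < t_full))

  # 20 random scores: agrees with exhaustive sweep
  set.seed(55)
  s20 <- rnorm(20)
  l20 <- sample(c("biometric", "non_biometric"), 20, replace = TRUE,
                prob = c(0.7, 0.3))
  for (r in c(0.5, 0.8, 0.95, 1)) {
    expect_equal(choose_threshold(s20, l20, "biometric_recall", r),
                 brute_recall_threshold(s20, l20, r))
  }
  expect_error(choose_threshold(s20, l20, "biometric_recall", recall = 1.2),
               "unattainable")
})

test_that("classification AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(66)
  s <- rnorm(60)
  lab <- sample(c("biometric", "non_biometric"), 60, replace = TRUE)
  ours <- classification_auc(s, lab)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(lab, levels = c("biometric", "non_biometric")),
    predictor = s, direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})

test_that("flag matrices recover an easy synthetic occlusion", {
  ds <- tiny_dataset()
  cfg <- run_config(cost_grid = tiny_grid_svm()$cost,
                    gamma_grid = tiny_grid_svm()$gamma, seed = 4)
  m <- fit_dataset_classifier(ds, cfg)
  grid <- patch_grid()
  proto <- make_subject_prototype(123456, grid)

  f_clean <- flag_matrix(m, proto, grid)
  expect_equal(dim(f_clean), c(5L, 5L))
  expect_true(mean(f_clean == "biometric") >= 0.95)

  # accessory covering exactly the eye row -> that row flagged non-biometric
  acc <- accessory_spec("sunglasses_like",
                        c(x = 0, y = 30, width = 130, height = 30),
                        "uniform_dark", value = 20)
  occ <- apply_accessory(proto, acc, jitter = 0)
  f_occ <- flag_matrix(m, occ$pixels, grid)
  expect_true(all(f_occ[2, ] == "non_biometric"))
  expect_true(mean(f_occ[-2, ] == "biometric") >= 0.9)
})

test_that("classifier persistence round-trips", {
  fx <- separable_descriptors(10)
  m <- train_patch_classifier(fx$x, fx$labels, seed = 1,
                              cost_grid = 2, gamma_grid = 2^-5)
  f <- withr::local_tempfile(fileext = ".rds")
  save_patch_classifier(m, f)
  m2 <- load_patch_classifier(f)
  expect_identical(score_patch(m2, fx$x[1, ]), score_patch(m, fx$x[1, ]))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, bad)
  expect_error(load_patch_classifier(bad), "not a patch_classifier")
})
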