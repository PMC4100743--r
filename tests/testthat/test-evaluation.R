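test_that("verification rates follow the count formulas", {
  perfect <- rates(ga = 4, fa = 0, gr = 4, fr = 0)
  expect_equal(perfect[c("gar", "far", "accuracy")],
               list(gar = 100, far = 0, accuracy = 100))
  mixed <- rates(ga = 3, fa = 1, gr = 3, fr = 1)
  expect_equal(mixed[c("gar", "far", "accuracy")],
               list(gar = 75, far = 25, accuracy = 75))
  inverted <- rates(ga = 0, fa = 4, gr = 0, fr = 4)
  expect_equal(inverted[c("gar", "far", "accuracy")],
               list(gar = 0, far = 100, accuracy = 0))
  expect_error(rates(0, 1, 1, 0), "no genuine")
  expect_error(rates(1, 0, 0, 1), "no impostor")
})

test_that("rate complements conserve per-class totals", {
  set.seed(10)
  for (rep in 1:5) {
    c4 <- rmultinom(1, 40, rep(0.25, 4)) + 1
    r <- rates(c4[1], c4[2], c4[3], c4[4])
    frr <- 100 * c4[4] / (c4[1] + c4[4])
    grr <- 100 * c4[3] / (c4[2] + c4[3])
    expect_equal(r$gar + frr, 100)
    expect_equal(r$far + grr, 100)
  }
})

test_that("ROC handles separated, chance-level and toy distributions", {
  sep <- roc_curve(genuine = c(1, 2, 3), impostor = c(10, 11, 12))
  expect_equal(eer(sep), 0)
  expect_equal(gar_at_far(sep, 0.001), 1)
  expect_equal(gar_at_far(sep, 0.1), 1)

  same <- roc_curve(genuine = 1:20, impostor = 1:20)
  expect_equal(eer(same), 0.5, tolerance = 0.05)
  expect_equal(gar_at_far(same, 0.25), 0.25, tolerance = 0.06)

  expect_error(roc_curve(numeric(0), 1:3), "at least one")
  expect_error(roc_curve(c(Inf, Inf), c(Inf)), "infinite")
})

test_that("ROC sweep matches exhaustive enumeration on a toy set", {
  set.seed(23)
  gen <- round(runif(6, 0, 5), 2)
  imp <- round(runif(4, 0, 5), 2)
  curve <- roc_curve(gen, imp)
  ref <- brute_roc(gen, imp)
  expect_equal(curve$threshold, ref$threshold)
  expect_equal(curve$far, ref$far)
  expect_equal(curve$gar, ref$gar)
  expect_true(all(diff(curve$far) >= 0))
  expect_true(all(diff(curve$gar) >= 0))
})

test_that("ROC is invariant under strictly monotone distance transforms", {
  set.seed(29)
  gen <- runif(15); imp <- runif(15) + 0.3
  c1 <- roc_curve(gen, imp)
  c2 <- roc_curve(exp(3 * gen), exp(3 * imp))
  expect_equal(c1$far, c2$far)
  expect_equal(c1$gar, c2$gar)
  expect_equal(eer(c1), eer(c2))
  for (f in c(0.01, 0.1, 0.5))
    expect_equal(gar_at_far(c1, f), gar_at_far(c2, f))
})

test_that("infinite distances count as rejections everywhere", {
  curve <- roc_curve(c(0.1, 0.2, Inf, Inf), c(0.5, Inf))
  expect_equal(attr(curve, "n_infinite"), 3L)
  expect_equal(max(curve$gar), 0.5)  # the Inf genuine pairs never accept
  expect_equal(max(curve$far), 0.5)
})

test_that("region labelling follows the strict-majority row rule", {
  clean <- matrix("biometric", 5, 5)
  expect_length(region_labels(clean), 0)

  eyes <- clean; eyes[2, 1:3] <- "non_biometric"
  expect_equal(region_labels(eyes), "eyes")
  eyes2 <- clean; eyes2[2, 1:2] <- "non_biometric"  # only 2 of 5
  expect_length(region_labels(eyes2), 0)

  lips5 <- clean; lips5[4, ] <- "non_biometric"     # 5 of 10: not disguised
  expect_length(region_labels(lips5), 0)
  lips6 <- lips5; lips6[5, 1] <- "non_biometric"    # 6 of 10: disguised
  expect_equal(region_labels(lips6), "lips_chin")

  expect_error(region_labels(matrix("biometric", 4, 5)), "5 x 5")
})

test_that("16 region combinations enumerate and label canonically", {
  combos <- all_region_combos()
  expect_length(combos, 16L)
  expect_length(unique(combos), 16L)
  expect_equal(region_combo(character(0)), "none")
  expect_equal(region_combo(c("nose", "forehead")), "forehead+nose")
  expect_error(region_combo("ears"), "unknown regions")
})

test_that("pair combination is the union of the two images' regions", {
  clean <- matrix("biometric", 5, 5)
  eyes <- clean; eyes[2, ] <- "non_biometric"
  nose <- clean; nose[3, ] <- "non_biometric"
  expect_equal(pair_region_combo(eyes, nose), "eyes+nose")
  expect_equal(pair_region_combo(clean, clean), "none")
})

test_that("combination error table reproduces the worked 10/31 fraction", {
  combos <- c(rep("eyes", 31), rep("none", 9))
  correct <- c(rep(FALSE, 10), rep(TRUE, 21), rep(TRUE, 9))
  tab <- combo_error_table(combos, correct)
  expect_equal(nrow(tab), 16L)
  eyes_row <- tab[tab$combo == "eyes", ]
  expect_equal(eyes_row$n, 31L)
  expect_equal(eyes_row$fraction, 10 / 31)
  expect_equal(tab$fraction[tab$combo == "none"], 0)
  expect_true(all(is.na(tab$fraction) | (tab$fraction >= 0 & tab$fraction <= 1)))
  expect_equal(sum(tab$n), length(combos))
  expect_true(all(is.na(tab$fraction[tab$n == 0])))
})
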