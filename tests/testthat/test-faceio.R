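test_that("to_grayscale handles gray, equal-channel and pure-colour input", {
  g <- matrix(seq(0, 255, length.out = 12), 3, 4)
  expect_identical(to_grayscale(g), g)

  eq <- array(100, dim = c(4, 4, 3))
  expect_equal(to_grayscale(eq), matrix(100, 4, 4))

  red <- array(0, dim = c(3, 3, 3)); red[, , 1] <- 255
  blue <- array(0, dim = c(3, 3, 3)); blue[, , 3] <- 255
  expect_equal(unique(as.vector(to_grayscale(red))), 0.299 * 255)
  expect_equal(unique(as.vector(to_grayscale(blue))), 0.114 * 255)

  expect_error(to_grayscale(matrix(numeric(0), 0, 0)), "empty")
  expect_error(to_grayscale(matrix(300, 2, 2)), "outside")
})

test_that("to_grayscale preserves the 8-bit value range", {
  set.seed(1)
  for (rep in 1:5) {
    a <- array(runif(4 * 5 * 3, 0, 255), dim = c(4, 5, 3))
    g <- to_grayscale(a)
    expect_true(all(g >= 0 & g <= 255))
  }
})

test_that("normalize_face is the identity for already-canonical eyes", {
  grid <- patch_grid()
  can <- maskedlbp:::canonical_eye_positions(grid)
  set.seed(7)
  img <- matrix(round(runif(grid$face_height * grid$face_width, 0, 255)),
                grid$face_height, grid$face_width)
  out <- normalize_face(img, can$left, can$right, grid)
  expect_equal(out$pixels, img)
  # idempotence: renormalizing the canonical output changes nothing
  out2 <- normalize_face(out$pixels, can$left, can$right, grid)
  expect_equal(out2$pixels, out$pixels)
})

test_that("normalize_face validates eye geometry", {
  img <- matrix(0, 150, 130)
  expect_error(normalize_face(img, c(50, 50), c(50, 50)), "degenerate")
  # mirrored input with swapped labels: eye_right not right of eye_left
  expect_error(normalize_face(img, c(91, 45), c(39, 45)), "right of")
})

test_that("normalize_face applies the documented similarity transform", {
  # On a linear ramp image I(x, y) = 2x + y the bilinearly resampled output
  # must equal the ramp evaluated at the transformed coordinates exactly.
  grid <- patch_grid()
  can <- maskedlbp:::canonical_eye_positions(grid)
  h <- 300; w <- 260
  img <- outer(0:(h - 1), 0:(w - 1), function(y, x) (2 * x + y) / 8)
  # eyes at twice the canonical separation, pure scale about the left eye
  el <- c(60, 80)
  er <- el + 2 * c(can$right["x"] - can$left["x"], 0)
  out <- normalize_face(img, el, er, grid)
  xo <- rep(0:(grid$face_width - 1), each = grid$face_height)
  yo <- rep(0:(grid$face_height - 1), times = grid$face_width)
  xs <- el[1] + 2 * (xo - can$left["x"])
  ys <- el[2] + 2 * (yo - can$left["y"])
  expected <- ifelse(xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1,
                     (2 * xs + ys) / 8, 0)
  expect_equal(as.vector(out$pixels), expected, tolerance = 1e-10)
})

test_that("elliptical mask zeroes corners, keeps centre, covers ~pi/4", {
  face <- matrix(255, 150, 130)
  masked <- apply_elliptical_mask(face)
  expect_equal(masked[1, 1], 0)
  expect_equal(masked[1, 130], 0)
  expect_equal(masked[150, 1], 0)
  expect_equal(masked[75, 65], 255)
  expect_equal(mean(masked > 0), pi / 4, tolerance = 0.01)
})

test_that("tessellate partitions the face into the documented grid", {
  grid <- patch_grid()
  set.seed(3)
  px <- matrix(round(runif(150 * 130, 0, 255)), 150, 130)
  patches <- tessellate(px, grid)
  expect_length(patches, 25L)
  for (p in patches) expect_equal(dim(p$pixels), c(30L, 26L))
  # reassembly equality: every pixel in exactly one patch
  rebuilt <- matrix(NA_real_, 150, 130)
  for (p in patches) {
    b <- maskedlbp:::patch_bounds(grid, p$row_index, p$col_index)
    rebuilt[b$rows, b$cols] <- p$pixels
  }
  expect_identical(rebuilt, px)
  expect_equal(sum(vapply(patches, function(p) sum(p$pixels), numeric(1))),
               sum(px))

  one <- tessellate(px, patch_grid(1, 1, 130, 150))
  expect_length(one, 1L)
  expect_identical(one[[1]]$pixels, px)

  expect_error(tessellate(px[-1, ], grid), "grid mismatch")
})

test_that("PGM and PNG round-trips preserve pixels", {
  set.seed(11)
  img <- matrix(round(runif(30 * 20, 0, 255)), 30, 20)
  pgm <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(img, pgm)
  expect_equal(read_pgm(pgm), img)
  png_path <- withr::local_tempfile(fileext = ".png")
  write_face_image(img, png_path)
  expect_equal(read_face_image(png_path), img, tolerance = 1e-8)
})

test_that("manifest round-trips with required columns", {
  m <- data.frame(image_id = c("a", "b"), subject_id = c("s1", "s1"),
                  path = c("images/a.pgm", "images/b.pgm"),
                  is_neutral = c(TRUE, FALSE), split = c("train", "train"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, f)
  expect_equal(read_manifest(f), m)
  bad <- m[, -4]
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(read_manifest(f2), "missing columns")
})
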