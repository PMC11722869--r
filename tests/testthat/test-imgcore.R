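test_that("gray_image and edge_map enforce their invariants", {
  expect_error(gray_image(matrix(0.5, 2, 5)), "at least 3x3")
  expect_error(gray_image(matrix(1.5, 4, 4)), "\\[0, 1\\]")
  expect_error(gray_image(matrix(NA_real_, 4, 4)), "finite")
  expect_error(edge_map(matrix(0.5, 3, 3)), "0 or 1")
  em <- edge_map(matrix(c(0, 1), 4, 4))
  expect_true(all(em %in% 0:1))
  expect_error(match_edges(edge_map(matrix(0, 3, 3)),
                           edge_map(matrix(0, 4, 4))), "shape mismatch")
})

test_that("8-bit loading divides by 255 and converts RGB via BT.601 luminance", {
  tmp <- withr::local_tempdir()
  # plain-text PGM with center pixel 128
  pgm <- file.path(tmp, "center.pgm")
  writeLines(c("P2", "3 3", "255", "0 0 0", "0 128 0", "0 0 0"), pgm)
  img <- load_image(pgm)
  expect_equal(img[2, 2], 128 / 255, tolerance = 1e-12)
  expect_equal(img[1, 1], 0)
  # all-255 and all-0 raw PGM round extremes
  save_image(gray_image(matrix(1, 4, 4)), file.path(tmp, "w.pgm"))
  expect_equal(max(abs(load_image(file.path(tmp, "w.pgm")) - 1)), 0)
  save_image(gray_image(matrix(0, 4, 4)), file.path(tmp, "b.png"))
  expect_equal(max(abs(load_image(file.path(tmp, "b.png")))), 0)
  # RGB PNG: luminance weights
  arr <- array(0, c(4, 4, 3))
  arr[, , 1] <- 1  # pure red
  rgb_path <- file.path(tmp, "red.png")
  png::writePNG(arr, rgb_path)
  expect_equal(load_image(rgb_path)[1, 1], 0.299, tolerance = 1 / 255)
  expect_error(load_image(file.path(tmp, "absent.png")), "not found")
})

test_that("8-bit save/load round trip is exact to half a quantization step", {
  tmp <- withr::local_tempdir()
  img <- random_smooth_image(32, 32, seed = 5)
  for (ext in c("png", "tif", "pgm")) {
    p <- file.path(tmp, paste0("rt.", ext))
    save_image(img, p)
    back <- load_image(p)
    expect_lt(max(abs(back - img)), 1 / 510 + 1e-12)
  }
})

test_that("edge maps binarize on load and round trip as {0,255} images", {
  tmp <- withr::local_tempdir()
  gt <- edge_map(matrix(sample(c(0, 1), 64, replace = TRUE), 8, 8))
  p <- file.path(tmp, "gt.png")
  save_edge_map(gt, p)
  expect_identical(unclass(load_edge_map(p, 0.5)), unclass(gt))
  # pixel value 100/255 < 0.5 stays off
  writeLines(c("P2", "3 3", "255", "0 0 0", "0 100 0", "0 0 0"),
             file.path(tmp, "dim.pgm"))
  expect_equal(sum(load_edge_map(file.path(tmp, "dim.pgm"), 0.5)), 0)
})

test_that("convolve2d matches a brute-force loop oracle and its contracts", {
  img <- unclass(random_smooth_image(12, 11, seed = 2))
  kernels <- list(
    identity = matrix(1, 1, 1),
    sobel = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE),
    box = matrix(1 / 9, 3, 3),
    asym = matrix(c(1, -2, 0.5, 0, 3, -1, 2, 0, -0.5, 1, 0, 4, 1, -1, 2),
                  3, 5)
  )
  for (k in kernels) {
    expect_equal(convolve2d(img, k), bf_convolve(img, k), tolerance = 1e-12)
  }
  expect_identical(convolve2d(img, kernels$identity), img)
  # zero-sum kernel annihilates constants; unit-sum preserves them
  expect_equal(max(abs(convolve2d(matrix(0.7, 9, 9), kernels$sobel))), 0)
  expect_equal(convolve2d(matrix(0.7, 9, 9), kernels$box),
               matrix(0.7, 9, 9), tolerance = 1e-12)
  expect_error(convolve2d(img, matrix(1, 2, 2)), "odd")
  expect_error(convolve2d(matrix(0, 3, 3), matrix(1, 5, 5)), "smaller")
})

test_that("convolve2d is linear and gives the hand Sobel step response", {
  a <- unclass(random_smooth_image(10, 10, seed = 3))
  b <- unclass(random_smooth_image(10, 10, seed = 4))
  k <- matrix(rnorm(9), 3, 3)
  lhs <- convolve2d(2.5 * a + 0.3 * b, k)
  rhs <- 2.5 * convolve2d(a, k) + 0.3 * convolve2d(b, k)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  # columns (0,0,1,1): |gx| = 4 at the two step-adjacent columns, 0 outside
  step <- cbind(matrix(0, 3, 2), matrix(1, 3, 2))
  gx <- convolve2d(step, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3,
                                byrow = TRUE))
  expect_equal(abs(gx[2, ]), c(0, 4, 4, 0))
})
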