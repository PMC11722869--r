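test_that("gradient fields obey the magnitude identity and step response", {
  img <- random_smooth_image(24, 24, seed = 6)
  for (op in c("sobel", "prewitt", "roberts")) {
    g <- gradient(img, op)
    expect_lt(max(abs(g$magnitude - sqrt(g$gx^2 + g$gy^2))), 1e-9)
    expect_equal(dim(g$gx), dim(img))
    # constant image: flat field
    expect_equal(max(gradient(gray_image(matrix(0.3, 8, 8)), op)$magnitude), 0)
  }
  # columns (0,0,1,1): |gx| = 4 at step-adjacent columns for Sobel
  g <- gradient(step_image(5, 2, 2), "sobel")
  expect_equal(abs(g$gx[3, ]), c(0, 4, 4, 0))
  expect_equal(max(abs(g$gy)), 0)
  # transposing the image swaps and transposes the components
  gt_ <- gradient(gray_image(t(unclass(img))), "sobel")
  expect_lt(max(abs(gt_$magnitude - t(gradient(img, "sobel")$magnitude))),
            1e-9)
})

test_that("rotating the image 90 degrees rotates the sobel/prewitt magnitude", {
  img <- random_smooth_image(20, 20, seed = 7)
  rot <- function(m) t(m[nrow(m):1, , drop = FALSE])
  for (op in c("sobel", "prewitt")) {
    m1 <- gradient(gray_image(rot(unclass(img))), op)$magnitude
    m2 <- rot(gradient(img, op)$magnitude)
    expect_lt(max(abs(m1 - m2)), 1e-9)
  }
})

test_that("thresholded detection marks the max-response step and nothing else", {
  img <- step_image(8, 4, 4)
  det <- detect(img, detector_params("sobel", threshold = 0.5))
  expect_true(all(det[, c(4, 5)] == 1))
  expect_true(all(det[, c(1:3, 6:8)] == 0))
  # constant image gives an empty map for every operator
  flat <- gray_image(matrix(0.42, 32, 32))
  expect_equal(sum(detect(flat, detector_params("sobel", threshold = 0.1))), 0)
  expect_equal(sum(detect(flat, detector_params("log", threshold = 0.05))), 0)
  expect_equal(sum(detect(flat, detector_params("canny", low = 0.1,
                                                high = 0.3))), 0)
  expect_equal(sum(standard_detect(flat, "roberts")), 0)
})

test_that("raising the threshold never adds edge pixels, for all operators", {
  img <- as_gray_image(unclass(apply_noise(random_smooth_image(48, 48, 8),
                                           noise_spec("gaussian", 0.01, 5))))
  ths <- c(0.05, 0.15, 0.3, 0.5, 0.7, 0.9)
  for (op in c("sobel", "prewitt", "roberts", "log")) {
    prev <- NULL
    for (t in ths) {
      cur <- detect(img, detector_params(op, threshold = t))
      if (!is.null(prev)) expect_true(all(cur <= prev))
      prev <- cur
    }
  }
  # canny with the low/high ratio fixed
  prev <- NULL
  for (hi in ths) {
    cur <- detect(img, detector_params("canny", low = 0.4 * hi, high = hi))
    if (!is.null(prev)) expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("LoG marks zero-crossing bands on steps and respects its threshold", {
  img <- step_image(16, 8, 8)
  lo <- detect(img, detector_params("log", threshold = 0.01))
  # a crossing band exists along the step
  expect_gt(sum(lo[, 7:10]), 0)
  # oracle: direct sign-change scan of the response reproduced through a
  # near-zero threshold
  hi <- detect(img, detector_params("log", threshold = 0.8))
  expect_true(all(hi <= lo))
})

test_that("canny NMS keeps no pixel dominated along its gradient direction and
           hysteresis output is 8-connected to strong pixels", {
  ph <- make_phantom("MD", c(64, 64), seed = 12)
  img <- apply_noise(ph$image, noise_spec("gaussian", 0.005, 3))
  low <- 0.1
  high <- 0.3
  det <- detect(img, detector_params("canny", low = low, high = high))
  # recompute the front end to inspect magnitudes
  resp <- edgethresh:::response_canny(as_gray_image(img), 1.4)
  expect_true(all(det[!resp$nms] == 0))
  # every output pixel is weak or better, and flood-filling the output from
  # its strong pixels reaches all of it (connectivity property)
  expect_true(all(resp$mag[det == 1] >= low))
  strong_in_out <- det == 1 & resp$mag >= high
  expect_gt(sum(strong_in_out), 0)
  reached <- edgethresh:::hysteresis_fill(strong_in_out, det == 1)
  expect_identical(unclass(reached), unclass(unclass(det)))
})

test_that("a clean vertical step yields a single 1-px canny line with F = 1", {
  img <- step_image(32, 16, 16)
  det <- detect(img, detector_params("canny", low = 0.2, high = 0.5))
  cols <- colSums(unclass(det))
  expect_equal(sum(cols > 0), 1)          # exactly one column marked
  expect_true(all(det[, cols > 0] == 1))  # the full line
  gt <- edge_map(col(matrix(0, 32, 32)) == which(cols > 0))
  expect_equal(f_measure(det, gt, tolerance = 0), 1)
})

test_that("the standard baseline equals detection at the Otsu threshold", {
  ph <- make_phantom("LD", c(64, 64), seed = 4)
  img <- apply_noise(ph$image, noise_spec("speckle", 0.05, 9))
  det <- standard_detect(img, "sobel")
  par <- attr(det, "params")
  redo <- detect(img, par)
  stripped <- det
  attr(stripped, "params") <- NULL
  expect_identical(unclass(stripped), unclass(redo))
  # brute-force Otsu oracle on a bimodal step histogram
  vals <- c(rep(0.1, 600), rep(0.9, 400))
  th <- otsu_threshold(vals)
  bins <- (1:256) / 256
  crit <- sapply(bins, function(t) {
    w0 <- mean(vals < t)
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    (mean(vals[vals < t]) - mean(vals[vals >= t]))^2 * w0 * w1
  })
  expect_equal(th, bins[which.max(crit)], tolerance = 1 / 256)
  expect_gt(th, 0.1)
  expect_lt(th, 0.9)
})

test_that("detect dispatches to the operator-specific implementations", {
  img <- random_smooth_image(32, 32, seed = 9)
  p1 <- detector_params("sobel", threshold = 0.5)
  expect_identical(unclass(detect(img, p1)),
                   unclass(detect_gradient_operator(img, p1)))
  p2 <- detector_params("canny", low = 0.1, high = 0.3)
  expect_identical(unclass(detect(img, p2)), unclass(detect_canny(img, p2)))
  p3 <- detector_params("log", threshold = 0.2)
  expect_identical(unclass(detect(img, p3)), unclass(detect_log(img, p3)))
  expect_error(detector_params("canny", low = 0.5, high = 0.2), "low < high")
  expect_error(detector_params("sobel", threshold = 1.2), "\\(0, 1\\)")
})
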