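test_that("the default dataset stores 1800 values: 300 per single operator,
           600 for canny", {
  ds <- generate_threshold_dataset()
  expect_equal(n_threshold_values(ds), 1800)
  expect_true(all(lengths(ds$single) == 300))
  expect_equal(nrow(ds$canny), 300)
  # candidate lists are sorted, duplicate-free, inside (0,1)
  for (v in ds$single) {
    expect_true(all(diff(v) > 0))
    expect_true(min(v) > 0 && max(v) < 1)
  }
  expect_true(all(ds$canny$low < ds$canny$high))
  expect_equal(ds$canny$low, 0.4 * ds$canny$high, tolerance = 1e-12)
  # grid construction: single candidate sits at the midpoint
  expect_equal(generate_threshold_dataset(1, 1)$single$sobel, 0.5)
  expect_error(generate_threshold_dataset(0, 10), "count_single")
})

test_that("threshold datasets round-trip through CSV", {
  tmp <- withr::local_tempdir()
  ds <- generate_threshold_dataset(17, 9, low_ratio = 0.3)
  p <- file.path(tmp, "thresholds.csv")
  write_threshold_dataset(ds, p)
  back <- read_threshold_dataset(p)
  expect_equal(back$single, ds$single, tolerance = 1e-12)
  expect_equal(back$canny, ds$canny, tolerance = 1e-12)
  expect_equal(n_threshold_values(back), n_threshold_values(ds))
})

test_that("grid search returns exactly the best of an exhaustive detect loop", {
  ds <- generate_threshold_dataset(25, 25)
  for (s in 1:4) {
    ph <- make_phantom(c("LD", "MD", "HD")[1 + s %% 3], c(64, 64), seed = s)
    img <- apply_noise(ph$image, noise_spec("gaussian", 0.01, seed = s))
    for (op in c("sobel", "log", "canny")) {
      res <- grid_search(img, ph$gt, op, ds, metric = "f", tolerance = 1)
      cand <- if (op == "canny") ds$canny else data.frame(value = ds$single[[op]])
      scores <- sapply(seq_len(nrow(cand)), function(i) {
        par <- if (op == "canny") {
          detector_params("canny", low = cand$low[i], high = cand$high[i])
        } else {
          detector_params(op, threshold = cand$value[i])
        }
        f_measure(detect(img, par), ph$gt, tolerance = 1)
      })
      expect_equal(res$score, max(scores), tolerance = 1e-12)
      # tie-break toward the smallest (first) candidate
      first <- which(scores == max(scores))[1]
      if (op == "canny") {
        expect_equal(res$best$high, cand$high[first], tolerance = 1e-12)
      } else {
        expect_equal(res$best$threshold, cand$value[first], tolerance = 1e-12)
      }
      # reported score is consistent with its own edge map
      expect_equal(res$score, f_measure(res$edge_map, ph$gt, tolerance = 1),
                   tolerance = 1e-12)
    }
  }
})

test_that("a singleton dataset returns its only candidate", {
  ph <- make_phantom("LD", c(64, 64), seed = 9)
  ds <- generate_threshold_dataset(1, 1)
  res <- grid_search(ph$image, ph$gt, "sobel", ds)
  expect_equal(res$best$threshold, 0.5)
  expect_equal(res$k, 1)
})

test_that("random search is a seeded subset of grid search", {
  ph <- make_phantom("MD", c(64, 64), seed = 21)
  img <- apply_noise(ph$image, noise_spec("speckle", 0.05, seed = 2))
  ds <- generate_threshold_dataset(40, 40)
  gs <- grid_search(img, ph$gt, "sobel", ds)
  for (seed in 1:20) {
    rs <- random_search(img, ph$gt, "sobel", ds, k = 9, seed = seed)
    expect_lte(rs$score, gs$score)              # dominance
    rs2 <- random_search(img, ph$gt, "sobel", ds, k = 9, seed = seed)
    expect_identical(rs$best, rs2$best)         # seeded determinism
    expect_identical(rs$score, rs2$score)
  }
  # k = dataset size degenerates to grid search
  full <- random_search(img, ph$gt, "sobel", ds, k = 40, seed = 5)
  expect_equal(full$score, gs$score, tolerance = 1e-12)
  expect_equal(full$best$threshold, gs$best$threshold, tolerance = 1e-12)
  # k = 1 returns the single sampled candidate
  one <- random_search(img, ph$gt, "sobel", ds, k = 1, seed = 7)
  expect_equal(one$k, 1)
  expect_error(random_search(img, ph$gt, "sobel", ds, k = 0, seed = 1), "k")
  expect_error(random_search(img, ph$gt, "sobel", ds, k = 41, seed = 1), "k")
})

test_that("a noiseless step phantom is solved perfectly by a mid-grid
           threshold", {
  img <- step_image(32, 16, 16)
  gt <- edge_map(matrix(col(matrix(0, 32, 32)) %in% c(16, 17), 32, 32))
  ds <- generate_threshold_dataset(9, 9)  # contains 0.5
  res <- grid_search(img, gt, "sobel", ds, tolerance = 0)
  expect_equal(res$score, 1)
})
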