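toy_5x5 <- function() {
  # gt: 3 pixels; det: 4 pixels, 3 coinciding -> (tp, fp, fn) = (3, 1, 0)
  gt <- matrix(0, 5, 5)
  gt[cbind(c(2, 3, 4), c(2, 3, 4))] <- 1
  det <- gt
  det[1, 5] <- 1
  list(det = edge_map(det), gt = edge_map(gt))
}

test_that("identical maps score 1 and disjoint/empty maps score 0", {
  m <- edge_map(matrix(sample(c(0, 1), 49, TRUE, prob = c(0.8, 0.2)), 7, 7))
  ev <- evaluate_edges(m, m)
  expect_equal(unlist(ev[c("precision", "recall", "f", "fom", "pr")]),
               c(precision = 1, recall = 1, f = 1, fom = 1, pr = 1))
  empty <- edge_map(matrix(0, 7, 7))
  gt5 <- edge_map(matrix(c(rep(1, 5), rep(0, 44)), 7, 7))
  expect_equal(match_edges(empty, gt5), c(tp = 0, fp = 0, fn = 5))
  expect_equal(f_measure(empty, gt5), 0)
  expect_equal(pratt_fom(empty, gt5), 0)
  expect_equal(performance_ratio(empty, gt5), 0)
  # disjoint at tolerance 0
  a <- edge_map(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0)))
  b <- edge_map(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)))
  expect_equal(f_measure(a, b, 0), 0)
  expect_equal(performance_ratio(a, b, 0), 0)
  # both empty: identity fixed point
  expect_equal(f_measure(empty, empty), 1)
  expect_equal(pratt_fom(empty, empty), 1)
  expect_equal(performance_ratio(empty, empty), 1)
})

test_that("the 5x5 toy case gives (3,1,0), F = 6/7, PR = 0.75", {
  t5 <- toy_5x5()
  expect_equal(match_edges(t5$det, t5$gt, 0), c(tp = 3, fp = 1, fn = 0))
  expect_equal(f_measure(t5$det, t5$gt, 0), 6 / 7, tolerance = 1e-12)
  expect_equal(performance_ratio(t5$det, t5$gt, 0), 0.75, tolerance = 1e-12)
  ev <- evaluate_edges(t5$det, t5$gt, 0)
  expect_equal(ev$precision, 0.75, tolerance = 1e-12)
  expect_equal(ev$recall, 1)
  # FoM from the actual nearest distance of the stray pixel
  d <- min(sqrt((c(2, 3, 4) - 1)^2 + (c(2, 3, 4) - 5)^2))
  expect_equal(ev$fom, (3 + 1 / (1 + d^2 / 9)) / 4, tolerance = 1e-12)
})

test_that("a unit-offset single pixel has FoM = 0.9 at alpha = 1/9", {
  gt <- matrix(0, 9, 9)
  gt[5, 5] <- 1
  det <- matrix(0, 9, 9)
  det[5, 6] <- 1
  expect_equal(pratt_fom(edge_map(det), edge_map(gt), alpha = 1 / 9), 0.9,
               tolerance = 1e-12)
})

test_that("matching and FoM agree with brute-force enumeration on random maps", {
  set.seed(31)
  for (rep in 1:25) {
    det <- matrix(rbinom(64, 1, 0.2), 8, 8)
    gt <- matrix(rbinom(64, 1, 0.2), 8, 8)
    dm <- edge_map(det)
    gm <- edge_map(gt)
    # exact pixel enumeration at tolerance 0
    expect_equal(match_edges(dm, gm, 0),
                 c(tp = sum(det & gt), fp = sum(det & !gt),
                   fn = sum(gt & !det)))
    for (tol in c(1, 2)) {
      expect_equal(match_edges(dm, gm, tol), bf_match(det, gt, tol))
    }
    if (sum(det) > 0 && sum(gt) > 0) {
      d <- bf_nn_dist(det, gt)
      expect_equal(pratt_fom(dm, gm),
                   sum(1 / (1 + d^2 / 9)) / max(sum(det), sum(gt)),
                   tolerance = 1e-12)
    }
  }
})

test_that("FoM never increases as a detected pixel moves away from the truth", {
  gt <- matrix(0, 15, 15)
  gt[8, 8] <- 1
  gm <- edge_map(gt)
  foms <- sapply(0:6, function(off) {
    det <- matrix(0, 15, 15)
    det[8, 8 + off] <- 1
    pratt_fom(edge_map(det), gm)
  })
  expect_true(all(diff(foms) < 0))
  expect_equal(foms[1], 1)
})

test_that("tolerant matching forgives unit offsets but not larger ones", {
  gt <- matrix(0, 9, 9)
  gt[3, ] <- 1
  det <- matrix(0, 9, 9)
  det[4, ] <- 1  # parallel line offset by one row
  expect_equal(f_measure(edge_map(det), edge_map(gt), tolerance = 0), 0)
  expect_equal(f_measure(edge_map(det), edge_map(gt), tolerance = 1), 1)
  det2 <- matrix(0, 9, 9)
  det2[6, ] <- 1
  expect_equal(f_measure(edge_map(det2), edge_map(gt), tolerance = 1), 0)
})
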