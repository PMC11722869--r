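# Objective edge-quality measures against a ground-truth map. Distances are
# exact Euclidean via EBImage's distance transform.

# distance of every pixel to the nearest 1-pixel of `mask` (Inf if none)
dist_to_set <- function(mask) {
  m <- as_plain_matrix(mask)
  if (sum(m) == 0) return(matrix(Inf, nrow(m), ncol(m)))
  d <- EBImage::distmap(1 - m, metric = "euclidean")
  matrix(as.numeric(d), nrow(m), ncol(m))
}

#' Match detected edge pixels against ground truth
#'
#' At `tolerance = 0` pixels must coincide exactly:
#' `tp = |det & gt|`, `fp = |det & !gt|`, `fn = |gt & !det|`. At
#' `tolerance > 0` a detected pixel counts as a true positive when some
#' ground-truth pixel lies within Euclidean distance `tolerance` of it, and a
#' ground-truth pixel counts as missed when no detected pixel lies within
#' `tolerance`.
#'
#' @param det,gt [edge_map]s of equal shape.
#' @param tolerance non-negative matching distance in pixels.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
#' @examples
#' a <- edge_map(diag(5)); b <- edge_map(diag(5))
#' match_edges(a, b)
match_edges <- function(det, gt, tolerance = 0) {
  assert_same_shape(det, gt)
  stopifnot(tolerance >= 0)
  d <- as_plain_matrix(det) == 1
  g <- as_plain_matrix(gt) == 1
  if (tolerance == 0) {
    tp <- sum(d & g)
    fp <- sum(d & !g)
    fn <- sum(g & !d)
  } else {
    dg <- dist_to_set(gt)
    tp <- sum(d & dg <= tolerance)
    fp <- sum(d & dg > tolerance)
    dd <- dist_to_set(det)
    fn <- sum(g & dd > tolerance)
  }
  c(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' F-measure (F1) of an edge detection
#'
#' Harmonic mean of edge-pixel precision and recall under the matching rule of
#' [match_edges()]. Zero-denominator precision/recall are 0; when both maps
#' are empty the detection is perfect by convention and F = 1.
#'
#' @inheritParams match_edges
#' @return F in `[0, 1]`.
#' @export
f_measure <- function(det, gt, tolerance = 0) {
  counts <- match_edges(det, gt, tolerance)
  unname(f_from_counts(counts)["f"])
}

f_from_counts <- function(counts) {
  tp <- counts[["tp"]]
  fp <- counts[["fp"]]
  fn <- counts[["fn"]]
  if (tp + fp + fn == 0) {
    return(c(precision = 1, recall = 1, f = 1))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  c(precision = precision, recall = recall, f = f)
}

#' Pratt's figure of merit
#'
#' `FoM = 1 / max(N_I, N_D) * sum_i 1 / (1 + alpha * d_i^2)` over detected
#' pixels `i`, where `N_I` and `N_D` are the ground-truth and detected edge
#' counts and `d_i` is the Euclidean distance from detected pixel `i` to the
#' nearest ground-truth pixel. Equals 1 exactly when the two non-empty sets
#' coincide; 1 when both are empty, 0 when exactly one is empty.
#'
#' @param det,gt [edge_map]s of equal shape.
#' @param alpha scaling constant of the distance penalty (classical 1/9).
#' @return FoM in `[0, 1]`.
#' @export
pratt_fom <- function(det, gt, alpha = 1 / 9) {
  assert_same_shape(det, gt)
  stopifnot(alpha > 0)
  d <- as_plain_matrix(det) == 1
  g <- as_plain_matrix(gt) == 1
  nd <- sum(d)
  ni <- sum(g)
  if (nd == 0 && ni == 0) return(1)
  if (nd == 0 || ni == 0) return(0)
  di <- dist_to_set(gt)[d]
  sum(1 / (1 + alpha * di^2)) / max(ni, nd)
}

#' Performance ratio of an edge detection
#'
#' The bounded ratio `PR = tp / (tp + fp + fn)` under the matching rule of
#' [match_edges()]; 1 when both maps are empty. The unbounded alternative
#' `tp / (fp + fn)` is available with `bounded = FALSE` (Inf for a perfect
#' detection).
#'
#' @inheritParams match_edges
#' @param bounded use the bounded form (default `TRUE`).
#' @return PR in `[0, 1]` (bounded form).
#' @export
performance_ratio <- function(det, gt, tolerance = 0, bounded = TRUE) {
  counts <- match_edges(det, gt, tolerance)
  tp <- counts[["tp"]]
  denom <- if (bounded) sum(counts) else counts[["fp"]] + counts[["fn"]]
  if (bounded && denom == 0) return(1)
  if (!bounded && denom == 0) return(if (tp > 0) Inf else 1)
  tp / denom
}

#' Evaluate a detection against ground truth on all measures
#'
#' Bundles precision, recall, F, Pratt's FoM and PR plus the raw counts for
#' one (detection, ground truth) pair.
#'
#' @inheritParams match_edges
#' @param alpha FoM distance-penalty constant.
#' @return An `eval_result`: list with `precision`, `recall`, `f`, `fom`,
#'   `pr`, `tp`, `fp`, `fn`.
#' @export
#' @examples
#' gt <- edge_map(diag(8))
#' evaluate_edges(gt, gt)
evaluate_edges <- function(det, gt, tolerance = 0, alpha = 1 / 9) {
  counts <- match_edges(det, gt, tolerance)
  prf <- f_from_counts(counts)
  structure(list(
    precision = unname(prf["precision"]),
    recall = unname(prf["recall"]),
    f = unname(prf["f"]),
    fom = pratt_fom(det, gt, alpha),
    pr = performance_ratio(det, gt, tolerance),
    tp = counts[["tp"]], fp = counts[["fp"]], fn = counts[["fn"]]
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> P %.3f  R %.3f  F %.3f  FoM %.3f  PR %.3f  (tp %d fp %d fn %d)\n",
    x$precision, x$recall, x$f, x$fom, x$pr, x$tp, x$fp, x$fn))
  invisible(x)
}

# scalar score used by the search methods
score_edge_map <- function(det, gt, metric = c("f", "fom", "pr"),
                           tolerance = 0, alpha = 1 / 9) {
  metric <- match.arg(metric)
  switch(metric,
    f = unname(f_measure(det, gt, tolerance)),
    fom = pratt_fom(det, gt, alpha),
    pr = performance_ratio(det, gt, tolerance)
  )
}

# Precompiled scorer for threshold sweeps: fixes (gt, metric, tolerance,
# alpha) and returns a function of a logical detection mask that reproduces
# score_edge_map exactly, hoisting the ground-truth distance transform out of
# the candidate loop. Tolerance-t coverage of gt by the detection is done by
# shifting the detection over the integer offsets with dr^2 + dc^2 <= t^2
# (identical to thresholding the detection's distance transform at t).
make_scorer <- function(gt, metric, tolerance, alpha) {
  g <- as_plain_matrix(gt) == 1
  ng <- sum(g)
  if (metric == "fom") {
    dg <- dist_to_set(gt)
    return(function(d) {
      nd <- sum(d)
      if (nd == 0 && ng == 0) return(1)
      if (nd == 0 || ng == 0) return(0)
      sum(1 / (1 + alpha * dg[d]^2)) / max(ng, nd)
    })
  }
  counts_fun <- if (tolerance == 0) {
    function(d) {
      tp <- sum(d & g)
      c(tp, sum(d) - tp, ng - tp)
    }
  } else {
    near <- dist_to_set(gt) <= tolerance
    rad <- ceiling(tolerance)
    offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    offs <- offs[offs$dr^2 + offs$dc^2 <= tolerance^2, , drop = FALSE]
    function(d) {
      tp <- sum(d & near)
      cov <- matrix(FALSE, nrow(d), ncol(d))
      for (i in seq_len(nrow(offs))) {
        cov <- cov | shift_zero(d, offs$dr[i], offs$dc[i]) > 0
      }
      c(tp, sum(d) - tp, sum(g & !cov))
    }
  }
  if (metric == "f") {
    function(d) {
      cnt <- counts_fun(d)
      unname(f_from_counts(c(tp = cnt[1], fp = cnt[2], fn = cnt[3]))["f"])
    }
  } else {
    function(d) {
      cnt <- counts_fun(d)
      if (sum(cnt) == 0) 1 else cnt[1] / sum(cnt)
    }
  }
}

# Scorer over a monotone threshold sweep of a fixed response map: returns a
# function of the threshold t that scores the detection `map > t` exactly as
# score_edge_map would, in O(log n) per threshold. A detected pixel is a true
# positive iff it lies within `tolerance` of gt; a gt pixel is covered iff
# the maximum response within `tolerance` of it exceeds t.
sweep_scorer <- function(map, gt, metric, tolerance, alpha) {
  g <- as_plain_matrix(gt) == 1
  ng <- sum(g)
  n_greater <- function(sorted, t) length(sorted) - findInterval(t, sorted)
  if (metric == "fom") {
    dg <- dist_to_set(gt)
    mvs <- sort(as.vector(map))
    ord <- order(as.vector(map))
    w <- 1 / (1 + alpha * as.vector(dg)[ord]^2)
    suffix <- rev(cumsum(rev(w)))  # suffix[i] = sum of w for sorted idx >= i
    return(function(t) {
      k <- findInterval(t, mvs)
      nd <- length(mvs) - k
      if (nd == 0 && ng == 0) return(1)
      if (nd == 0 || ng == 0) return(0)
      suffix[k + 1] / max(ng, nd)
    })
  }
  if (tolerance == 0) {
    near_vals <- sort(map[g])
    gmax_vals <- near_vals
  } else {
    near <- dist_to_set(gt) <= tolerance
    rad <- ceiling(tolerance)
    offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    offs <- offs[offs$dr^2 + offs$dc^2 <= tolerance^2, , drop = FALSE]
    gmax <- map
    for (i in seq_len(nrow(offs))) {
      if (offs$dr[i] == 0 && offs$dc[i] == 0) next
      gmax <- pmax(gmax, shift_zero(map, offs$dr[i], offs$dc[i]))
    }
    near_vals <- sort(map[near])
    gmax_vals <- sort(gmax[g])
  }
  all_vals <- sort(as.vector(map))
  function(t) {
    tp <- n_greater(near_vals, t)
    nd <- n_greater(all_vals, t)
    fp <- nd - tp
    fn <- ng - n_greater(gmax_vals, t)
    if (tp + fp + fn == 0) return(1)
    if (metric == "f") {
      unname(f_from_counts(c(tp = tp, fp = fp, fn = fn))["f"])
    } else {
      tp / (tp + fp + fn)
    }
  }
}
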