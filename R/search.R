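# Candidate-threshold dataset and the grid / random threshold-selection
# methods — the core of the approach: pick, per image, the threshold that
# maximizes an objective edge-quality measure against ground truth.

SINGLE_OPERATORS <- c("sobel", "prewitt", "roberts", "log")

#' Generate the candidate-threshold dataset
#'
#' Builds the per-operator candidate lists the search methods draw from.
#' Single-threshold operators (Sobel, Prewitt, Roberts, LoG) get a uniform
#' grid `t_i = i / (count + 1)`, `i = 1..count`, on `(0, 1)`. Canny candidates
#' are `(low, high)` pairs over the same grid of highs with
#' `low = low_ratio * high`, so each pair stores two values. The defaults
#' (300 candidates per single operator, 300 Canny pairs) store
#' `4 * 300 + 2 * 300 = 1800` threshold values in total; `count_single = 100`
#' gives the compact 100-per-operator preset.
#'
#' @param count_single candidates per single-threshold operator (>= 1).
#' @param count_canny_pairs Canny `(low, high)` pairs (>= 1).
#' @param low_ratio ratio tying `low = low_ratio * high` in `(0, 1)`.
#' @return A `threshold_dataset`.
#' @export
#' @examples
#' ds <- generate_threshold_dataset()
#' n_threshold_values(ds)  # 1800
generate_threshold_dataset <- function(count_single = 300L,
                                       count_canny_pairs = 300L,
                                       low_ratio = 0.4) {
  stopifnot(count_single >= 1, count_canny_pairs >= 1,
            low_ratio > 0, low_ratio < 1)
  grid_s <- seq_len(count_single) / (count_single + 1)
  highs <- seq_len(count_canny_pairs) / (count_canny_pairs + 1)
  single <- stats::setNames(
    lapply(SINGLE_OPERATORS, function(op) grid_s), SINGLE_OPERATORS)
  structure(list(
    single = single,
    canny = data.frame(low = low_ratio * highs, high = highs),
    count_single = as.integer(count_single),
    count_canny_pairs = as.integer(count_canny_pairs),
    low_ratio = low_ratio
  ), class = "threshold_dataset")
}

#' Total number of stored threshold values in a dataset
#'
#' Each single-operator candidate stores one value; each Canny pair stores
#' two.
#'
#' @param dataset a `threshold_dataset`.
#' @return Integer count.
#' @export
n_threshold_values <- function(dataset) {
  stopifnot(inherits(dataset, "threshold_dataset"))
  sum(lengths(dataset$single)) + 2L * nrow(dataset$canny)
}

#' @export
print.threshold_dataset <- function(x, ...) {
  cat(sprintf(
    "<threshold_dataset> %d per single operator, %d canny pairs (%d stored values)\n",
    x$count_single, x$count_canny_pairs, n_threshold_values(x)))
  invisible(x)
}

#' Write / read a threshold dataset as CSV
#'
#' Columns `operator, value1, value2`; `value2` is empty for single-threshold
#' operators and holds the Canny `high` (with `value1 = low`).
#'
#' @param dataset a `threshold_dataset`.
#' @param path CSV file path.
#' @return `path` invisibly; `read_threshold_dataset` returns the dataset.
#' @export
write_threshold_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "threshold_dataset"))
  rows <- do.call(rbind, c(
    lapply(SINGLE_OPERATORS, function(op) {
      data.frame(operator = op, value1 = dataset$single[[op]],
                 value2 = NA_real_)
    }),
    list(data.frame(operator = "canny", value1 = dataset$canny$low,
                    value2 = dataset$canny$high))
  ))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_dataset
#' @export
read_threshold_dataset <- function(path) {
  rows <- read.csv(path)
  stopifnot(all(c("operator", "value1") %in% names(rows)))
  single <- lapply(SINGLE_OPERATORS, function(op)
    sort(rows$value1[rows$operator == op]))
  names(single) <- SINGLE_OPERATORS
  cn <- rows[rows$operator == "canny", , drop = FALSE]
  cn <- cn[order(cn$value2), , drop = FALSE]
  canny <- data.frame(low = cn$value1, high = cn$value2)
  ratio <- if (nrow(canny) > 0) canny$low[1] / canny$high[1] else 0.4
  structure(list(single = single, canny = canny,
                 count_single = length(single[[1]]),
                 count_canny_pairs = nrow(canny),
                 low_ratio = ratio),
            class = "threshold_dataset")
}

# candidate list for one operator, as a data.frame ordered ascending
candidates_for <- function(dataset, operator) {
  stopifnot(inherits(dataset, "threshold_dataset"))
  if (operator == "canny") {
    if (nrow(dataset$canny) == 0) stop("empty candidate list", call. = FALSE)
    dataset$canny
  } else {
    v <- dataset$single[[operator]]
    if (is.null(v) || length(v) == 0) {
      stop("empty candidate list for operator ", operator, call. = FALSE)
    }
    data.frame(value = v)
  }
}

# evaluate the candidates at `idx` (ascending order) on a shared response;
# first maximum wins, so ties break toward the smallest candidate. The sweep
# works on plain logical masks with a precompiled scorer; the winning edge
# map is rebuilt through the same thresholding path detect() uses.
search_candidates <- function(img, gt, operator, dataset, idx,
                              metric, tolerance, alpha, sigma) {
  cand <- candidates_for(dataset, operator)
  resp <- operator_response(img, operator, sigma)
  best_score <- -Inf
  best_i <- NA_integer_
  if (resp$kind == "map") {
    # detections are monotone in the threshold, so every count the measures
    # need reduces to "response values > t" lookups on pre-sorted vectors
    score_at <- sweep_scorer(resp$map, gt, metric, tolerance, alpha)
    for (i in idx) {
      s <- score_at(cand$value[i])
      if (s > best_score) {
        best_score <- s
        best_i <- i
      }
    }
  } else {
    scorer <- make_scorer(gt, metric, tolerance, alpha)
    for (i in idx) {
      d <- hysteresis_fill(resp$nms & resp$mag >= cand$high[i],
                           resp$nms & resp$mag >= cand$low[i]) == 1L
      s <- scorer(d)
      if (s > best_score) {
        best_score <- s
        best_i <- i
      }
    }
  }
  if (operator == "canny") {
    best <- list(operator = operator, low = cand$low[best_i],
                 high = cand$high[best_i])
    best_map <- threshold_response(resp, low = best$low, high = best$high)
  } else {
    best <- list(operator = operator, threshold = cand$value[best_i])
    best_map <- threshold_response(resp, threshold = best$threshold)
  }
  list(best = best, score = best_score, index = best_i, edge_map = best_map)
}

search_result <- function(res, metric, method, k, seed) {
  structure(list(best = res$best, score = res$score, metric = metric,
                 method = method, k = as.integer(k), seed = seed,
                 edge_map = res$edge_map),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  th <- if (x$best$operator == "canny") {
    sprintf("low %.4f high %.4f", x$best$low, x$best$high)
  } else {
    sprintf("threshold %.4f", x$best$threshold)
  }
  cat(sprintf("<search_result> %s via %s (k = %d): %s, %s = %.4f\n",
              x$best$operator, x$method, x$k, th, x$metric, x$score))
  invisible(x)
}

#' Grid search over the candidate thresholds
#'
#' Detects edges at every candidate threshold of the operator and returns the
#' candidate maximizing the chosen objective measure against the ground
#' truth. Fully deterministic; ties break toward the smallest candidate.
#'
#' @param img [gray_image] (or coercible matrix).
#' @param gt ground-truth [edge_map], same shape as `img`.
#' @param operator one of the five operator names.
#' @param dataset a `threshold_dataset` (default: the compact 100-value
#'   preset).
#' @param metric selection measure: `"f"` (default), `"fom"` or `"pr"`.
#' @param tolerance matching tolerance in pixels passed to the measure
#'   (default 1; see the package vignette on discrete boundary offsets).
#' @param alpha FoM constant.
#' @param sigma optional smoothing scale override.
#' @return A `search_result` with fields `best`, `score`, `metric`, `method`,
#'   `k`, `seed`, `edge_map`.
#' @export
grid_search <- function(img, gt, operator,
                        dataset = generate_threshold_dataset(100L, 100L),
                        metric = c("f", "fom", "pr"), tolerance = 1,
                        alpha = 1 / 9, sigma = NULL) {
  metric <- match.arg(metric)
  assert_same_shape(as_gray_image(img), gt)
  cand <- candidates_for(dataset, operator)
  res <- search_candidates(img, gt, operator, dataset, seq_len(nrow(cand)),
                           metric, tolerance, alpha, sigma)
  search_result(res, metric, "GS", nrow(cand), NA_integer_)
}

#' Random search over the candidate thresholds
#'
#' Draws `k` distinct candidates uniformly without replacement (seeded) and
#' returns the best of those `k` under the chosen measure. The grid-search
#' score over the same dataset is an upper bound for every draw.
#'
#' @inheritParams grid_search
#' @param k sample size, `1 <= k <=` candidate-list size (e.g. 3, 6, 9).
#' @param seed integer seed; identical seeds give identical draws.
#' @return A `search_result`.
#' @export
random_search <- function(img, gt, operator,
                          dataset = generate_threshold_dataset(100L, 100L),
                          k = 9L, seed = 0L,
                          metric = c("f", "fom", "pr"), tolerance = 1,
                          alpha = 1 / 9, sigma = NULL) {
  metric <- match.arg(metric)
  assert_same_shape(as_gray_image(img), gt)
  cand <- candidates_for(dataset, operator)
  n <- nrow(cand)
  if (!(k >= 1 && k <= n)) stop("k must be in [1, ", n, "]", call. = FALSE)
  idx <- sort(with_seed(seed, sample.int(n, k)))
  res <- search_candidates(img, gt, operator, dataset, idx,
                           metric, tolerance, alpha, sigma)
  search_result(res, metric, "RS", k, as.integer(seed))
}
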