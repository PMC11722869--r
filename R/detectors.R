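# The five classical detectors. Each single-threshold operator reduces to a
# precomputed response map in [0,1] plus a cut, so threshold sweeps (the search
# module) reuse one response per image. Canny keeps the NMS mask alongside the
# normalized magnitude, with only the double threshold + hysteresis per cut.

KERNEL_SOBEL_GX <- matrix(c(-1, 0, 1,
                            -2, 0, 2,
                            -1, 0, 1), 3, 3, byrow = TRUE)
KERNEL_PREWITT_GX <- matrix(c(-1, 0, 1,
                              -1, 0, 1,
                              -1, 0, 1), 3, 3, byrow = TRUE)
KERNEL_LAPLACIAN <- matrix(c(0,  1, 0,
                             1, -4, 1,
                             0,  1, 0), 3, 3, byrow = TRUE)

#' Detector parameters
#'
#' Validates and bundles the parameters of one detector. Single-threshold
#' operators (Sobel, Prewitt, Roberts, LoG) take one normalized threshold in
#' `(0, 1)`; Canny takes a `(low, high)` pair with `0 < low < high < 1`.
#' `sigma` is the Gaussian smoothing scale used by Canny (default 1.4) and LoG
#' (default 2.0).
#'
#' @param operator `"sobel"`, `"prewitt"`, `"roberts"`, `"log"` or `"canny"`.
#' @param threshold normalized threshold for single-threshold operators.
#' @param low,high Canny hysteresis thresholds.
#' @param sigma smoothing scale in pixels (> 0); operator-specific default.
#' @return A `detector_params` object.
#' @export
#' @examples
#' detector_params("sobel", threshold = 0.3)
#' detector_params("canny", low = 0.1, high = 0.3)
detector_params <- function(operator = c("sobel", "prewitt", "roberts", "log",
                                         "canny"),
                            threshold = NULL, low = NULL, high = NULL,
                            sigma = NULL) {
  operator <- match.arg(operator)
  if (operator == "canny") {
    if (is.null(low) || is.null(high)) {
      stop("canny requires `low` and `high`", call. = FALSE)
    }
    if (!(low > 0 && high < 1 && low < high)) {
      stop("canny thresholds must satisfy 0 < low < high < 1", call. = FALSE)
    }
    if (is.null(sigma)) sigma <- 1.4
  } else {
    if (is.null(threshold)) stop("`threshold` required for ", operator,
                                 call. = FALSE)
    if (!(threshold > 0 && threshold < 1)) {
      stop("threshold must lie in (0, 1)", call. = FALSE)
    }
    if (is.null(sigma)) sigma <- if (operator == "log") 2.0 else NA_real_
  }
  stopifnot(is.na(sigma) || sigma > 0)
  structure(list(operator = operator, threshold = threshold,
                 low = low, high = high, sigma = sigma),
            class = "detector_params")
}

#' First-derivative gradient field
#'
#' Convolves the image with the classical kernel pair of the chosen operator:
#' Sobel (`[-1 0 1; -2 0 2; -1 0 1]` and its transpose), Prewitt
#' (`[-1 0 1; -1 0 1; -1 0 1]` and transpose), or Roberts cross
#' (`[1 0; 0 -1]`, `[0 1; -1 0]` on the 2x2 forward neighborhood, anchored at
#' the top-left pixel, replicate padding on the last row/column). Borders use
#' replicate padding throughout.
#'
#' @param img [gray_image] (or coercible matrix).
#' @param operator `"sobel"`, `"prewitt"` or `"roberts"`.
#' @return A `gradient_field`: list with `gx`, `gy` and
#'   `magnitude = sqrt(gx^2 + gy^2)`, all image-shaped.
#' @export
gradient <- function(img, operator = c("sobel", "prewitt", "roberts")) {
  operator <- match.arg(operator)
  m <- as_plain_matrix(as_gray_image(img))
  if (operator == "roberts") {
    nr <- nrow(m)
    nc <- ncol(m)
    p <- m[c(seq_len(nr), nr), c(seq_len(nc), nc)]  # replicate 1 px bottom/right
    a <- p[seq_len(nr), seq_len(nc)]
    b <- p[seq_len(nr), 1L + seq_len(nc)]
    cc <- p[1L + seq_len(nr), seq_len(nc)]
    d <- p[1L + seq_len(nr), 1L + seq_len(nc)]
    gx <- a - d
    gy <- b - cc
  } else {
    kx <- if (operator == "sobel") KERNEL_SOBEL_GX else KERNEL_PREWITT_GX
    gx <- convolve2d(m, kx, "replicate")
    gy <- convolve2d(m, t(kx), "replicate")
  }
  structure(list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2)),
            class = "gradient_field")
}

# ---- response maps (shared by detect* and the threshold search) ---------

# normalized gradient magnitude response in [0,1]
response_gradient <- function(img, operator) {
  g <- gradient(img, operator)
  list(kind = "map", map = normalize01(g$magnitude))
}

# LoG zero-crossing strength: Gaussian smooth, 3x3 Laplacian, normalize by the
# max absolute response, then per pixel the largest |difference| across an
# opposing 4-neighbor pair with a sign change; 0 where no crossing.
response_log <- function(img, sigma = 2.0) {
  m <- as_plain_matrix(as_gray_image(img))
  r <- convolve2d(gaussian_smooth(m, sigma), KERNEL_LAPLACIAN, "replicate")
  mx <- max(abs(r))
  if (mx > 0) r <- r / mx
  left <- shift_replicate(r, 0, -1)
  right <- shift_replicate(r, 0, 1)
  up <- shift_replicate(r, -1, 0)
  down <- shift_replicate(r, 1, 0)
  h <- ifelse(left * right < 0, abs(left - right), 0)
  v <- ifelse(up * down < 0, abs(up - down), 0)
  list(kind = "map", map = pmax(h, v))
}

# Canny front end: smooth, Sobel gradient, min-max normalized magnitude, and
# non-maximum suppression along the quantized gradient direction. On exactly
# symmetric steps the two straddling pixels tie; (m > prev) & (m >= next)
# keeps exactly one, so clean steps give 1-px lines.
response_canny <- function(img, sigma = 1.4) {
  m <- as_plain_matrix(as_gray_image(img))
  sm <- gaussian_smooth(m, sigma)
  gx <- convolve2d(sm, KERNEL_SOBEL_GX, "replicate")
  gy <- convolve2d(sm, t(KERNEL_SOBEL_GX), "replicate")
  mag <- normalize01(sqrt(gx^2 + gy^2))
  sector <- (round(atan2(gy, gx) / (pi / 4)) %% 4)
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  keep <- matrix(FALSE, nrow(m), ncol(m))
  for (s in 0:3) {
    o <- offs[[as.character(s)]]
    nxt <- shift_replicate(mag, o[1], o[2])
    prv <- shift_replicate(mag, -o[1], -o[2])
    keep <- keep | (sector == s & mag > prv & mag >= nxt)
  }
  list(kind = "canny", mag = mag, nms = keep & mag > 0)
}

# response for any operator; params needs only operator + sigma
operator_response <- function(img, operator, sigma = NULL) {
  switch(operator,
    sobel = ,
    prewitt = ,
    roberts = response_gradient(img, operator),
    log = response_log(img, if (is.null(sigma) || is.na(sigma)) 2.0 else sigma),
    canny = response_canny(img, if (is.null(sigma) || is.na(sigma)) 1.4 else sigma),
    stop("unknown operator: ", operator, call. = FALSE)
  )
}

# apply a threshold (or canny pair) to a precomputed response
threshold_response <- function(resp, threshold = NULL, low = NULL, high = NULL) {
  if (resp$kind == "map") {
    edge_map(resp$map > threshold)
  } else {
    strong <- resp$nms & resp$mag >= high
    weak <- resp$nms & resp$mag >= low
    edge_map(hysteresis_fill(strong, weak) == 1L)
  }
}

#' Detect edges with a first-derivative operator at a fixed threshold
#'
#' Computes the gradient magnitude, min-max normalizes it to `[0, 1]` (a flat
#' response gives an empty map), and marks pixels whose normalized magnitude
#' strictly exceeds the threshold.
#'
#' @param img [gray_image] (or coercible matrix).
#' @param params [detector_params] with operator sobel/prewitt/roberts.
#' @return An [edge_map].
#' @export
detect_gradient_operator <- function(img, params) {
  stopifnot(inherits(params, "detector_params"),
            params$operator %in% c("sobel", "prewitt", "roberts"))
  threshold_response(response_gradient(img, params$operator),
                     threshold = params$threshold)
}

#' Detect edges with the Laplacian-of-Gaussian operator
#'
#' Smooths at `sigma` (default 2.0), applies the 3x3 Laplacian, normalizes the
#' response by its maximum absolute value, and marks pixels where a sign
#' change occurs between opposing 4-neighbors and the absolute normalized
#' response difference across the crossing exceeds the threshold.
#'
#' @param img [gray_image] (or coercible matrix).
#' @param params [detector_params] with `operator = "log"`.
#' @return An [edge_map].
#' @export
detect_log <- function(img, params) {
  stopifnot(inherits(params, "detector_params"), params$operator == "log")
  threshold_response(response_log(img, params$sigma),
                     threshold = params$threshold)
}

#' Detect edges with the Canny operator
#'
#' The classical pipeline: Gaussian smoothing at `sigma` (default 1.4, kernel
#' truncated at 4 sigma), Sobel gradient, non-maximum suppression with the
#' gradient direction quantized to 4 sectors, double threshold on the min-max
#' normalized magnitude, and hysteresis — weak pixels (>= `low`) are kept only
#' when 8-connected through weak pixels to a strong pixel (>= `high`).
#'
#' @param img [gray_image] (or coercible matrix).
#' @param params [detector_params] with `operator = "canny"`.
#' @return An [edge_map].
#' @export
detect_canny <- function(img, params) {
  stopifnot(inherits(params, "detector_params"), params$operator == "canny")
  threshold_response(response_canny(img, params$sigma),
                     low = params$low, high = params$high)
}

#' Detect edges (operator dispatch)
#'
#' @param img [gray_image] (or coercible matrix).
#' @param params [detector_params].
#' @return An [edge_map].
#' @export
#' @examples
#' img <- gray_image(cbind(matrix(0, 8, 4), matrix(1, 8, 4)))
#' detect(img, detector_params("sobel", threshold = 0.5))
detect <- function(img, params) {
  stopifnot(inherits(params, "detector_params"))
  switch(params$operator,
    sobel = ,
    prewitt = ,
    roberts = detect_gradient_operator(img, params),
    log = detect_log(img, params),
    canny = detect_canny(img, params)
  )
}

#' Otsu's threshold on values in `[0, 1]`
#'
#' Histogram-based between-class variance maximization over `n_bins` equal
#' bins; returns the upper boundary of the best split bin on the `[0, 1]`
#' scale. Used by [standard_detect()] to derive the no-search baseline
#' threshold.
#'
#' @param values numeric values in `[0, 1]`.
#' @param n_bins number of histogram bins (default 256).
#' @return A threshold in `(0, 1)`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- values[is.finite(values)]
  stopifnot(length(v) > 0)
  bins <- pmin(pmax(floor(v * n_bins), 0), n_bins - 1L)
  counts <- tabulate(bins + 1L, nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  k / n_bins
}

#' Detect edges with the standard (no-search) baseline
#'
#' The automatic baseline every search method is compared against: the
#' threshold is Otsu's threshold on the operator's normalized response values
#' (gradient magnitude for Sobel/Prewitt/Roberts; crossing strength for LoG).
#' For Canny, `high` is the Otsu value on the normalized magnitude and
#' `low = 0.4 * high`.
#'
#' @param img [gray_image] (or coercible matrix).
#' @param operator one of the five operator names.
#' @param sigma optional smoothing scale (operator default when `NULL`).
#' @return An [edge_map] with the derived [detector_params] attached as
#'   attribute `"params"`.
#' @export
standard_detect <- function(img, operator = c("sobel", "prewitt", "roberts",
                                              "log", "canny"),
                            sigma = NULL) {
  operator <- match.arg(operator)
  resp <- operator_response(img, operator, sigma)
  eps <- 1e-6
  if (resp$kind == "map") {
    mx <- max(resp$map)
    th <- if (mx <= 0) 1 - eps else {
      # LoG strengths live in [0, 2); rescale for the [0,1] histogram
      otsu_threshold(resp$map / max(mx, 1)) * max(mx, 1)
    }
    th <- min(max(th, eps), 1 - eps)
    out <- threshold_response(resp, threshold = th)
    params <- detector_params(operator, threshold = th, sigma = sigma)
  } else {
    high <- if (max(resp$mag) <= 0) 1 - eps else otsu_threshold(resp$mag)
    high <- min(max(high, 2 * eps), 1 - eps)
    low <- 0.4 * high
    out <- threshold_response(resp, low = low, high = high)
    params <- detector_params("canny", low = low, high = high, sigma = sigma)
  }
  attr(out, "params") <- params
  out
}
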