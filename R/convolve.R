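#' 2-D convolution with replicate border handling
#'
#' Convolves an image with an odd-sized kernel in true convolution orientation
#' (the kernel is flipped in both dimensions before the sliding product), with
#' replicate (edge-clamp) padding so the output has the same shape as the
#' input. Replicate padding avoids the spurious border responses that
#' zero-padding creates, and preserves constant images under any unit-sum
#' kernel.
#'
#' @param img numeric matrix (a [gray_image] or any 2-D grid).
#' @param kernel numeric matrix with odd dimensions.
#' @param border border handling; only `"replicate"` is supported.
#' @return Numeric matrix, same shape as `img`.
#' @export
#' @examples
#' convolve2d(matrix(1:9, 3, 3), matrix(1, 1, 1))  # identity kernel
convolve2d <- function(img, kernel, border = "replicate") {
  border <- match.arg(border, "replicate")
  img <- as_plain_matrix(img)
  if (!is.matrix(kernel) || nrow(kernel) %% 2 == 0 || ncol(kernel) %% 2 == 0) {
    stop("kernel dimensions must be odd", call. = FALSE)
  }
  if (nrow(img) < nrow(kernel) || ncol(img) < ncol(kernel)) {
    stop("image smaller than kernel", call. = FALSE)
  }
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  k <- kernel[kr:1, kc:1, drop = FALSE]  # flip: convolution, not correlation
  pr <- (kr - 1L) %/% 2L
  pc <- (kc - 1L) %/% 2L
  pad <- pad_replicate(img, pr, pc)
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- k[i, j]
      if (w != 0) {
        out <- out + w * pad[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
      }
    }
  }
  out
}

# 1-D Gaussian taps, truncated at `truncate` standard deviations; the radius
# is clamped so the kernel never exceeds the image extent it is applied to
gaussian_taps <- function(sigma, truncate = 4, max_radius = Inf) {
  stopifnot(sigma > 0)
  radius <- max(1L, as.integer(ceiling(truncate * sigma)))
  radius <- min(radius, max_radius)
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# separable Gaussian smoothing with replicate borders
gaussian_smooth <- function(img, sigma, truncate = 4) {
  gr <- gaussian_taps(sigma, truncate, max_radius = (ncol(img) - 1) %/% 2)
  gc <- gaussian_taps(sigma, truncate, max_radius = (nrow(img) - 1) %/% 2)
  tmp <- convolve2d(img, matrix(gr, nrow = 1), "replicate")
  convolve2d(tmp, matrix(gc, ncol = 1), "replicate")
}
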