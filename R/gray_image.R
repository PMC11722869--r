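#' Grayscale image in `[0, 1]`
#'
#' A `gray_image` is a numeric matrix of intensities on the normalized scale
#' `[0, 1]`, at least 3x3 (the smallest size every 3x3 detector kernel
#' accepts). Rows index image rows, columns index image columns. All package
#' stages — noise simulation, detection, complexity statistics — operate on
#' this unit.
#'
#' @param pixels numeric matrix with finite values in `[0, 1]`, dims >= 3.
#' @return A `gray_image` object (a classed matrix).
#' @export
#' @examples
#' img <- gray_image(matrix(seq(0, 1, length.out = 25), 5, 5))
#' dim(img)
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 3 || ncol(pixels) < 3) {
    stop("image must be at least 3x3", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(pixels, class = c("gray_image", "matrix"))
}

#' Coerce to a grayscale image
#'
#' @param x matrix or `gray_image`.
#' @return A `gray_image`.
#' @export
as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(as_plain_matrix(x))
}

# strip classes so matrix arithmetic stays fast and predictable
as_plain_matrix <- function(x) {
  x <- unclass(x)
  attr(x, "params") <- NULL
  x
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, intensity range [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Binary edge map
#'
#' An `edge_map` is a binary (0/1) integer matrix marking edge pixels, with the
#' same shape as the image it was derived from.
#'
#' @param mask matrix with values in `{0, 1}` (logical or numeric).
#' @return An `edge_map` object (a classed integer matrix).
#' @export
#' @examples
#' em <- edge_map(diag(5))
#' sum(em)
edge_map <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  if (is.logical(mask)) {
    m <- mask
    m[] <- as.integer(mask)
    storage.mode(m) <- "integer"
  } else {
    if (anyNA(mask) || !all(mask %in% c(0, 1))) {
      stop("edge map values must be exactly 0 or 1", call. = FALSE)
    }
    m <- mask
    storage.mode(m) <- "integer"
  }
  structure(m, class = c("edge_map", "matrix"))
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %d x %d, %d edge pixels (%.1f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

assert_same_shape <- function(a, b) {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
    stop("shape mismatch: ", nrow(a), "x", ncol(a), " vs ",
         nrow(b), "x", ncol(b), call. = FALSE)
  }
  invisible(TRUE)
}
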