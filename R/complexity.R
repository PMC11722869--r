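#' Spatial-information statistics of an image
#'
#' Applies the Sobel filter to the horizontal and vertical components of the
#' image (replicate borders), forms the per-pixel spatial information
#' `SI_r = sqrt(sh^2 + sv^2)`, and summarizes it by its mean, population
#' standard deviation and root mean square. The population convention makes
#' the identity `si_rms^2 = si_mean^2 + si_stdev^2` exact.
#'
#' @param img [gray_image] (or coercible matrix).
#' @return A `spatial_info`: list with `si_mean`, `si_stdev`, `si_rms`.
#' @export
#' @examples
#' spatial_information(gray_image(cbind(matrix(0, 8, 4), matrix(1, 8, 4))))
spatial_information <- function(img) {
  si <- gradient(img, "sobel")$magnitude
  mu <- mean(si)
  structure(list(
    si_mean = mu,
    si_stdev = sqrt(mean((si - mu)^2)),
    si_rms = sqrt(mean(si^2))
  ), class = "spatial_info")
}

#' @export
print.spatial_info <- function(x, ...) {
  cat(sprintf("<spatial_info> mean %.4f  stdev %.4f  rms %.4f\n",
              x$si_mean, x$si_stdev, x$si_rms))
  invisible(x)
}

#' Classify image complexity from spatial information
#'
#' Assigns the low/medium/high-detail label from the SI mean with right-open
#' intervals: `si_mean < b1` is LD, `b1 <= si_mean < b2` is MD, and
#' `si_mean >= b2` is HD.
#'
#' @param si a `spatial_info` (from [spatial_information()]) or a single
#'   numeric SI-mean value.
#' @param boundaries numeric `c(b1, b2)` with `b1 < b2`.
#' @return A `complexity_class`: list with `label` (`"LD"`, `"MD"` or `"HD"`)
#'   and the `boundaries` used.
#' @export
#' @examples
#' classify_complexity(0.05, boundaries = c(0.1, 0.3))
classify_complexity <- function(si, boundaries) {
  stopifnot(length(boundaries) == 2)
  b1 <- boundaries[1]
  b2 <- boundaries[2]
  if (!(b1 < b2)) stop("boundaries must satisfy b1 < b2", call. = FALSE)
  mu <- if (inherits(si, "spatial_info")) si$si_mean else {
    stopifnot(is.numeric(si), length(si) == 1)
    si
  }
  label <- if (mu < b1) "LD" else if (mu < b2) "MD" else "HD"
  structure(list(label = label, boundaries = c(b1 = b1, b2 = b2)),
            class = "complexity_class")
}

#' @export
print.complexity_class <- function(x, ...) {
  cat(sprintf("<complexity_class> %s (boundaries %.4f / %.4f)\n",
              x$label, x$boundaries[1], x$boundaries[2]))
  invisible(x)
}

#' Calibrate complexity boundaries from a corpus
#'
#' Computes the 33.33rd and 66.67th percentiles (linear interpolation) of the
#' SI-mean values of a corpus, yielding tercile boundaries under which a
#' balanced corpus splits evenly into the three complexity classes.
#'
#' @param corpus list of images ([gray_image] or coercible matrices) or of
#'   `phantom` objects, or a numeric vector of precomputed SI means.
#' @return Numeric `c(b1, b2)`.
#' @export
calibrate_boundaries <- function(corpus) {
  mus <- if (is.numeric(corpus)) corpus else {
    vapply(corpus, function(im) {
      if (inherits(im, "phantom")) im <- im$image
      spatial_information(im)$si_mean
    }, numeric(1))
  }
  if (length(mus) < 3) stop("need at least 3 images", call. = FALSE)
  if (length(unique(mus)) < 2) {
    stop("degenerate corpus: all SI means identical", call. = FALSE)
  }
  b <- unname(quantile(mus, probs = c(1, 2) / 3, type = 7))
  if (!(b[1] < b[2])) {
    stop("degenerate corpus: tercile boundaries coincide", call. = FALSE)
  }
  c(b1 = b[1], b2 = b[2])
}
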