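#' Noise specification
#'
#' Bundles a noise model, its intensity and a seed. Intensity semantics follow
#' the common `imnoise` conventions: variance for Gaussian and speckle noise,
#' corruption density (a probability) for salt-and-pepper, and the standard
#' deviation sigma of the complex Gaussian perturbation for Rician noise.
#'
#' @param kind one of `"gaussian"`, `"salt_pepper"`, `"speckle"`, `"rician"`,
#'   `"none"`.
#' @param intensity non-negative intensity; must lie in `[0, 1]` for
#'   salt-and-pepper. Ignored for `"none"`.
#' @param seed integer seed for the corruption draw.
#' @return A `noise_spec` object.
#' @export
#' @examples
#' noise_spec("gaussian", 0.01, seed = 7)
noise_spec <- function(kind = c("gaussian", "salt_pepper", "speckle", "rician",
                                "none"),
                       intensity = 0, seed = 0L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(intensity), length(intensity) == 1, intensity >= 0)
  if (kind == "salt_pepper" && intensity > 1) {
    stop("salt-and-pepper density is a probability; must be in [0, 1]",
         call. = FALSE)
  }
  structure(list(kind = kind, intensity = intensity, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add Gaussian noise
#'
#' Adds i.i.d. zero-mean normal noise with the given variance to every pixel
#' and clips the result back to `[0, 1]`.
#'
#' @param img [gray_image] (or coercible matrix).
#' @param variance noise variance, >= 0.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A [gray_image].
#' @export
add_gaussian <- function(img, variance, seed = 0L) {
  img <- as_gray_image(img)
  stopifnot(variance >= 0)
  if (variance == 0) return(img)
  m <- as_plain_matrix(img)
  n <- with_seed(seed, rnorm(length(m), mean = 0, sd = sqrt(variance)))
  gray_image(clip01(m + matrix(n, nrow(m), ncol(m))))
}

#' Add salt-and-pepper (impulse) noise
#'
#' Each pixel is independently corrupted with probability `density`; a
#' corrupted pixel is set to 0 (pepper) or 1 (salt) with equal probability,
#' all other pixels are left unchanged.
#'
#' @param img [gray_image] (or coercible matrix).
#' @param density corruption probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A [gray_image].
#' @export
add_salt_pepper <- function(img, density, seed = 0L) {
  img <- as_gray_image(img)
  stopifnot(density >= 0, density <= 1)
  if (density == 0) return(img)
  m <- as_plain_matrix(img)
  np <- length(m)
  draw <- with_seed(seed, {
    hit <- runif(np) < density
    salt <- runif(np) < 0.5
    list(hit = hit, salt = salt)
  })
  m[draw$hit] <- as.numeric(draw$salt[draw$hit])
  gray_image(m)
}

#' Add speckle (multiplicative) noise
#'
#' Applies `out = clip(img + n * img, 0, 1)` with `n` i.i.d. zero-mean noise of
#' the given variance. The multiplier is uniform on
#' `[-sqrt(3 v), sqrt(3 v)]` (the `imnoise` convention) by default; a Gaussian
#' multiplier is available via `multiplier = "gaussian"`.
#'
#' @param img [gray_image] (or coercible matrix).
#' @param variance multiplier variance, >= 0.
#' @param seed integer seed.
#' @param multiplier `"uniform"` (default) or `"gaussian"`.
#' @return A [gray_image].
#' @export
add_speckle <- function(img, variance, seed = 0L,
                        multiplier = c("uniform", "gaussian")) {
  img <- as_gray_image(img)
  multiplier <- match.arg(multiplier)
  stopifnot(variance >= 0)
  if (variance == 0) return(img)
  m <- as_plain_matrix(img)
  n <- with_seed(seed, {
    if (multiplier == "uniform") {
      a <- sqrt(3 * variance)
      runif(length(m), -a, a)
    } else {
      rnorm(length(m), 0, sqrt(variance))
    }
  })
  gray_image(clip01(m + matrix(n, nrow(m), ncol(m)) * m))
}

#' Add Rician noise
#'
#' Applies the standard magnitude-MRI model
#' `out = clip(sqrt((img + n1)^2 + n2^2), 0, 1)` with `n1, n2` i.i.d.
#' `Normal(0, sigma^2)`. On zero signal this reduces to Rayleigh noise with
#' mean `sigma * sqrt(pi / 2)`.
#'
#' @param img [gray_image] (or coercible matrix).
#' @param sigma standard deviation of the complex perturbation, >= 0.
#' @param seed integer seed.
#' @return A [gray_image].
#' @export
add_rician <- function(img, sigma, seed = 0L) {
  img <- as_gray_image(img)
  stopifnot(sigma >= 0)
  if (sigma == 0) return(img)
  m <- as_plain_matrix(img)
  np <- length(m)
  n <- with_seed(seed, rnorm(2 * np, 0, sigma))
  n1 <- matrix(n[seq_len(np)], nrow(m), ncol(m))
  n2 <- matrix(n[np + seq_len(np)], nrow(m), ncol(m))
  gray_image(clip01(sqrt((m + n1)^2 + n2^2)))
}

#' Corrupt an image according to a noise specification
#'
#' Dispatches to the matching noise simulator; `kind = "none"` returns the
#' input unchanged.
#'
#' @param img [gray_image] (or coercible matrix).
#' @param spec a [noise_spec].
#' @return A [gray_image].
#' @export
#' @examples
#' img <- gray_image(matrix(0.5, 8, 8))
#' apply_noise(img, noise_spec("salt_pepper", 0.1, seed = 3))
apply_noise <- function(img, spec) {
  if (!inherits(spec, "noise_spec")) stop("`spec` must be a noise_spec",
                                          call. = FALSE)
  switch(spec$kind,
    none        = as_gray_image(img),
    gaussian    = add_gaussian(img, spec$intensity, spec$seed),
    salt_pepper = add_salt_pepper(img, spec$intensity, spec$seed),
    speckle     = add_speckle(img, spec$intensity, spec$seed),
    rician      = add_rician(img, spec$intensity, spec$seed),
    stop("unknown noise kind: ", spec$kind, call. = FALSE)
  )
}
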