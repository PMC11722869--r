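# fixtures and independent oracles used across test files

# vertical step image: left columns `lo`, right columns `hi`
step_image <- function(nr, nc_lo, nc_hi, lo = 0, hi = 1) {
  gray_image(cbind(matrix(lo, nr, nc_lo), matrix(hi, nr, nc_hi)))
}

# brute-force 2-D convolution oracle: explicit loops, replicate padding,
# flipped kernel
bf_convolve <- function(img, kernel) {
  nr <- nrow(img)
  nc <- ncol(img)
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  cr <- (kr + 1) / 2
  cc <- (kc + 1) / 2
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    acc <- 0
    for (u in 1:kr) for (v in 1:kc) {
      rr <- min(max(r - (u - cr), 1), nr)
      ccc <- min(max(c - (v - cc), 1), nc)
      acc <- acc + kernel[u, v] * img[rr, ccc]
    }
    out[r, c] <- acc
  }
  out
}

# brute-force nearest-neighbor distance from each 1-pixel of `from` to the
# 1-pixel set of `to`
bf_nn_dist <- function(from, to) {
  fp <- which(from == 1, arr.ind = TRUE)
  tp <- which(to == 1, arr.ind = TRUE)
  apply(fp, 1, function(p)
    min(sqrt((tp[, 1] - p[1])^2 + (tp[, 2] - p[2])^2)))
}

# brute-force tolerance matching by pixel enumeration
bf_match <- function(det, gt, tolerance) {
  d <- which(det == 1, arr.ind = TRUE)
  g <- which(gt == 1, arr.ind = TRUE)
  near <- function(p, set) {
    nrow(set) > 0 && min((set[, 1] - p[1])^2 + (set[, 2] - p[2])^2) <= tolerance^2
  }
  tp <- if (nrow(d) > 0) sum(apply(d, 1, near, set = g)) else 0L
  fn <- if (nrow(g) > 0) sum(!apply(g, 1, near, set = d)) else 0L
  c(tp = tp, fp = nrow(d) - tp, fn = fn)
}

# random low-frequency test image (smoothed noise), deterministic in seed
random_smooth_image <- function(nr, nc, seed) {
  ph <- make_phantom("MD", c(max(nr, 64), max(nc, 64)), seed = seed)
  gray_image(unclass(ph$image)[seq_len(nr), seq_len(nc)])
}

# one shared experiment run for the end-to-end assertions; computed once per
# test session
experiment_cache <- new.env(parent = emptyenv())

shared_experiment <- function() {
  if (is.null(experiment_cache$records)) {
    cfg <- experiment_config(n_per_class = 10L, size = c(96L, 96L),
                             methods = c("standard", "GS", "RS9"),
                             seed = 101L)
    experiment_cache$config <- cfg
    experiment_cache$records <- run_experiment(cfg)
  }
  experiment_cache$records
}
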