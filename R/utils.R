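# internal helpers shared across modules

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, then restores
#' the previous RNG state so callers never see global side effects. All seeded
#' operations in the package go through this helper.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with arbitrary string/numeric labels into a
#' 31-bit non-negative integer, so that every cell of an experiment grid gets
#' its own deterministic seed without storing intermediate state.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "img3", "gaussian", 0.05)
derive_seed <- function(seed, ...) {
  key <- paste(c(format(as.integer(seed)), vapply(list(...), function(x)
    paste(format(x), collapse = ","), character(1))), collapse = "|")
  h <- 0
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# replicate (edge-clamp) padding by pr rows / pc cols on each side
pad_replicate <- function(m, pr, pc) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- c(rep(1L, pr), seq_len(nr), rep(nr, pr))
  ci <- c(rep(1L, pc), seq_len(nc), rep(nc, pc))
  m[ri, ci, drop = FALSE]
}

# shift a matrix by (dr, dc) with replicate border: out[r,c] = m[r+dr, c+dc]
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# min-max normalization to [0,1]; flat input maps to all zeros
normalize01 <- function(x) {
  mn <- min(x)
  mx <- max(x)
  if (!is.finite(mn) || !is.finite(mx) || (mx - mn) < .Machine$double.eps) {
    return(array(0, dim = dim(x)))
  }
  (x - mn) / (mx - mn)
}
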