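# Seeded synthetic phantoms with exact 1-px ground-truth boundaries, standing
# in for the three complexity classes of a medical corpus: few large organs
# (LD), a moderate mix of structures and thin curves (MD), and many small
# structures plus a branching vessel-like tree and mild texture (HD). Shapes
# are placed with a 2-px clearance so every drawn boundary is a clean
# structure-vs-background step; thin curves are their own boundary.

# zero-padded shift: out[r,c] = m[r+dr, c+dc], 0 outside
shift_zero <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# 8-connected Bresenham line as a 2-col matrix of (row, col)
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0)
  dc <- abs(c1 - c0)
  sr <- sign(r1 - r0)
  sc <- sign(c1 - c0)
  err <- dc - dr
  pts <- matrix(0L, dr + dc + 1L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    pts[n, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) {
      err <- err - dr
      c0 <- c0 + sc
    }
    if (e2 < dc) {
      err <- err + dc
      r0 <- r0 + sr
    }
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic phantom with exact ground truth
#'
#' Produces a seeded synthetic image of the requested complexity class
#' together with its exact 1-pixel, 8-connected ground-truth boundary map:
#'
#' * `LD` — 1–3 large filled ellipses/rectangles on a smooth background;
#' * `MD` — 8–15 mixed shapes plus 2–4 smooth thin curves;
#' * `HD` — 30+ small shapes plus a branching vessel-like tree (random
#'   recursive bifurcation) and mild smooth texture.
#'
#' Structure intensities are separated from the background by at least 0.2 so
#' noiseless boundaries are recoverable by the detectors; the ground truth is
#' the interior rasterized boundary of every drawn structure (thin curves are
#' their own boundary) and never contains a 2x2 solid block.
#'
#' @param label `"LD"`, `"MD"` or `"HD"`.
#' @param size `c(height, width)`, both >= 64 (default 96 x 96).
#' @param seed integer seed; identical `(label, size, seed)` give
#'   bit-identical phantoms.
#' @return A `phantom`: list with `image` ([gray_image]), `gt` ([edge_map]),
#'   `label`, `seed`.
#' @export
#' @examples
#' ph <- make_phantom("LD", c(64, 64), seed = 1)
#' sum(ph$gt)
make_phantom <- function(label = c("LD", "MD", "HD"), size = c(96, 96),
                         seed = 0L) {
  label <- match.arg(label)
  h <- as.integer(size[1])
  w <- as.integer(size[2])
  if (h < 64 || w < 64) stop("phantom size must be at least 64 x 64",
                             call. = FALSE)
  with_seed(seed, {
    region <- matrix(0L, h, w)
    values <- numeric(0)
    next_id <- 0L

    new_region <- function(value) {
      next_id <<- next_id + 1L
      values[next_id] <<- value
      next_id
    }

    # is the (row, col) bounding box, expanded by `margin`, free?
    bbox_free <- function(r0, r1, c0, c1, margin = 2L) {
      r0 <- max(1L, r0 - margin)
      r1 <- min(h, r1 + margin)
      c0 <- max(1L, c0 - margin)
      c1 <- min(w, c1 + margin)
      all(region[r0:r1, c0:c1] == 0L)
    }

    ellipse_cells <- function(cr, cc, ra, rb) {
      rs <- max(1L, floor(cr - ra)):min(h, ceiling(cr + ra))
      cs <- max(1L, floor(cc - rb)):min(w, ceiling(cc + rb))
      inside <- outer(((rs - cr) / ra)^2, ((cs - cc) / rb)^2, `+`) <= 1
      cbind(rep(rs, times = length(cs))[as.vector(inside)],
            rep(cs, each = length(rs))[as.vector(inside)])
    }

    place_shapes <- function(n_target, rmin, rmax) {
      placed <- 0L
      tries <- 0L
      while (placed < n_target && tries < 400L * n_target) {
        tries <- tries + 1L
        ra <- runif(1, rmin, rmax)
        rb <- runif(1, rmin, rmax)
        cr <- runif(1, ra + 4, h - ra - 3)
        cc <- runif(1, rb + 4, w - rb - 3)
        rect <- runif(1) < 0.4
        r0 <- floor(cr - ra)
        r1 <- ceiling(cr + ra)
        c0 <- floor(cc - rb)
        c1 <- ceiling(cc + rb)
        if (!bbox_free(r0, r1, c0, c1)) next
        id <- new_region(runif(1, 0.62, 0.95))
        if (rect) {
          region[r0:r1, c0:c1] <<- id
        } else {
          cells <- ellipse_cells(cr, cc, ra, rb)
          region[cells] <<- id
        }
        placed <- placed + 1L
      }
      placed
    }

    # draw a polyline pixel-by-pixel, skipping pixels within `clear` of any
    # other structure; returns the count of painted pixels
    draw_path <- function(pts, id, clear = 2L) {
      n <- 0L
      for (i in seq_len(nrow(pts))) {
        r <- pts[i, 1]
        cc <- pts[i, 2]
        if (r < 2 || cc < 2 || r > h - 1 || cc > w - 1) next
        win <- region[max(1, r - clear):min(h, r + clear),
                      max(1, cc - clear):min(w, cc + clear)]
        if (any(win != 0L & win != id)) next
        region[r, cc] <<- id
        n <- n + 1L
      }
      n
    }

    smooth_curve_points <- function() {
      r <- runif(1, h * 0.15, h * 0.85)
      cc <- runif(1, w * 0.1, w * 0.3)
      heading <- runif(1, -0.5, 0.5)
      pts <- NULL
      for (seg in seq_len(10)) {
        len <- runif(1, 5, 10)
        r2 <- r + len * sin(heading)
        c2 <- cc + len * cos(heading)
        pts <- rbind(pts, bresenham(round(r), round(cc), round(r2), round(c2)))
        r <- r2
        cc <- c2
        heading <- heading + rnorm(1, 0, 0.35)
        if (r < 3 || r > h - 2 || cc < 3 || cc > w - 2) break
      }
      pts
    }

    grow_tree <- function(id) {
      # recursive bifurcating tree from a border point inward
      edge <- sample(4, 1)
      start <- switch(edge,
        c(2, round(runif(1, w * 0.2, w * 0.8)), pi / 2),          # top, heading down
        c(h - 1, round(runif(1, w * 0.2, w * 0.8)), -pi / 2),     # bottom, up
        c(round(runif(1, h * 0.2, h * 0.8)), 2, 0),               # left, right
        c(round(runif(1, h * 0.2, h * 0.8)), w - 1, pi))          # right, left
      grow <- function(r, cc, heading, depth) {
        len <- runif(1, 10, 18)
        jitter <- rnorm(1, 0, 0.15)
        r2 <- r + len * sin(heading + jitter)
        c2 <- cc + len * cos(heading + jitter)
        draw_path(bresenham(round(r), round(cc), round(r2), round(c2)), id)
        if (depth >= 5 || r2 < 3 || r2 > h - 2 || c2 < 3 || c2 > w - 2) return()
        spread <- runif(1, 0.35, 0.8)
        grow(r2, c2, heading + spread, depth + 1)
        if (runif(1) < 0.85) grow(r2, c2, heading - spread, depth + 1)
      }
      grow(start[1], start[2], start[3], 1)
    }

    # background: gentle ramp, optionally mild texture for HD
    b0 <- runif(1, 0.14, 0.20)
    bx <- runif(1, -0.08, 0.08)
    by <- runif(1, -0.08, 0.08)
    bg <- b0 + outer(by * seq_len(h) / h, bx * seq_len(w) / w, `+`)
    bg <- bg - min(0, min(bg)) # keep non-negative

    if (label == "LD") {
      place_shapes(sample(1:3, 1), 0.13 * min(h, w), 0.23 * min(h, w))
    } else if (label == "MD") {
      for (i in seq_len(sample(2:4, 1))) {
        draw_path(smooth_curve_points(), new_region(runif(1, 0.85, 0.98)))
      }
      place_shapes(sample(8:15, 1), 3.5, 7)
    } else {
      grow_tree(new_region(runif(1, 0.85, 0.98)))
      place_shapes(sample(32:42, 1), 2, 3.5)
    }

    img <- bg
    for (k in seq_len(next_id)) img[region == k] <- values[k]
    if (label == "HD") {
      tex <- gaussian_smooth(matrix(rnorm(h * w), h, w), 1.5)
      img <- img + tex * (0.02 / max(stats::sd(tex), 1e-12))
    }
    img <- clip01(img)

    # interior 1-px boundary: structure pixels with a background 4-neighbor
    occ <- (region > 0L) * 1L
    open4 <- shift_zero(occ, 1, 0) == 0L | shift_zero(occ, -1, 0) == 0L |
      shift_zero(occ, 0, 1) == 0L | shift_zero(occ, 0, -1) == 0L
    gt <- (occ == 1L) & open4

    # thinness: break up any 2x2 solid block (keep 3 of 4 pixels)
    repeat {
      g <- gt * 1L
      blocks <- g == 1L & shift_zero(g, 0, 1) == 1L &
        shift_zero(g, 1, 0) == 1L & shift_zero(g, 1, 1) == 1L
      if (!any(blocks)) break
      hits <- which(blocks, arr.ind = TRUE)
      gt[cbind(hits[, 1] + 1L, hits[, 2] + 1L)] <- FALSE
    }

    structure(list(image = gray_image(img), gt = edge_map(gt),
                   label = label, seed = as.integer(seed)),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s  %d x %d, %d gt pixels, seed %d\n",
              x$label, nrow(x$image), ncol(x$image), sum(x$gt), x$seed))
  invisible(x)
}

#' Generate a balanced corpus of phantoms
#'
#' Produces `n_per_class` phantoms for each of the three complexity classes,
#' with per-phantom sub-seeds derived deterministically from `seed`.
#'
#' @param n_per_class phantoms per class (>= 1).
#' @param size `c(height, width)` passed to [make_phantom()].
#' @param seed master integer seed.
#' @return List of `3 * n_per_class` `phantom` objects, grouped by class
#'   (LD first).
#' @export
#' @examples
#' corpus <- make_corpus(2, c(64, 64), seed = 1)
#' table(vapply(corpus, `[[`, "", "label"))
make_corpus <- function(n_per_class, size = c(96, 96), seed = 0L) {
  stopifnot(n_per_class >= 1)
  out <- list()
  for (label in c("LD", "MD", "HD")) {
    for (j in seq_len(n_per_class)) {
      out[[length(out) + 1L]] <-
        make_phantom(label, size, derive_seed(seed, label, j))
    }
  }
  out
}
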