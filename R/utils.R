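# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

clamp_ <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Signed shoelace area of a closed polygon (vertices as n x 2 matrix, no
# repeated end vertex). Positive for counter-clockwise orientation.
polygon_area_ <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Area centroid of a simple closed polygon.
polygon_centroid_ <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Resample a closed polyline to n vertices uniformly spaced by arc length.
# Input and output exclude the repeated end vertex.
resample_closed_ <- function(v, n) {
  vc <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(vc)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(matrix(rep(v[1, ], n), ncol = 2, byrow = TRUE))
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  cbind(stats::approx(s, vc[, 1], xout = target)$y,
        stats::approx(s, vc[, 2], xout = target)$y)
}

# Ensure counter-clockwise orientation.
orient_ccw_ <- function(v) if (polygon_area_(v) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v

# Proper-intersection test between segments p1-p2 and p3-p4.
segments_cross_ <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# Simplicity check for a closed polygon: no two non-adjacent edges cross.
# O(n^2); intended for imported user contours of modest size.
is_simple_polygon_ <- function(v) {
  n <- nrow(v)
  vc <- rbind(v, v[1, , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (segments_cross_(vc[i, ], vc[i + 1L, ], vc[j, ], vc[j + 1L, ])) return(FALSE)
    }
  }
  TRUE
}

# Triangle wave through [0, extent], starting at 0 moving up, unit speed.
triangle_wave_ <- function(t, extent, speed) {
  period <- 2 * extent / speed
  ph <- (t %% period) / period
  extent * (2 * pmin(ph, 1 - ph))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
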