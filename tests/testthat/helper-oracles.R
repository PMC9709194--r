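# Independent oracles, deliberately written differently from the package
# internals: a per-point leftward-ray crossing test for pixel counting,
# and plain textbook formulas for the statistics.

# Even-odd point-in-polygon, one point at a time, ray cast to the left
# (the package counts crossings to the right, scanline-organized). Points
# exactly on the boundary are excluded, matching the package rule; the
# ray-parity test alone gives arbitrary answers for them.
oracle_on_edge <- function(px, py, poly, tol = 1e-12) {
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    len2 <- (bx - ax)^2 + (by - ay)^2
    if (cross^2 <= tol * max(len2, tol)) {
      dot <- (px - ax) * (bx - ax) + (py - ay) * (by - ay)
      if (dot >= -tol && dot <= len2 + tol) return(TRUE)
    }
    j <- i
  }
  FALSE
}

oracle_point_in_polygon <- function(px, py, poly) {
  if (oracle_on_edge(px, py, poly)) return(FALSE)
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- poly[i, 1] + (py - yi) * (poly[j, 1] - poly[i, 1]) / (yj - yi)
      if (px > xint) inside <- !inside  # leftward ray
    }
    j <- i
  }
  inside
}

oracle_pixel_count <- function(poly, width, height) {
  n <- 0L
  for (r in seq_len(height) - 1L) {
    for (c in seq_len(width) - 1L) {
      if (oracle_point_in_polygon(c + 0.5, r + 0.5, poly)) n <- n + 1L
    }
  }
  n
}

# Textbook statistics.
oracle_one_sample_t <- function(d, mu0 = 0) {
  n <- length(d)
  t <- (mean(d) - mu0) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# A small random simple polygon: points on a jittered circle, ordered by
# angle (star-shaped, hence simple).
random_simple_polygon <- function(seed, max_extent = 12) {
  set.seed(seed)
  k <- sample(3:9, 1)
  th <- sort(runif(k, 0, 2 * pi))
  r <- runif(k, 0.2, 0.48) * max_extent
  cx <- max_extent / 2 + runif(1, -1, 1)
  cy <- max_extent / 2 + runif(1, -1, 1)
  cbind(cx + r * cos(th), cy + r * sin(th))
}
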