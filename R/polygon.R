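# Polygon primitives: shoelace area, even-odd rasterization, pixel-center
# counting. The pixel-inclusion rule is fixed package-wide: a pixel belongs
# to a region iff its center lies strictly inside the boundary polygon
# under the even-odd rule; centers exactly on the boundary are excluded.

as_polygon <- function(polygon) {
  p <- as.matrix(polygon)
  if (!is.numeric(p) || ncol(p) != 2L) {
    stop("polygon must be a 2-column numeric matrix of (x, y) vertices")
  }
  n <- nrow(p)
  if (n >= 2L && all(abs(p[1L, ] - p[n, ]) < 1e-12)) {
    p <- p[-n, , drop = FALSE]  # drop duplicated closing vertex
  }
  if (nrow(p) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  p
}

#' Shoelace polygon area
#'
#' @param polygon Two-column matrix of (x, y) vertices, in order; an
#'   explicit closing vertex is optional.
#' @return Unsigned area in the square of the coordinate unit.
#' @export
shoelace_area <- function(polygon) {
  p <- as_polygon(polygon)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Even-odd rasterization by scanline. Returns a logical [ny, nx] matrix:
# mask[r + 1, c + 1] is TRUE iff the center (x0 + c + 0.5, y0 + r + 0.5)
# of 0-based pixel (r, c) lies strictly inside the polygon. Intersections
# use the half-open vertex convention ((y1 > py) != (y2 > py)), so rays
# through vertices are counted consistently; horizontal edges never cross.
polygon_raster_mask <- function(polygon, nx, ny, x0 = 0, y0 = 0) {
  p <- as_polygon(polygon)
  n <- nrow(p)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dxdy <- ifelse(y2 == y1, 0, (x2 - x1) / (y2 - y1))
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  for (r in seq_len(ny) - 1L) {
    py <- y0 + r + 0.5
    cross <- (y1 > py) != (y2 > py)
    if (!any(cross)) next
    xs <- sort(x1[cross] + (py - y1[cross]) * dxdy[cross])
    for (k in seq_len(length(xs) %/% 2L)) {
      lo <- xs[2L * k - 1L]; hi <- xs[2L * k]
      # strict inclusion: x0 + c + 0.5 in (lo, hi)
      cmin <- max(0L, floor(lo - x0 - 0.5) + 1L)
      cmax <- min(nx - 1L, ceiling(hi - x0 - 0.5) - 1L)
      if (cmax >= cmin) mask[r + 1L, (cmin + 1L):(cmax + 1L)] <- TRUE
    }
  }
  mask
}

#' Count pixels inside a polygon
#'
#' Counts image pixels whose centers lie strictly inside the boundary
#' polygon (even-odd rule; boundary centers excluded). Pixel (row r,
#' col c), 0-based, has center (c + 0.5, r + 0.5).
#'
#' @param region A [food_region()] or a two-column (x, y) vertex matrix.
#' @param width,height Pixel grid extent; defaults to the polygon bounding
#'   box (or the region's stored grid for a `food_region`).
#' @return Integer pixel count.
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' count_pixels(sq)  # 100
#' @export
count_pixels <- function(region, width = NULL, height = NULL) {
  polygon <- if (inherits(region, "food_region")) region$polygon else region
  p <- as_polygon(polygon)
  if (is.null(width)) width <- ceiling(max(p[, 1]))
  if (is.null(height)) height <- ceiling(max(p[, 2]))
  sum(polygon_raster_mask(p, nx = width, ny = height))
}

#' Segmented food region
#'
#' Boundary polygon, pixel count and enclosing box of a segmented food
#' region, as returned by [segment_food()].
#'
#' @param polygon Two-column (x, y) vertex matrix in image coordinates.
#' @param pixel_count Number of pixel centers inside the polygon.
#' @param box The [region_box()] the segmentation was confined to.
#' @param found Logical; `FALSE` marks a not-found result (empty polygon).
#' @return An object of class `food_region`.
#' @export
food_region <- function(polygon, pixel_count, box, found = TRUE) {
  structure(list(polygon = polygon, pixel_count = pixel_count, box = box,
                 found = found),
            class = "food_region")
}

#' @export
print.food_region <- function(x, ...) {
  if (!x$found) {
    cat("<food_region> not found\n")
  } else {
    cat(sprintf("<food_region> %d boundary points, n = %d px\n",
                nrow(x$polygon), as.integer(x$pixel_count)))
  }
  invisible(x)
}
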