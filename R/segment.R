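# Plate-circle detection and food-region segmentation.
#
# Both are classical-operator pipelines: the plate is found by a
# gradient-vector Hough accumulator over a radius range; the food boundary
# is the sub-pixel iso-intensity contour at the Otsu level of the smoothed
# image, which for a high-contrast step edge coincides with the gradient
# maximum (the edge locus).

sobel_gradients <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(m)), t(kx))))
  gy <- t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(m)), t(t(kx)))))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

smooth_gray <- function(image, sigma) {
  m <- as_gray_matrix(image)
  if (sigma > 0) {
    m <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)),
                                             sigma = sigma)))
  }
  m
}

#' Detected plate circle
#'
#' @param center (x, y) center in image coordinates, px.
#' @param radius Radius, px.
#' @param score Fraction of the expected rim support that voted for the
#'   circle (0-1).
#' @param found `FALSE` marks a not-found result.
#' @return An object of class `plate_circle`.
#' @export
plate_circle <- function(center, radius, score, found = TRUE) {
  structure(list(center = center, radius = radius, score = score,
                 found = found),
            class = "plate_circle")
}

#' @export
print.plate_circle <- function(x, ...) {
  if (!x$found) {
    cat("<plate_circle> not found\n")
  } else {
    cat(sprintf("<plate_circle> center (%.1f, %.1f), r = %.1f px, score %.2f\n",
                x$center[1], x$center[2], x$radius, x$score))
  }
  invisible(x)
}

# Least-squares (Kasa) circle fit: minimizes the (optionally weighted)
# algebraic distance |x|^2 - 2 cx x - 2 cy y - c over edge points.
fit_circle_ls <- function(x, y, w = NULL) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  if (!is.null(w)) {
    sw <- sqrt(w)
    A <- A * sw
    b <- b * sw
  }
  th <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(th)) return(NULL)
  r2 <- th[3] + th[1]^2 + th[2]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(cx = th[1], cy = th[2], r = sqrt(r2))
}

#' Detect the plate circle
#'
#' Gradient-direction circular Hough search followed by a least-squares
#' refinement. Edge pixels (gradient magnitude above a noise-floor
#' multiple of the median) vote for circle centers at +/- r along their
#' gradient direction over a range of radii, into a coarse accumulator
#' that tolerates direction noise; the cell with the most raw votes wins,
#' so of two clean circles the larger one (longer rim, more votes) is
#' returned. Edge pixels in an annulus around the winning cell are then
#' fitted with an algebraic least-squares circle. The score is the
#' fraction of the rim's angular range covered by inlier edge pixels;
#' below `min_score` a not-found result is returned rather than an error.
#'
#' The plate circle reports tableware area only; it is never used as a
#' scale reference (scale comes from capture geometry).
#'
#' @param image A [food_image()].
#' @param radius_range Candidate radii in px, `c(min, max)`; default
#'   0.08-0.47 of the shorter image side.
#' @param sigma Gaussian smoothing sd before gradients, px.
#' @param edge_floor Edge threshold as a multiple of the median gradient
#'   magnitude.
#' @param min_score Minimum angular-coverage score to accept a circle.
#' @return A [plate_circle()].
#' @export
detect_plate <- function(image, radius_range = NULL, sigma = 4,
                         edge_floor = 5, min_score = 0.5) {
  stopifnot(inherits(image, "food_image"))
  m <- smooth_gray(image, sigma)
  H <- nrow(m); W <- ncol(m)
  if (is.null(radius_range)) {
    radius_range <- c(max(5, round(0.08 * min(H, W))),
                      round(0.47 * min(H, W)))
  }
  not_found <- plate_circle(c(NA, NA), NA, 0, found = FALSE)
  if (diff(range(m)) < 0.02) return(not_found)
  g <- sobel_gradients(m)
  th <- edge_floor * stats::median(g$mag)
  idx <- which(g$mag > th)
  if (length(idx) < 10L) return(not_found)
  er <- (idx - 1L) %% H       # 0-based row
  ec <- (idx - 1L) %/% H      # 0-based col
  ex <- ec + 0.5; ey <- er + 0.5
  ux <- g$gx[idx] / g$mag[idx]; uy <- g$gy[idx] / g$mag[idx]

  binw <- 4
  nbx <- ceiling(W / binw); nby <- ceiling(H / binw)
  radii <- seq(radius_range[1], radius_range[2], by = 2)
  best <- list(votes = 0)
  for (r in radii) {
    cx <- c(ex - r * ux, ex + r * ux)
    cy <- c(ey - r * uy, ey + r * uy)
    keep <- cx >= 0 & cx < W & cy >= 0 & cy < H
    if (!any(keep)) next
    bins <- floor(cx[keep] / binw) * nby + floor(cy[keep] / binw) + 1
    votes <- tabulate(bins, nbins = nbx * nby)
    v <- max(votes)
    if (v > best$votes) {
      b <- which.max(votes) - 1L
      best <- list(votes = v, r = r,
                   cx = (b %/% nby + 0.5) * binw,
                   cy = (b %% nby + 0.5) * binw)
    }
  }
  if (best$votes < 5) return(not_found)

  # refine center and radius on annulus inliers, weighted by gradient
  # magnitude (the blur halo is symmetric about the true edge, so the
  # magnitude-weighted fit centers on it); annulus tolerance shrinks with
  # each pass but never below the blur scale
  cx <- best$cx; cy <- best$cy; r <- best$r
  mag <- g$mag[idx]
  tols <- c(max(3 * sigma, 0.1 * r), max(2 * sigma, 0.05 * r),
            max(2 * sigma, 0.04 * r))
  for (tol in tols) {
    d <- sqrt((ex - cx)^2 + (ey - cy)^2)
    # rim pixels have radial gradients; drop edges whose direction is off
    # by more than ~35 degrees (e.g. food boundaries near the rim)
    radial <- abs(ux * (ex - cx) + uy * (ey - cy)) / pmax(d, 1e-9)
    inl <- abs(d - r) < tol & radial > 0.8
    if (sum(inl) < 10L) return(not_found)
    # cap weights at their 70th percentile so a few very strong non-rim
    # edges cannot dominate the faint rim
    w <- pmin(mag[inl], stats::quantile(mag[inl], 0.7))
    fit <- fit_circle_ls(ex[inl], ey[inl], w = w)
    if (is.null(fit)) return(not_found)
    cx <- fit$cx; cy <- fit$cy; r <- fit$r
  }
  d <- sqrt((ex - cx)^2 + (ey - cy)^2)
  inl <- abs(d - r) < max(3, 0.03 * r)
  ang_bins <- unique(floor((atan2(ey[inl] - cy, ex[inl] - cx) + pi) /
                             (2 * pi) * 90))
  score <- length(ang_bins) / 90
  if (score < min_score || r <= 0) return(not_found)
  plate_circle(c(cx, cy), r, score)
}

#' Segment the food region
#'
#' Finds the food boundary inside a region of interest: the smoothed
#' grayscale crop is thresholded at the Otsu level, the boundary polygon is
#' extracted as the sub-pixel iso-contour at that level, and the pixel
#' count is the number of pixel centers strictly inside the polygon
#' (even-odd rule, via [count_pixels()]). Among closed contours the one
#' enclosing the largest area is taken as the food boundary. When the crop
#' is effectively uniform, or the two Otsu intensity classes are closer
#' than `min_contrast`, or no closed contour exists, a not-found region is
#' returned rather than an error.
#'
#' @param image A [food_image()].
#' @param box A [region_box()] confining the search; default whole image.
#' @param sigma Gaussian smoothing sd, px.
#' @param min_contrast Minimum separation of the mean intensities of the
#'   two threshold classes for a region to count as present.
#' @return A [food_region()] with the polygon in full-image coordinates.
#' @export
segment_food <- function(image, box = NULL, sigma = 1, min_contrast = 0.15) {
  stopifnot(inherits(image, "food_image"))
  box <- if (is.null(box)) whole_image_box(image) else clip_box(box, image)
  m <- smooth_gray(image, sigma)
  m <- m[(box$row0 + 1L):box$row1, (box$col0 + 1L):box$col1, drop = FALSE]
  not_found <- food_region(NULL, 0L, box, found = FALSE)
  if (diff(range(m)) < min_contrast) return(not_found)
  level <- EBImage::otsu(EBImage::Image(t(m)))
  lo <- mean(m[m <= level]); hi <- mean(m[m > level])
  if (!is.finite(lo) || !is.finite(hi) || (hi - lo) < min_contrast) {
    return(not_found)
  }
  nyx <- dim(m)
  cl <- grDevices::contourLines(x = seq_len(nyx[2]) - 0.5,
                                y = seq_len(nyx[1]) - 0.5,
                                z = t(m), levels = level)
  closed <- Filter(function(ct) {
    length(ct$x) >= 4 &&
      abs(ct$x[1] - ct$x[length(ct$x)]) < 1e-9 &&
      abs(ct$y[1] - ct$y[length(ct$y)]) < 1e-9
  }, cl)
  if (length(closed) == 0L) return(not_found)
  areas <- vapply(closed, function(ct) shoelace_area(cbind(ct$x, ct$y)),
                  numeric(1))
  ct <- closed[[which.max(areas)]]
  poly <- cbind(x = ct$x + box$col0, y = ct$y + box$row0)
  n <- count_pixels(poly, width = ncol(image$data), height = nrow(image$data))
  if (n == 0L) return(not_found)
  food_region(poly, n, box)
}
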