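# Image container and I/O.
#
# Pixel data are stored as plain R arrays in [row, col] (grayscale) or
# [row, col, channel] (RGB) order with intensities in [0, 1]. EBImage
# stores [x, y(, channel)], so conversion transposes at the boundary.
#
# Continuous image coordinates: x runs along columns, y along rows, origin
# at the top-left image corner; pixel (row r, col c), 0-based, has its
# center at (c + 0.5, r + 0.5). Polygons, circles and boxes all live in
# this coordinate system.

#' Food image container
#'
#' Wraps a pixel array together with optional capture metadata.
#'
#' @param data Numeric matrix (grayscale) or `[row, col, 3]` array (RGB)
#'   with values in `[0, 1]`.
#' @param spec Optional [camera_spec()] describing the capturing camera.
#' @param geom Optional [capture_geometry()].
#' @return An object of class `food_image`.
#' @export
food_image <- function(data, spec = NULL, geom = NULL) {
  stopifnot(is.numeric(data), length(dim(data)) %in% c(2L, 3L))
  if (length(dim(data)) == 3L && dim(data)[3] != 3L) {
    stop("RGB image must have 3 channels")
  }
  if (any(dim(data)[1:2] == 0L)) stop("empty image")
  if (!is.null(spec)) stopifnot(inherits(spec, "camera_spec"))
  if (!is.null(geom)) stopifnot(inherits(geom, "capture_geometry"))
  structure(list(data = data, spec = spec, geom = geom),
            class = "food_image")
}

#' @export
print.food_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<food_image> %d x %d px (%s)%s\n", d[2], d[1],
              if (length(d) == 3L) "RGB" else "grayscale",
              if (!is.null(x$spec)) sprintf(", f35 = %g mm", x$spec$f35)
              else ""))
  invisible(x)
}

#' @export
dim.food_image <- function(x) dim(x$data)

#' Read an image file
#'
#' Reads PNG/JPEG/TIFF via EBImage and returns a [food_image()]. Color
#' images are kept as RGB; alpha channels are dropped.
#'
#' @param path File path.
#' @inheritParams food_image
#' @return A `food_image`.
#' @export
read_food_image <- function(path, spec = NULL, geom = NULL) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(a)[3] == 1L) a <- a[, , 1]
  }
  data <- if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
  food_image(data, spec = spec, geom = geom)
}

#' Write an image to file
#'
#' @param image A [food_image()].
#' @param path Output path; format from extension (png, jpeg, tiff).
#' @export
write_food_image <- function(image, path) {
  stopifnot(inherits(image, "food_image"))
  a <- image$data
  img <- if (length(dim(a)) == 3L) {
    EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
  } else {
    EBImage::Image(t(a))
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

# Grayscale view of the pixel data (luma weights for RGB).
as_gray_matrix <- function(image) {
  a <- if (inherits(image, "food_image")) image$data else image
  if (length(dim(a)) == 2L) return(a)
  0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
}

#' Axis-aligned region box
#'
#' A rectangular region of interest in 0-based, half-open pixel
#' coordinates: rows `row0 <= r < row1`, columns `col0 <= c < col1`.
#'
#' @param row0,row1,col0,col1 Integer bounds.
#' @return An object of class `region_box`.
#' @export
region_box <- function(row0, row1, col0, col1) {
  stopifnot(row0 >= 0, col0 >= 0, row1 > row0, col1 > col0)
  structure(list(row0 = as.integer(row0), row1 = as.integer(row1),
                 col0 = as.integer(col0), col1 = as.integer(col1)),
            class = "region_box")
}

whole_image_box <- function(image) {
  d <- dim(image$data)
  region_box(0L, d[1], 0L, d[2])
}

clip_box <- function(box, image) {
  d <- dim(image$data)
  if (box$row1 > d[1] || box$col1 > d[2]) {
    stop("region box exceeds image bounds")
  }
  box
}
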