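# Unit convention used throughout this module (documented prominently):
#   object distance u ........ cm
#   focal lengths f, f35 ..... mm
#   object-plane lengths ..... cm
#   object-plane areas ....... cm^2
# With u in cm and f35 in mm, the thin-lens object length
#   L_mm = frame_mm * (x/axis_px) * (u_mm/f35 - 1)
# becomes, after u_mm = 10 u and mm -> cm,
#   L_cm = frame_mm * (x/axis_px) * (u/f35 - 0.1).
# The 0.1 in the bracket is purely this mixed-unit convention; no other
# choice of units reproduces it, which is how the convention was fixed.

# Full-frame (36 x 24 mm) geometry from which every equivalent-frame
# constant is derived. A 35-mm-equivalent focal length is the focal length
# a full-frame camera would need for the same diagonal field of view, so
# the equivalent frame for an aspect ratio is the rectangle of that aspect
# sharing the full-frame diagonal.
FF_WIDTH_MM  <- 36
FF_HEIGHT_MM <- 24

#' Equivalent-frame dimensions for an aspect ratio
#'
#' Derives, from the 36 x 24 mm full frame, the dimensions of the frame a
#' sensor of the given aspect ratio is mapped onto when focal lengths are
#' expressed as 35-mm equivalents: the rectangle with that aspect ratio and
#' the full-frame diagonal (43.27 mm). For 4:3 this gives the
#' 34.6 x 26.0 mm frame underlying all pixel-to-length conversions; for 3:2
#' it is the full frame itself.
#'
#' @param aspect `"4:3"` or `"3:2"`.
#' @return Named numeric vector with elements `long`, `short`, `diagonal`
#'   (mm), and the width conversion constant `width_const` such that
#'   f35 = width_const * f / w for a sensor of width `w` mm.
#' @examples
#' equivalent_frame("4:3")  # long 34.61, short 25.96, diagonal 43.27
#' @export
equivalent_frame <- function(aspect = c("4:3", "3:2")) {
  aspect <- match.arg(aspect)
  d35 <- sqrt(FF_WIDTH_MM^2 + FF_HEIGHT_MM^2)
  ar <- switch(aspect, "4:3" = 4 / 3, "3:2" = 3 / 2)
  short <- d35 / sqrt(1 + ar^2)
  long <- ar * short
  c(long = long, short = short, diagonal = d35, width_const = long)
}

# Printed-precision equivalent frame used by the ground-sample formulas.
# These are equivalent_frame("4:3") rounded to 3 significant figures; the
# rounded values are used (rather than the exact ones) so that computed
# lengths match the published conversion table exactly.
EQ_LONG_MM  <- 34.6
EQ_SHORT_MM <- 26.0
EQ_DIAG_MM  <- 43.3
EQ_32_WIDTH_MM <- 36.0

#' Camera specification
#'
#' Resolution and 35-mm-equivalent focal length of the capturing camera.
#' `width_px` counts pixels along the *short* equivalent side (26.0 mm for
#' 4:3) and `height_px` along the *long* side (34.6 mm); a landscape image
#' is normalized so that `width_px <= height_px`.
#'
#' @param f35 35-mm-equivalent focal length, mm.
#' @param width_px Pixel count along the short equivalent side.
#' @param height_px Pixel count along the long equivalent side.
#' @param aspect Declared aspect ratio, `"4:3"` or `"3:2"`.
#' @return An object of class `camera_spec`.
#' @examples
#' camera_spec(f35 = 46, width_px = 3000, height_px = 4000)
#' @export
camera_spec <- function(f35, width_px, height_px, aspect = c("4:3", "3:2")) {
  aspect <- match.arg(aspect)
  stopifnot(is.numeric(f35), length(f35) == 1L, f35 > 0)
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  stopifnot(width_px > 0L, height_px > 0L)
  if (width_px > height_px) {  # orientation normalization
    tmp <- width_px; width_px <- height_px; height_px <- tmp
  }
  ar <- switch(aspect, "4:3" = 4 / 3, "3:2" = 3 / 2)
  if (abs(height_px / width_px - ar) / ar > 0.01) {
    stop("declared aspect ", aspect, " inconsistent with ",
         width_px, "x", height_px, " (>1% off)")
  }
  structure(list(f35 = f35, width_px = width_px, height_px = height_px,
                 aspect = aspect),
            class = "camera_spec")
}

#' @export
print.camera_spec <- function(x, ...) {
  cat(sprintf("<camera_spec> f35 = %g mm, %d x %d px (%s)\n",
              x$f35, x$width_px, x$height_px, x$aspect))
  invisible(x)
}

#' Physical sensor specification
#'
#' Describes the true focal length and physical sensor size, from which the
#' 35-mm-equivalent focal length can be computed. At least one of
#' `sensor_width_mm` and `sensor_diagonal_mm` is required.
#'
#' @param f True focal length, mm.
#' @param sensor_width_mm Sensor width, mm (optional).
#' @param sensor_diagonal_mm Sensor diagonal, mm (optional).
#' @param aspect `"4:3"` or `"3:2"`.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(f, sensor_width_mm = NULL, sensor_diagonal_mm = NULL,
                        aspect = c("4:3", "3:2")) {
  aspect <- match.arg(aspect)
  stopifnot(is.numeric(f), length(f) == 1L, f > 0)
  if (is.null(sensor_width_mm) && is.null(sensor_diagonal_mm)) {
    stop("sensor_spec requires at least one of sensor_width_mm, ",
         "sensor_diagonal_mm")
  }
  if (!is.null(sensor_width_mm) && !is.null(sensor_diagonal_mm)) {
    ar <- switch(aspect, "4:3" = 4 / 3, "3:2" = 3 / 2)
    implied_d <- sensor_width_mm * sqrt(1 + 1 / ar^2)
    if (abs(implied_d - sensor_diagonal_mm) / sensor_diagonal_mm > 0.01) {
      stop("sensor width and diagonal inconsistent with aspect ", aspect)
    }
  }
  structure(list(f = f, w = sensor_width_mm, d = sensor_diagonal_mm,
                 aspect = aspect),
            class = "sensor_spec")
}

#' Capture geometry
#'
#' @param object_distance_cm Camera-to-food-plane distance, cm. Must exceed
#'   0.1 times the equivalent focal length in mm (object beyond the focal
#'   plane); this is validated where a `camera_spec` is available.
#' @return An object of class `capture_geometry`.
#' @export
capture_geometry <- function(object_distance_cm) {
  stopifnot(is.numeric(object_distance_cm), length(object_distance_cm) == 1L,
            object_distance_cm > 0)
  structure(list(u = object_distance_cm), class = "capture_geometry")
}

check_geometry <- function(u, f35) {
  if (u / f35 <= 0.1) {
    stop("object at or inside the focal plane: u/f35 = ",
         format(u / f35), " <= 0.1 (u in cm, f35 in mm)")
  }
  invisible(TRUE)
}

#' 35-mm-equivalent focal length from a physical sensor
#'
#' Converts a true focal length to its 35-mm equivalent using the sensor
#' width or diagonal. The conversion constants follow from matching the
#' field of view against the equivalent frame: 34.6 f/w (4:3 by width),
#' 36.0 f/w (3:2 by width), 43.3 f/d (either aspect by diagonal, preferred
#' when both dimensions are supplied).
#'
#' @param sensor A [sensor_spec()].
#' @return The equivalent focal length, mm.
#' @examples
#' equivalent_focal_length(sensor_spec(10, sensor_width_mm = 34.6))  # 10
#' equivalent_focal_length(sensor_spec(4.25, sensor_width_mm = 5.76))
#' @export
equivalent_focal_length <- function(sensor) {
  stopifnot(inherits(sensor, "sensor_spec"))
  if (!is.null(sensor$d)) {
    return(EQ_DIAG_MM * sensor$f / sensor$d)
  }
  wconst <- switch(sensor$aspect, "4:3" = EQ_LONG_MM, "3:2" = EQ_32_WIDTH_MM)
  wconst * sensor$f / sensor$w
}

#' Object-plane length of a pixel extent
#'
#' Maps a pixel extent `x` along one image axis to the physical length it
#' spans in the object plane:
#' `C * (x / axis_px) * (u / f35 - 0.1)` cm, with `C = 26.0` mm for the
#' short axis and `C = 34.6` mm for the long axis of the 4:3 equivalent
#' frame. `u` is in cm and `f35` in mm; the 0.1 arises from that mixed-unit
#' convention (see [thin_lens_object_length()] for the underlying optics).
#'
#' @param x Pixel extent, 0 <= x <= axis_px.
#' @param axis_px Full-image pixel count along the same axis.
#' @param u Object distance, cm.
#' @param f35 Equivalent focal length, mm.
#' @param axis `"short"` (26.0 mm side) or `"long"` (34.6 mm side).
#' @return Length in cm.
#' @examples
#' ground_sample_length(3000, 3000, u = 40.6, f35 = 46, axis = "long")
#' @export
ground_sample_length <- function(x, axis_px, u, f35,
                                 axis = c("short", "long")) {
  axis <- match.arg(axis)
  stopifnot(all(x >= 0), all(x <= axis_px), axis_px > 0, u > 0, f35 > 0)
  check_geometry(u, f35)
  C <- if (axis == "short") EQ_SHORT_MM else EQ_LONG_MM
  C * (x / axis_px) * (u / f35 - 0.1)
}

#' Object-plane area of one pixel
#'
#' The cm^2 spanned by a single pixel at the given camera and capture
#' geometry: `[(26.0/a) * (u/f35 - 0.1)]^2` where `a` is the pixel count
#' along the short equivalent side. The long-side form
#' `[(34.6/b) * (u/f35 - 0.1)]^2` is equal within the aspect tolerance and
#' is used only as a consistency check; the short-side form is canonical.
#'
#' @param spec A [camera_spec()].
#' @param geom A [capture_geometry()].
#' @return Scale in cm^2 per pixel.
#' @export
pixel_area_scale <- function(spec, geom) {
  stopifnot(inherits(spec, "camera_spec"), inherits(geom, "capture_geometry"))
  check_geometry(geom$u, spec$f35)
  ((EQ_SHORT_MM / spec$width_px) * (geom$u / spec$f35 - 0.1))^2
}

#' Physical area of a pixel region
#'
#' Converts a pixel count to object-plane area:
#' `S = n * [(26.0/a) * (u/f35 - 0.1)]^2` cm^2. Linear in `n`; quadratic in
#' the distance bracket `(u/f35 - 0.1)`.
#'
#' @param n Pixel count, >= 0.
#' @param spec A [camera_spec()].
#' @param geom A [capture_geometry()].
#' @return An object of class `area_estimate`: list with `pixel_count`,
#'   `scale_cm2_per_px` and `area_cm2`.
#' @examples
#' spec <- camera_spec(46, 3000, 4000)
#' region_area(1e6, spec, capture_geometry(40.6))
#' @export
region_area <- function(n, spec, geom) {
  stopifnot(is.numeric(n), length(n) == 1L)
  if (n < 0) stop("pixel count must be non-negative")
  scale <- pixel_area_scale(spec, geom)
  structure(list(pixel_count = n, scale_cm2_per_px = scale,
                 area_cm2 = n * scale),
            class = "area_estimate")
}

#' @export
print.area_estimate <- function(x, ...) {
  cat(sprintf("<area_estimate> n = %g px x %.4g cm^2/px = %.4g cm^2\n",
              x$pixel_count, x$scale_cm2_per_px, x$area_cm2))
  invisible(x)
}

#' Thin-lens object length (independent optics oracle)
#'
#' Solves the thin-lens equation 1/v + 1/u = 1/f for the image distance
#' v = f u / (u - f), takes the magnification m = v/u = f/(u - f), and
#' returns the object-plane length corresponding to an image-plane length:
#' `image_length * (u - f) / f`. All arguments in mm. This is the
#' first-principles derivation that [ground_sample_length()] must agree
#' with; it is kept separate so the two can be checked against each other.
#'
#' @param image_length_mm Length on the (equivalent) image plane, mm.
#' @param u Object distance, mm. Must exceed `f` (real image).
#' @param f Focal length, mm.
#' @return Object-plane length, mm.
#' @examples
#' thin_lens_object_length(26, u = 2 * 46, f = 46)  # unit magnification
#' @export
thin_lens_object_length <- function(image_length_mm, u, f) {
  stopifnot(u > 0, f > 0)
  if (u <= f) stop("no real image: object distance must exceed focal length")
  image_length_mm * (u - f) / f
}
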