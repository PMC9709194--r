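# Classifier-path preprocessing and training-set augmentation.
#
# These operate on the recognition path only: area measurement always uses
# the native-resolution image, never the 224 x 224 rescale.

#' Preprocess an image for the classifier path
#'
#' Center-crops to a 1:1 aspect ratio, then rescales to `size` x `size`
#' pixels (default 224). Used only to normalize inputs for a food-type
#' classifier; pixel-count area measurement must use the original image.
#'
#' @param image A [food_image()].
#' @param size Output side length in pixels.
#' @return A `food_image` of dimensions `size` x `size` (metadata dropped,
#'   since the crop invalidates the pixel-to-length scale).
#' @export
preprocess_image <- function(image, size = 224L) {
  stopifnot(inherits(image, "food_image"), size >= 1)
  a <- image$data
  d <- dim(a)
  side <- min(d[1], d[2])
  r0 <- (d[1] - side) %/% 2L
  c0 <- (d[2] - side) %/% 2L
  a <- if (length(d) == 3L) {
    a[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
  } else {
    a[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
  }
  img <- if (length(dim(a)) == 3L) {
    EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
  } else {
    EBImage::Image(t(a))
  }
  out <- EBImage::resize(img, w = size, h = size)
  b <- EBImage::imageData(out)
  data <- if (length(dim(b)) == 3L) aperm(b, c(2, 1, 3)) else t(b)
  food_image(pmin(pmax(data, 0), 1))
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Augment an image
#'
#' One of the three training-set augmentations: contrast/brightness
#' increase, additive Gaussian noise, or a lossless 90-degree rotation.
#' Applying all three to a set of k images yields 3k new images. All modes
#' are deterministic given `seed`.
#'
#' @param image A [food_image()].
#' @param mode `"contrast_brightness"`, `"noise"` or `"rotate90"`.
#' @param seed Integer seed (used by the `"noise"` mode).
#' @param contrast Contrast gain about mid-gray (contrast_brightness mode).
#' @param brightness Additive brightness offset (contrast_brightness mode).
#' @param noise_sd Noise standard deviation in intensity units.
#' @return A `food_image`.
#' @export
augment_image <- function(image,
                          mode = c("contrast_brightness", "noise", "rotate90"),
                          seed = 0L, contrast = 1.2, brightness = 0.1,
                          noise_sd = 0.02) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "food_image"))
  a <- image$data
  out <- switch(mode,
    contrast_brightness = pmin(pmax((a - 0.5) * contrast + 0.5 + brightness,
                                    0), 1),
    noise = with_seed(seed,
      pmin(pmax(a + rnorm(length(a), sd = noise_sd), 0), 1)),
    rotate90 = {
      if (length(dim(a)) == 3L) {
        d <- dim(a)
        r <- array(0, c(d[2], d[1], 3L))
        for (ch in 1:3) r[, , ch] <- rot90_cw(a[, , ch])
        r
      } else {
        rot90_cw(a)
      }
    })
  food_image(out)
}
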