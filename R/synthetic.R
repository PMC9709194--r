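# Synthetic top-view scene generator.
#
# Emulates the capture protocol behind the shipped calibrations: fixed
# 35-mm-equivalent focal length 46 mm, shooting height 40.6 cm, top-down
# view, uniform light background. Scenes carry exact ground truth (object
# plane polygon in cm, its shoelace area, its pixel rasterization, and a
# trait-consistent weight), so the whole pipeline can be checked
# closed-loop against known values.

#' Default synthetic camera
#'
#' 640 x 480 px, 4:3, f35 = 46 mm; paired with the 40.6 cm shooting height
#' this gives a pixel pitch of ~0.0424 cm/px and a 27.1 x 20.3 cm field of
#' view, comfortably holding a dinner plate.
#'
#' @return A [camera_spec()].
#' @export
default_scene_camera <- function() camera_spec(46, 480L, 640L)

#' Synthetic scene specification
#'
#' Geometry in object-plane cm coordinates with the optical axis at the
#' origin: a plate disk, a food polygon, flat intensities and additive
#' Gaussian pixel noise. Food and plate/background intensities must be
#' separated by at least `contrast_margin` so the scene is segmentable.
#'
#' @param camera A [camera_spec()]; default [default_scene_camera()].
#' @param geom A [capture_geometry()]; default 40.6 cm.
#' @param plate_center_cm,plate_radius_cm Plate disk, cm.
#' @param food_polygon_cm Two-column (x, y) vertex matrix in cm, or `NULL`
#'   for a plate-only scene.
#' @param trait One of [trait_classes()].
#' @param intensities Named vector with `background`, `plate`, `food` in
#'   `[0, 1]`.
#' @param noise_sd Pixel noise sd in intensity units.
#' @param weight_noise_sd_g Sd of the weight noise draw, g; default the
#'   trait's calibrated noise level ([trait_noise_sd()]).
#' @param seed Integer seed driving both noise draws.
#' @param contrast_margin Minimum food-to-surroundings intensity gap.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(camera = default_scene_camera(),
                       geom = capture_geometry(40.6),
                       plate_center_cm = c(0, 0), plate_radius_cm = 8.5,
                       food_polygon_cm = NULL,
                       trait = "block_thick_bar",
                       intensities = c(background = 0.92, plate = 0.98,
                                       food = 0.30),
                       noise_sd = 0.02, weight_noise_sd_g = NULL,
                       seed = 0L, contrast_margin = 0.3) {
  check_trait(trait)
  stopifnot(inherits(camera, "camera_spec"),
            inherits(geom, "capture_geometry"),
            all(c("background", "plate", "food") %in% names(intensities)),
            plate_radius_cm > 0, noise_sd >= 0)
  gap <- min(abs(intensities["food"] - intensities["plate"]),
             abs(intensities["food"] - intensities["background"]))
  if (gap < contrast_margin) {
    stop("food intensity within ", contrast_margin,
         " of plate/background; scene not segmentable")
  }
  if (is.null(weight_noise_sd_g)) weight_noise_sd_g <- trait_noise_sd(trait)
  if (!is.null(food_polygon_cm)) food_polygon_cm <- as_polygon(food_polygon_cm)
  structure(list(camera = camera, geom = geom,
                 plate_center_cm = plate_center_cm,
                 plate_radius_cm = plate_radius_cm,
                 food_polygon_cm = food_polygon_cm, trait = trait,
                 intensities = intensities, noise_sd = noise_sd,
                 weight_noise_sd_g = weight_noise_sd_g,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Calibrated weight-noise level for a trait
#'
#' The Gaussian weight-noise sd that reproduces a target R-squared when
#' areas are uniform on `area_range`: sd = |slope| * sd(area) *
#' sqrt(1/R^2 - 1), with sd(area) = range/sqrt(12). Defaults reproduce the
#' shipped models' R-squared values.
#'
#' @param trait One of [trait_classes()].
#' @param area_range Area range, cm^2.
#' @param r_squared Target R-squared; default the trait's shipped value.
#' @return Noise sd in g.
#' @export
trait_noise_sd <- function(trait, area_range = c(30, 150),
                           r_squared = NULL) {
  check_trait(trait)
  m <- default_models()[[trait]]
  if (is.null(r_squared)) r_squared <- m$r_squared
  abs(m$slope) * (diff(area_range) / sqrt(12)) * sqrt(1 / r_squared - 1)
}

#' Render a synthetic scene
#'
#' Maps the cm geometry to pixels through the inverse of
#' [pixel_area_scale()] (isotropic pixel pitch), rasterizes plate then
#' food by the package's pixel-center rule, then adds seeded Gaussian
#' pixel noise. Ground truth is computed before the noise: physical area
#' by shoelace on the cm polygon, pixel count from the rasterization, and
#' weight from the trait model plus a recorded noise draw, floored at 0.
#' Identical seeds give bit-identical images.
#'
#' @param scene A [scene_spec()].
#' @return List with `image` (a [food_image()]) and `truth` (class
#'   `ground_truth`: `area_cm2`, `pixel_count`, `weight_g`,
#'   `weight_noise_g`, `polygon_px`, `scale_cm2_per_px`).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  spec <- scene$camera
  W <- spec$height_px   # landscape: columns along the long side
  H <- spec$width_px
  scale <- pixel_area_scale(spec, scene$geom)
  k <- 1 / sqrt(scale)  # px per cm
  cx <- W / 2; cy <- H / 2
  ints <- scene$intensities
  img <- matrix(ints[["background"]], nrow = H, ncol = W)

  xs_cm <- ((seq_len(W) - 0.5) - cx) / k
  ys_cm <- ((seq_len(H) - 0.5) - cy) / k
  dx2 <- outer(rep(1, H), (xs_cm - scene$plate_center_cm[1])^2)
  dy2 <- outer((ys_cm - scene$plate_center_cm[2])^2, rep(1, W))
  img[dx2 + dy2 <= scene$plate_radius_cm^2] <- ints[["plate"]]

  truth_area <- 0
  truth_n <- 0L
  poly_px <- NULL
  if (!is.null(scene$food_polygon_cm)) {
    p <- scene$food_polygon_cm
    poly_px <- cbind(cx + p[, 1] * k, cy + p[, 2] * k)
    if (min(poly_px) < 0 || max(poly_px[, 1]) > W || max(poly_px[, 2]) > H) {
      stop("food polygon outside the field of view")
    }
    mask <- polygon_raster_mask(poly_px, nx = W, ny = H)  # [row, col]
    img[mask] <- ints[["food"]]
    truth_area <- shoelace_area(p)
    truth_n <- sum(mask)
  }

  model <- default_models()[[scene$trait]]
  out <- with_seed(scene$seed, {
    noise_g <- rnorm(1, sd = scene$weight_noise_sd_g)
    noisy <- if (scene$noise_sd > 0) {
      pmin(pmax(img + rnorm(length(img), sd = scene$noise_sd), 0), 1)
    } else img
    list(noise_g = noise_g, img = noisy)
  })
  weight <- max(model$slope * truth_area + model$intercept + out$noise_g, 0)
  list(
    image = food_image(out$img, spec = spec, geom = scene$geom),
    truth = structure(list(area_cm2 = truth_area, pixel_count = truth_n,
                           weight_g = weight, weight_noise_g = out$noise_g,
                           trait = scene$trait, polygon_px = poly_px,
                           scale_cm2_per_px = scale),
                      class = "ground_truth")
  )
}

#' Random convex food polygon of a given area
#'
#' Convex hull of radially jittered points on a circle, rescaled so the
#' shoelace area equals `area_cm2` exactly.
#'
#' @param area_cm2 Target area, cm^2.
#' @param n_vertices Number of boundary points before the hull.
#' @param irregularity Radial jitter fraction.
#' @param seed Integer seed.
#' @param center_cm Polygon centroid offset, cm.
#' @return Two-column (x, y) vertex matrix, cm.
#' @export
random_food_polygon <- function(area_cm2, n_vertices = 12,
                                irregularity = 0.25, seed = 0L,
                                center_cm = c(0, 0)) {
  stopifnot(area_cm2 > 0, n_vertices >= 3)
  with_seed(seed, {
    th <- sort(runif(n_vertices, 0, 2 * pi))
    r <- 1 + runif(n_vertices, -irregularity, irregularity)
    pts <- cbind(r * cos(th), r * sin(th))
    hull <- grDevices::chull(pts)
    p <- pts[hull, , drop = FALSE]
    p <- p * sqrt(area_cm2 / shoelace_area(p))
    cbind(p[, 1] + center_cm[1], p[, 2] + center_cm[2])
  })
}

#' Random full scene
#'
#' A random trait and a random convex food blob with area uniform on
#' `area_range`, plated so the food stays inside the plate rim: the food
#' center offset is drawn within the margin left between the blob's
#' maximum radial extent and the plate radius.
#'
#' @param seed Integer seed.
#' @param area_range Food area range, cm^2.
#' @param plate_radius_cm Plate radius, cm.
#' @param ... Passed to [scene_spec()].
#' @return A [scene_spec()].
#' @export
random_scene <- function(seed, area_range = c(30, 150),
                         plate_radius_cm = 8.5, ...) {
  draw <- with_seed(seed, {
    list(area = runif(1, area_range[1], area_range[2]),
         trait = sample(trait_classes(), 1),
         u = runif(2, -1, 1),
         poly_seed = sample.int(2^30, 1))
  })
  poly <- random_food_polygon(draw$area, irregularity = 0.2,
                              seed = draw$poly_seed)
  margin <- max(0, plate_radius_cm - max(sqrt(rowSums(poly^2))) - 0.3)
  off <- draw$u * min(1.5, margin)
  poly <- cbind(poly[, 1] + off[1], poly[, 2] + off[2])
  scene_spec(food_polygon_cm = poly, trait = draw$trait,
             plate_radius_cm = plate_radius_cm, seed = seed, ...)
}

#' Generate a synthetic calibration set
#'
#' Emulates the calibration campaign behind the shipped models: for each
#' trait, `n_per_trait` records with machine-recognized areas uniform on
#' `area_range` and weights from the trait's default model plus Gaussian
#' noise, floored at 0. The default noise sd per trait is
#' [trait_noise_sd()], which reproduces the shipped R-squared values.
#' Deterministic per seed.
#'
#' @param n_per_trait Records per trait (>= 3).
#' @param noise_sd_g Single noise sd for all traits, or `NULL` for the
#'   per-trait calibrated defaults.
#' @param area_range Area range, cm^2.
#' @param seed Integer seed.
#' @return Data frame in the calibration CSV schema
#'   (`food,trait,machine_area_cm2,actual_area_cm2,weight_g`),
#'   `3 * n_per_trait` rows.
#' @export
generate_calibration_set <- function(n_per_trait = 204, noise_sd_g = NULL,
                                     area_range = c(30, 150), seed = 0L) {
  stopifnot(n_per_trait >= 3)
  foods <- food_traits()
  models <- default_models()
  with_seed(seed, {
    recs <- lapply(trait_classes(), function(tr) {
      m <- models[[tr]]
      sdg <- if (is.null(noise_sd_g)) {
        trait_noise_sd(tr, area_range)
      } else noise_sd_g
      area <- runif(n_per_trait, area_range[1], area_range[2])
      w <- pmax(m$slope * area + m$intercept + rnorm(n_per_trait, sd = sdg),
                0)
      data.frame(
        food = sample(foods$food[foods$trait == tr], n_per_trait,
                      replace = TRUE),
        trait = tr,
        machine_area_cm2 = area,
        actual_area_cm2 = NA_real_,
        weight_g = w,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, recs)
  })
}
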