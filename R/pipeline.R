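# End-to-end pipeline: classify -> segment -> area -> weight -> report.
#
# The cloud food-type classifier is replaced by a pluggable interface with
# a deterministic label-lookup stub, so the pipeline is self-contained and
# testable offline.

#' Classify a food image
#'
#' Dispatches to a pluggable classifier function `function(image, label)`
#' returning `list(label, confidence)`. The default stub trusts a sidecar
#' `label` (e.g. from the filename) with confidence 1. The trait is then
#' attached from the shipped 51-dish lookup; an unknown label yields trait
#' `NA`, which downstream forces an explicit `trait` argument.
#'
#' @param image A [food_image()] (unused by the stub, passed to custom
#'   classifiers).
#' @param label Sidecar label for the stub classifier.
#' @param classifier Optional classifier function.
#' @return List of class `classifier_result`: `label`, `confidence`,
#'   `trait`.
#' @examples
#' classify_food(label = "French fries")$trait  # block_thick_bar
#' @export
classify_food <- function(image = NULL, label = NULL, classifier = NULL) {
  res <- if (is.null(classifier)) {
    list(label = if (is.null(label)) "unknown" else label, confidence = 1)
  } else {
    classifier(image, label)
  }
  trait <- if (identical(res$label, "unknown")) NA_character_ else {
    lookup_trait(res$label)
  }
  structure(list(label = res$label, confidence = res$confidence,
                 trait = trait),
            class = "classifier_result")
}

#' Estimate food weight from an image
#'
#' Runs the full pipeline: classify (stub or supplied trait), segment the
#' food region, convert the pixel count to physical area via the capture
#' geometry, optionally correct machine area to actual area, and predict
#' the weight from the trait's calibration model.
#'
#' Geometry resolution: explicit `u`/`f35` arguments win over metadata
#' attached to the image.
#'
#' @param image A [food_image()] or a path readable by
#'   [read_food_image()].
#' @param u Object distance, cm.
#' @param f35 35-mm-equivalent focal length, mm.
#' @param box Optional [region_box()] confining the segmentation.
#' @param label Food label for the stub classifier.
#' @param trait Trait override; required when the label is unknown.
#' @param models Per-trait calibration models.
#' @param apply_area_correction If `TRUE`, convert machine area to actual
#'   area with [correct_area()] before the weight model (off by default:
#'   the shipped weight models regress on machine-recognized area).
#' @param image_id Identifier echoed into the report.
#' @return An object of class `estimate_report`. On segmentation failure
#'   the report has `found = FALSE` and no area/weight fields; geometry or
#'   trait resolution failures are errors.
#' @export
estimate_food_weight <- function(image, u = NULL, f35 = NULL, box = NULL,
                                 label = NULL, trait = NULL,
                                 models = default_models(),
                                 apply_area_correction = FALSE,
                                 image_id = NULL) {
  if (is.character(image)) {
    if (is.null(image_id)) image_id <- basename(image)
    image <- read_food_image(image)
  }
  stopifnot(inherits(image, "food_image"))
  if (is.null(u)) u <- image$geom$u
  if (is.null(f35)) f35 <- image$spec$f35
  if (is.null(u) || is.null(f35)) {
    stop("capture geometry unresolved: need object distance (u, cm) and ",
         "equivalent focal length (f35, mm) from arguments or metadata")
  }
  cls <- classify_food(image, label = label)
  if (is.null(trait)) trait <- cls$trait
  if (is.na(trait)) {
    stop("trait unresolved: label ", deparse(cls$label),
         " is not in the registered vocabulary; pass `trait`")
  }
  check_trait(trait)

  region <- segment_food(image, box = box)
  base <- list(image_id = image_id, label = cls$label, trait = trait,
               found = region$found, geometry = list(u_cm = u, f35_mm = f35),
               model_source = models[[trait]]$source,
               area_corrected = apply_area_correction)
  if (!region$found) {
    return(structure(c(base, list(pixel_count = NA_integer_,
                                  area_cm2 = NA_real_,
                                  weight_g = NA_real_)),
                     class = "estimate_report"))
  }
  d <- dim(image$data)
  spec <- image$spec
  if (is.null(spec)) {
    spec <- camera_spec(f35, min(d[1], d[2]), max(d[1], d[2]))
  }
  geom <- capture_geometry(u)
  est <- region_area(region$pixel_count, spec, geom)
  area <- if (apply_area_correction) correct_area(est$area_cm2) else
    est$area_cm2
  w <- predict_weight(area, trait, models)
  structure(c(base, list(pixel_count = region$pixel_count,
                         machine_area_cm2 = est$area_cm2,
                         area_cm2 = area, weight_g = w$weight_g,
                         clipped = w$clipped, region = region)),
            class = "estimate_report")
}

#' @export
print.estimate_report <- function(x, ...) {
  cat("<estimate_report>", if (!is.null(x$image_id)) x$image_id else "", "\n")
  cat(sprintf("  label: %s (trait %s)\n", x$label, x$trait))
  if (!x$found) {
    cat("  segmentation: not found\n")
  } else {
    cat(sprintf("  n = %d px -> area %.2f cm^2 -> weight %.2f g\n",
                as.integer(x$pixel_count), x$area_cm2, x$weight_g))
  }
  invisible(x)
}

#' Serialize an estimate report to JSON
#'
#' @param report An `estimate_report`.
#' @param path Output path (omit to get the JSON string).
#' @export
estimate_to_json <- function(report, path = NULL) {
  x <- unclass(report)
  x$region <- if (!is.null(x$region) && x$region$found) {
    list(pixel_count = x$region$pixel_count,
         polygon = unname(apply(x$region$polygon, 1, as.numeric,
                                simplify = FALSE)))
  } else NULL
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Validate estimated against measured weights
#'
#' Joins two tables on `image_id` and runs the validation battery
#' ([validation_report()]) on estimated minus measured weight.
#'
#' @param estimates Data frame with columns `image_id`, `weight_g`.
#' @param measured Data frame with columns `image_id`, `weight_g`.
#' @return A [validation_report()].
#' @export
validate_estimates <- function(estimates, measured) {
  stopifnot(all(c("image_id", "weight_g") %in% names(estimates)),
            all(c("image_id", "weight_g") %in% names(measured)))
  j <- merge(estimates, measured, by = "image_id",
             suffixes = c("_est", "_meas"))
  if (nrow(j) < 3L) {
    stop("fewer than 3 joined rows; check that image ids overlap")
  }
  validation_report(j$weight_g_est, j$weight_g_meas)
}
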