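# Trait-stratified linear area -> weight calibration.
#
# Foods are grouped into three morphology traits (block/thick bar,
# slice/silk, grain/granule); each trait carries its own linear model
# weight_g = slope * area_cm2 + intercept fitted on machine-recognized
# area. The shipped default coefficients are the published calibration on
# 204 observations per trait.

#' Trait classes
#'
#' The three food-morphology categories, each with its own area-to-weight
#' calibration model.
#' @return Character vector of the three trait codes.
#' @export
trait_classes <- function() c("block_thick_bar", "slice_silk", "grain_granule")

check_trait <- function(trait) {
  if (length(trait) != 1L || !trait %in% trait_classes()) {
    stop("unknown trait ", deparse(trait), "; must be one of ",
         paste(trait_classes(), collapse = ", "))
  }
  trait
}

#' Linear calibration model
#'
#' Container for a simple linear calibration (area to weight, or machine
#' area to actual area): slope, intercept, Pearson r, R-squared and the
#' number of observations behind the fit. For a fitted simple regression
#' R-squared equals r squared; shipped defaults carry the published
#' (rounded) values.
#'
#' @param slope Slope, g per cm^2 (or cm^2 per cm^2 for area correction).
#' @param intercept Intercept, g (or cm^2).
#' @param pearson_r Pearson correlation of the calibration data.
#' @param r_squared Coefficient of determination.
#' @param n_obs Number of observations.
#' @param source `"shipped-default"` or `"fitted"`.
#' @param fit Optional underlying `lm` fit (kept for intervals).
#' @return An object of class `fw_model`.
#' @export
fw_model <- function(slope, intercept, pearson_r = NA_real_,
                     r_squared = NA_real_, n_obs = NA_integer_,
                     source = "fitted", fit = NULL) {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (is.finite(pearson_r)) stopifnot(abs(pearson_r) <= 1)
  if (is.finite(r_squared)) stopifnot(r_squared >= 0, r_squared <= 1)
  structure(list(slope = slope, intercept = intercept,
                 pearson_r = pearson_r, r_squared = r_squared,
                 n_obs = n_obs, source = source, fit = fit),
            class = "fw_model")
}

#' @export
print.fw_model <- function(x, digits = 4, ...) {
  cat(sprintf("<fw_model (%s)> y = %sx %s %s\n", x$source,
              format(x$slope, digits = digits),
              if (x$intercept < 0) "-" else "+",
              format(abs(x$intercept), digits = digits)))
  if (is.finite(x$pearson_r)) {
    cat(sprintf("  r = %.3f, R^2 = %.3f, n = %d\n",
                x$pearson_r, x$r_squared, as.integer(x$n_obs)))
  }
  invisible(x)
}

#' @export
coef.fw_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.fw_model <- function(object, ...) {
  if (!is.null(object$fit)) summary(object$fit) else unclass(object)
}

#' Predict from a calibration model
#'
#' Applies the linear map and clips negative predictions to zero (the
#' negative intercepts make very small areas go negative); the `clipped`
#' attribute flags where clipping happened.
#'
#' @param object An [fw_model()].
#' @param area Input areas, cm^2.
#' @param ... Unused.
#' @return Numeric predictions with a logical `clipped` attribute.
#' @export
predict.fw_model <- function(object, area, ...) {
  stopifnot(is.numeric(area), all(area >= 0))
  raw <- object$slope * area + object$intercept
  out <- pmax(raw, 0)
  attr(out, "clipped") <- raw < 0
  out
}

#' Shipped default area-to-weight models
#'
#' The three trait calibrations shipped with the package (204 observations
#' each): block/thick bar y = 2.5757x - 49.03 (r 0.986, R^2 0.971),
#' slice/silk y = 1.9684x - 46.3 (r 0.937, R^2 0.878), grain/granule
#' y = 2.2069x - 62.13 (r 0.972, R^2 0.944), with y weight in g and x
#' machine-recognized area in cm^2.
#'
#' @return Named list of [fw_model()] objects, one per trait.
#' @export
default_models <- function() {
  list(
    block_thick_bar = fw_model(2.5757, -49.03, 0.986, 0.971, 204L,
                               source = "shipped-default"),
    slice_silk      = fw_model(1.9684, -46.30, 0.937, 0.878, 204L,
                               source = "shipped-default"),
    grain_granule   = fw_model(2.2069, -62.13, 0.972, 0.944, 204L,
                               source = "shipped-default")
  )
}

#' Weight estimate for a measured area
#'
#' @param area Food area in cm^2 (machine-recognized unless corrected).
#' @param trait One of [trait_classes()].
#' @param models Named list of per-trait [fw_model()]s.
#' @return An object of class `weight_estimate`: weight in g, the model
#'   used, the input area and a `clipped` flag.
#' @examples
#' predict_weight(100, "block_thick_bar")  # 208.54 g
#' @export
predict_weight <- function(area, trait, models = default_models()) {
  check_trait(trait)
  stopifnot(is.numeric(area), length(area) == 1L, area >= 0)
  model <- models[[trait]]
  if (is.null(model)) stop("no model for trait ", trait)
  w <- predict(model, area)
  structure(list(weight_g = as.numeric(w), trait = trait, model = model,
                 area_cm2 = area, clipped = attr(w, "clipped")),
            class = "weight_estimate")
}

#' @export
print.weight_estimate <- function(x, ...) {
  cat(sprintf("<weight_estimate> %.2f g (%s, %.2f cm^2)%s\n", x$weight_g,
              x$trait, x$area_cm2, if (x$clipped) " [clipped at 0]" else ""))
  invisible(x)
}

#' Machine-area to actual-area correction
#'
#' The machine-recognized area is systematically smaller than the
#' physically measured area; the shipped correction model
#' `machine = 0.7378 * actual + 12.765` (R^2 0.9591) relates the two, with
#' the machine area as the response. [correct_area()] inverts it:
#' `actual = (machine - 12.765) / 0.7378`, floored at zero. The correction
#' is off by default in the pipeline because the weight calibrations are
#' themselves regressions on raw machine-recognized area.
#'
#' @return An [fw_model()] mapping actual area (x) to machine area (y).
#' @export
area_correction_model <- function() {
  fw_model(0.7378, 12.765, r_squared = 0.9591, pearson_r = 0.979,
           source = "shipped-default")
}

#' @rdname area_correction_model
#' @param machine_area Machine-recognized area, cm^2 (vectorized).
#' @return `correct_area()`: the corrected actual area, cm^2.
#' @export
correct_area <- function(machine_area) {
  stopifnot(all(machine_area >= 0))
  m <- area_correction_model()
  pmax((machine_area - m$intercept) / m$slope, 0)
}

#' Fit an area-to-weight calibration
#'
#' Ordinary least squares of measured weight on machine-recognized area
#' for one trait's calibration records.
#'
#' @param records Data frame of calibration records with columns `trait`,
#'   `machine_area_cm2` and `weight_g` (the schema of
#'   [read_calibration_csv()]).
#' @param trait Trait to fit; `NULL` is allowed when all records share one
#'   trait.
#' @return An [fw_model()] with the underlying `lm` fit attached.
#' @examples
#' rec <- data.frame(trait = "slice_silk",
#'                   machine_area_cm2 = c(10, 20, 30, 40, 50),
#'                   weight_g = 2 * c(10, 20, 30, 40, 50) + 1)
#' coef(fit_area_weight(rec))  # intercept 1, slope 2
#' @export
fit_area_weight <- function(records, trait = NULL) {
  stopifnot(is.data.frame(records),
            all(c("trait", "machine_area_cm2", "weight_g") %in%
                  names(records)))
  if (is.null(trait)) {
    trait <- unique(as.character(records$trait))
    if (length(trait) != 1L) {
      stop("records span several traits; pass `trait` explicitly")
    }
  }
  check_trait(trait)
  d <- records[records$trait == trait, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 records for trait ", trait)
  if (var(d$machine_area_cm2) == 0) stop("zero variance in area")
  fit <- lm(weight_g ~ machine_area_cm2, data = d)
  r <- cor(d$machine_area_cm2, d$weight_g)
  fw_model(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
           pearson_r = r, r_squared = r^2, n_obs = nrow(d),
           source = "fitted", fit = fit)
}

#' Fit all three trait calibrations
#'
#' @inheritParams fit_area_weight
#' @return Named list of [fw_model()]s for the traits present in `records`.
#' @export
fit_all_models <- function(records) {
  traits <- intersect(trait_classes(), unique(as.character(records$trait)))
  setNames(lapply(traits, function(tr) fit_area_weight(records, tr)), traits)
}

#' Calibration CSV schema
#'
#' Calibration tables are plain CSV with columns
#' `food,trait,machine_area_cm2,actual_area_cm2,weight_g`
#' (`actual_area_cm2` may be empty).
#'
#' @param path File path.
#' @return `read_calibration_csv()`: a data frame of records.
#' @export
read_calibration_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("food", "trait", "machine_area_cm2", "weight_g")
  if (!all(need %in% names(d))) {
    stop("calibration CSV must have columns ", paste(need, collapse = ", "))
  }
  bad <- !d$trait %in% trait_classes()
  if (any(bad)) stop("unknown trait(s): ", paste(unique(d$trait[bad]),
                                                 collapse = ", "))
  if (any(d$machine_area_cm2 <= 0) || any(d$weight_g < 0)) {
    stop("areas must be positive and weights non-negative")
  }
  d
}

#' @rdname read_calibration_csv
#' @param records Data frame of calibration records.
#' @export
write_calibration_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Serialize calibration models to JSON
#'
#' @param models Named list of [fw_model()]s.
#' @param path Output path (omit to get the JSON string).
#' @return The JSON string, invisibly when written to file.
#' @export
models_to_json <- function(models, path = NULL) {
  x <- lapply(models, function(m) {
    list(slope = m$slope, intercept = m$intercept, pearson_r = m$pearson_r,
         r_squared = m$r_squared, n_obs = m$n_obs, source = m$source)
  })
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname models_to_json
#' @export
models_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(x, function(m) {
    fw_model(m$slope, m$intercept,
             pearson_r = m$pearson_r %||% NA_real_,
             r_squared = m$r_squared %||% NA_real_,
             n_obs = m$n_obs %||% NA_integer_,
             source = m$source %||% "fitted")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
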