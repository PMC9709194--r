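test_that("shipped default models carry the published coefficients", {
  m <- default_models()
  expect_named(m, trait_classes())
  expect_equal(m$block_thick_bar$slope, 2.5757)
  expect_equal(m$block_thick_bar$intercept, -49.03)
  expect_equal(m$grain_granule$r_squared, 0.944)
  expect_equal(m$slice_silk$pearson_r, 0.937)
  # printed R^2 is consistent with printed r up to rounding
  for (mm in m) expect_lt(abs(mm$r_squared - mm$pearson_r^2), 0.005)
})

test_that("weight prediction is the clipped linear map", {
  w <- predict_weight(100, "block_thick_bar")
  expect_equal(w$weight_g, 2.5757 * 100 - 49.03)
  expect_equal(round(w$weight_g, 2), 208.54)
  expect_false(w$clipped)
  expect_equal(round(predict_weight(100, "grain_granule")$weight_g, 2),
               158.56)
  z <- predict_weight(0, "slice_silk")
  expect_equal(z$weight_g, 0)
  expect_true(z$clipped)
  expect_error(predict_weight(50, "noodle"), "unknown trait")
  # affine-monotone above the clipping point
  areas <- seq(20, 150, by = 5)
  ws <- vapply(areas, function(a)
    predict_weight(a, "slice_silk")$weight_g, numeric(1))
  expect_true(all(diff(ws) > 0))
})

test_that("area correction inverts the machine-area relation", {
  expect_equal(correct_area(12.765), 0)
  expect_equal(correct_area(0.7378 * 100 + 12.765), 100, tolerance = 1e-12)
  expect_equal(round(correct_area(86.545), 4), 100)
  # monotone increasing, floored at zero
  x <- seq(0, 200, by = 10)
  expect_true(all(diff(correct_area(x)) >= 0))
  expect_equal(correct_area(5), 0)
  # round trip: forward map then correction is the identity
  actual <- c(30, 75.5, 120)
  machine <- 0.7378 * actual + 12.765
  expect_equal(correct_area(machine), actual, tolerance = 1e-9)
})

test_that("calibration fitting is ordinary least squares", {
  rec <- data.frame(trait = "slice_silk",
                    machine_area_cm2 = c(10, 20, 30, 40, 50),
                    weight_g = 2 * c(10, 20, 30, 40, 50) + 1)
  m <- fit_area_weight(rec)
  expect_equal(unname(coef(m)), c(1, 2), tolerance = 1e-9)
  expect_equal(m$pearson_r, 1, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)

  # hand-computed OLS on a non-trivial quartet
  rec2 <- data.frame(trait = "grain_granule",
                     machine_area_cm2 = c(0, 1, 2, 3),
                     weight_g = c(0, 1, 0, 1))
  m2 <- fit_area_weight(rec2)
  expect_equal(unname(coef(m2)), c(0.2, 0.2), tolerance = 1e-9)
  expect_equal(unname(coef(m2)),
               unname(oracle_ols(rec2$machine_area_cm2, rec2$weight_g)),
               tolerance = 1e-12)
  expect_equal(m2$r_squared, m2$pearson_r^2, tolerance = 1e-12)

  expect_error(fit_area_weight(rec[1:2, ]), "at least 3")
  expect_error(fit_area_weight(
    data.frame(trait = "slice_silk", machine_area_cm2 = c(5, 5, 5),
               weight_g = c(1, 2, 3))), "variance")
})

test_that("noise-free synthetic calibration recovers coefficients exactly", {
  recs <- generate_calibration_set(n_per_trait = 20, noise_sd_g = 0,
                                   seed = 1)
  expect_equal(nrow(recs), 60)
  fits <- fit_all_models(recs)
  defaults <- default_models()
  for (tr in trait_classes()) {
    expect_equal(fits[[tr]]$slope, defaults[[tr]]$slope, tolerance = 1e-9)
    expect_equal(fits[[tr]]$intercept, defaults[[tr]]$intercept,
                 tolerance = 1e-9)
  }
})

test_that("fitted slope on calibrated noisy data sits in its own 95% CI", {
  recs <- generate_calibration_set(n_per_trait = 204, seed = 7)
  m <- fit_area_weight(recs, "block_thick_bar")
  ci <- stats::confint(m$fit)
  expect_true(ci["machine_area_cm2", 1] <= 2.5757 &&
                2.5757 <= ci["machine_area_cm2", 2])
  expect_equal(m$n_obs, 204L)
})

test_that("calibration records round-trip through CSV and models through JSON", {
  recs <- generate_calibration_set(n_per_trait = 5, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_calibration_csv(recs, path)
  back <- read_calibration_csv(path)
  expect_equal(back$machine_area_cm2, recs$machine_area_cm2)
  expect_equal(back$trait, recs$trait)
  unlink(path)

  jpath <- tempfile(fileext = ".json")
  models_to_json(default_models(), jpath)
  back_m <- models_from_json(jpath)
  expect_equal(back_m$block_thick_bar$slope, 2.5757)
  expect_equal(back_m$slice_silk$source, "shipped-default")
  unlink(jpath)
})

test_that("trait lookup covers the 51-dish vocabulary", {
  tab <- food_traits()
  expect_equal(nrow(tab), 51)
  expect_equal(as.integer(table(tab$trait)[trait_classes()]), rep(17L, 3))
  expect_equal(lookup_trait("French fries"), "block_thick_bar")
  expect_equal(lookup_trait("Pea"), "grain_granule")
  expect_equal(lookup_trait("potato silk"), "slice_silk")
  expect_true(is.na(lookup_trait("Ice cream")))
})
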