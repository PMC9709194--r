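test_that("equivalent focal length follows the sensor conversion table", {
  # full-frame 4:3-equivalent width: f35 equals f when w is 34.6 mm
  expect_equal(equivalent_focal_length(sensor_spec(10, sensor_width_mm = 34.6)),
               10)
  # diagonal form: f = d yields the constant itself
  expect_equal(
    equivalent_focal_length(sensor_spec(8, sensor_diagonal_mm = 8)), 43.3)
  # hand arithmetic: 34.6 * 4.25 / 5.76
  expect_equal(
    equivalent_focal_length(sensor_spec(4.25, sensor_width_mm = 5.76)),
    34.6 * 4.25 / 5.76, tolerance = 1e-12)
  expect_equal(round(
    equivalent_focal_length(sensor_spec(4.25, sensor_width_mm = 5.76)), 2),
    25.53)
  # 3:2 width uses the full-frame width constant
  expect_equal(
    equivalent_focal_length(sensor_spec(9, sensor_width_mm = 36,
                                        aspect = "3:2")), 9)
  # diagonal preferred when both dimensions are given
  s <- sensor_spec(5, sensor_width_mm = 6.4, sensor_diagonal_mm = 8,
                   aspect = "4:3")
  expect_equal(equivalent_focal_length(s), 43.3 * 5 / 8)
  expect_error(sensor_spec(5), "at least one")
})

test_that("width and diagonal conversions agree on a consistent sensor", {
  for (w in c(4.8, 5.76, 6.4, 7.2)) {
    d <- w * sqrt(1 + (3 / 4)^2)  # true 4:3 diagonal
    by_w <- equivalent_focal_length(sensor_spec(5, sensor_width_mm = w))
    by_d <- equivalent_focal_length(sensor_spec(5, sensor_diagonal_mm = d))
    expect_lt(abs(by_w - by_d) / by_d, 0.002)
  }
})

test_that("ground sample length matches the mixed-unit formula", {
  expect_equal(ground_sample_length(0, 3000, u = 50, f35 = 46), 0)
  # bracket equals 1 when u (cm) is numerically 1.1 x f35 (mm)
  expect_equal(ground_sample_length(3000, 3000, u = 50.6, f35 = 46,
                                    axis = "short"), 26)
  # capture-protocol geometry: 34.6 * (40.6/46 - 0.1)
  expect_equal(ground_sample_length(3000, 3000, u = 40.6, f35 = 46,
                                    axis = "long"),
               34.6 * (40.6 / 46 - 0.1), tolerance = 1e-12)
  expect_equal(round(ground_sample_length(3000, 3000, 40.6, 46, "long"), 2),
               27.08)
  expect_error(ground_sample_length(100, 3000, u = 4, f35 = 46),
               "focal plane")
})

test_that("pixel area scale and region area follow the quadratic law", {
  spec <- camera_spec(46, 3000, 4000)
  geom <- capture_geometry(40.6)
  expect_equal(pixel_area_scale(spec, geom),
               ((26 / 3000) * (40.6 / 46 - 0.1))^2, tolerance = 1e-12)
  expect_equal(signif(pixel_area_scale(spec, geom), 4), 4.600e-5)
  expect_equal(region_area(0, spec, geom)$area_cm2, 0)
  expect_equal(region_area(1e6, spec, geom)$area_cm2, 46.00378,
               tolerance = 1e-6)
  expect_error(region_area(-1, spec, geom), "non-negative")

  # additivity in n
  a1 <- region_area(123, spec, geom)$area_cm2
  a2 <- region_area(877, spec, geom)$area_cm2
  expect_equal(a1 + a2, region_area(1000, spec, geom)$area_cm2)

  # doubling the distance bracket quadruples the area
  u1 <- 0.1 * 46 + 10
  u2 <- 0.1 * 46 + 20
  r1 <- region_area(500, spec, capture_geometry(u1))$area_cm2
  r2 <- region_area(500, spec, capture_geometry(u2))$area_cm2
  expect_equal(r2 / r1, 4, tolerance = 1e-9)
})

test_that("short-side and long-side area forms agree on a true 4:3 spec", {
  spec <- camera_spec(46, 3000, 4000)
  u <- 40.6
  short_form <- ((26.0 / spec$width_px) * (u / spec$f35 - 0.1))^2
  long_form <- ((34.6 / spec$height_px) * (u / spec$f35 - 0.1))^2
  expect_lt(abs(short_form - long_form) / long_form, 0.01)
})

test_that("pixel-to-length formula is the thin-lens derivation exactly", {
  # object length from 1/v + 1/u = 1/f with the equivalent frame, vs the
  # package formula, over a grid of distances and focal lengths
  expect_equal(thin_lens_object_length(26, u = 2 * 46, f = 46), 26)
  expect_equal(thin_lens_object_length(26, u = 11 * 46, f = 46), 260)
  expect_error(thin_lens_object_length(26, u = 40, f = 46), "real image")
  for (f35 in c(24, 35, 46, 85)) {
    for (u_cm in seq(0.11 * f35, 100, length.out = 25)) {
      lens_mm <- thin_lens_object_length(26.0, u = 10 * u_cm, f = f35)
      pkg_cm <- ground_sample_length(3000, 3000, u = u_cm, f35 = f35,
                                     axis = "short")
      expect_equal(pkg_cm * 10, lens_mm, tolerance = 1e-9)
    }
  }
})

test_that("unit convention: converting u to mm reproduces the cm result", {
  u_cm <- 40.6; f35 <- 46
  a_cm <- ground_sample_length(1200, 3000, u_cm, f35, axis = "short")
  a_mm_derived <- 26.0 * (1200 / 3000) * (10 * u_cm / f35 - 1)
  expect_equal(a_cm, a_mm_derived / 10, tolerance = 1e-12)
})

test_that("camera and capture specs validate their invariants", {
  expect_error(camera_spec(-1, 3000, 4000))
  expect_error(camera_spec(46, 3000, 4500), "aspect")
  # orientation normalization: landscape input is flipped
  spec <- camera_spec(46, 4000, 3000)
  expect_equal(spec$width_px, 3000L)
  expect_error(capture_geometry(-5))
  expect_error(sensor_spec(5, sensor_width_mm = 6, sensor_diagonal_mm = 6),
               "inconsistent")
})
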