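test_that("linear calibration reproduces an exact line and rejects degeneracy", {
  pts <- calibration_points(c(0, 0.25, 0.5), c(1.0, 2.0, 3.0))
  fit <- fit_linear_calibration(pts)
  expect_equal(fit$slope, 4.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(
    fit_linear_calibration(calibration_points(c(0.2, 0.2, 0.2), c(1, 2, 3))),
    "distinct levels")
  # exact two-point line
  two <- fit_linear_calibration(calibration_points(c(0, 0.5), c(1, 3.85)))
  expect_equal(two$slope, 5.7, tolerance = 1e-12)
})

test_that("calibration fit is scale-equivariant in R1", {
  set.seed(42)
  x <- seq(0, 0.5, length.out = 6)
  y <- 0.6 + 5.7 * x + stats::rnorm(6, sd = 0.02)
  f1 <- fit_linear_calibration(calibration_points(x, y))
  f2 <- fit_linear_calibration(calibration_points(x, 2.7 * y))
  expect_equal(f2$slope, 2.7 * f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, 2.7 * f1$intercept, tolerance = 1e-10)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
})

test_that("slope SE is propagated from ROI errors when available", {
  x <- seq(0, 0.5, length.out = 5)
  pts <- calibration_points(x, 0.65 + 5.7 * x, r1_sd = 0.05, n_voxels = 100)
  fit <- fit_linear_calibration(pts)
  expect_identical(fit$se_method, "propagated")
  se_pt <- 0.05 / sqrt(100)
  sxx <- sum((x - mean(x))^2)
  expect_equal(fit$slope_se, se_pt / sqrt(sxx), tolerance = 1e-12)
  # residual fallback without voxel counts
  fit2 <- fit_linear_calibration(data.frame(level = x, r1_mean = 0.65 + 5.7 * x))
  expect_identical(fit2$se_method, "residual")
  # weighted fit requires usable uncertainties
  expect_error(fit_linear_calibration(data.frame(level = x,
                                                 r1_mean = 1 + x),
                                      weighted = TRUE), "weighted fit")
})

test_that("G-value reproduces the published worked example and its algebra", {
  g <- g_value(1.08, 5.7, 1.007)
  expect_equal(round(g$g_value, 3), 0.188)
  # frozen high-precision division oracle for the unit-density case
  expect_equal(g_value(1.08, 5.7, 1.0)$g_value, 0.189473684210526,
               tolerance = 1e-12)
  expect_equal(g_value(3.3, 3.3, 1.0)$g_value, 1.0, tolerance = 1e-12)
  # homogeneity of degree -1 in the concentration slope and in density
  expect_equal(g_value(1.08, 2 * 5.7, 1.007)$g_value, g$g_value / 2,
               tolerance = 1e-12)
  expect_equal(g_value(1.08, 5.7, 2 * 1.007)$g_value, g$g_value / 2,
               tolerance = 1e-12)
  # quadrature propagation of independent relative errors
  gu <- g_value(1.08, 5.7, 1.007, dose_sensitivity_se = 0.02,
                conc_slope_se = 0.1, density_se = 0.004)
  rel <- sqrt((0.02 / 1.08)^2 + (0.1 / 5.7)^2 + (0.004 / 1.007)^2)
  expect_equal(gu$g_value_se, gu$g_value * rel, tolerance = 1e-12)
  expect_error(g_value(-1, 5.7, 1), "positive")
})

test_that("ROI statistics follow voxel-centre inclusion on a uniform map", {
  r1 <- array(1.3, dim = c(21, 21, 9))
  mask <- array(TRUE, dim = dim(r1))
  map <- r1_volume(r1, valid_mask = mask)
  r <- roi_mean_r1(map, c(10.5, 10.5, 4.5), diameter_mm = 10)
  expect_equal(r$mean, 1.3)
  expect_equal(r$sd, 0)
  # voxel centres within a 5 mm radius of the centre voxel
  xs <- (1:21) - 0.5
  expect_equal(r$n, sum(outer((xs - 10.5)^2, (xs - 10.5)^2, `+`) <= 25))
  r3 <- roi_mean_r1(map, c(10.5, 10.5, 4.5), 10, n_slices = 3)
  expect_equal(r3$n, 3 * r$n)
  # ROI entirely outside the valid region errors with its geometry
  mask[, , ] <- FALSE
  map2 <- r1_volume(r1, valid_mask = mask, positive = FALSE)
  expect_error(roi_mean_r1(map2, c(10.5, 10.5, 4.5), 10), "no valid voxels")
})

test_that("ROI mean on a synthetic vial tracks the ground truth", {
  nl <- small_noiseless()
  spec <- small_spec()
  g <- vfadose:::phantom_geometry(spec)
  sim <- simulate_acquisition(spec, seed = 31, noiseless = nl)
  map <- fit_r1_volume(sim$control, nl$protocol)
  r <- roi_mean_r1(map, c(g$cx, g$cy, (g$z0 + g$z1) / 2), 10, n_slices = 5)
  expect_lt(abs(r$mean - spec$background_r1_per_s) / spec$background_r1_per_s,
            0.01)
})

test_that("calibration CSV round-trips", {
  pts <- calibration_points(c(0, 0.25, 0.5), c(0.65, 2.1, 3.5),
                            r1_sd = c(0.02, 0.03, 0.04), n_voxels = 78)
  path <- tempfile(fileext = ".csv")
  write_calibration_csv(pts, path, unit = "mM")
  back <- read_calibration_csv(path)
  expect_equal(back$level, pts$level)
  expect_equal(back$r1_mean, pts$r1_mean)
  expect_equal(back$r1_sd, pts$r1_sd)
  expect_identical(attr(back, "unit"), "mM")
  expect_error(read_calibration_csv(tempfile()), "not found")
})
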