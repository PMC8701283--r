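test_that("depth-dose curve hits its anchors: entrance, peak, tail", {
  b <- beam_model(entrance_dose_gy = 600)
  expect_identical(depth_dose(0, b), 600)
  z <- seq(0, 78, by = 0.02)
  d <- depth_dose(z, b)
  expect_equal(z[which.max(d)], b$peak_depth_mm, tolerance = 0.021)
  expect_equal(max(d), 600 * b$peak_to_entrance_ratio, tolerance = 1e-6 * 1800)
  # distal fall-off: < 1% of entrance dose ten peak-widths beyond the peak
  expect_lt(depth_dose(b$peak_depth_mm + 10 * b$peak_width_mm, b), 6)
  # continuity: no jumps anywhere on a fine grid
  expect_lt(max(abs(diff(d))), 600 * 0.05)
  expect_equal(depth_dose(15, beam_model(entrance_dose_gy = 0)), 0)
  expect_error(depth_dose(-1, b), "z_mm")
})

test_that("beam model parameters are validated", {
  expect_error(beam_model(peak_to_entrance_ratio = 0.9), "exceed 1")
  expect_error(beam_model(tail_fraction = 1.2), "tail_fraction")
  expect_error(beam_model(peak_width_mm = -1), "positive")
  b <- beam_model()
  z <- seq(0, 78, by = 1)
  expect_true(all(diff(penumbra_sigma_mm(z, b)) >= 0))
})

test_that("lateral blur conserves flux and the sigma->0 limit is the indicator", {
  spec <- small_spec()
  b <- spec$beam
  # analytic blurred edge integrates to the field side at any depth
  u <- seq(-16, 16, by = 0.01)
  for (z in c(5, 20, 24)) {
    s <- penumbra_sigma_mm(z, b)
    l <- vfadose:::lateral_edge_profile(u, b$field_side_mm, s)
    expect_equal(sum(l) * 0.01, b$field_side_mm, tolerance = 0.005 * 8)
  }
  l0 <- vfadose:::lateral_edge_profile(u, 8, 0)
  expect_true(all(l0 %in% c(0, 1)))
  expect_equal(sum(l0) * 0.01, 8, tolerance = 0.02)
})

test_that("dose volume is separable with zeroed, masked exterior", {
  spec <- small_spec()
  dv <- dose_volume(spec)
  g <- vfadose:::phantom_geometry(spec)
  ci <- round(g$cx); cj <- round(g$cy)
  b <- spec$beam
  for (k in c(10, 20, 30)) {
    z <- (k - 0.5) - g$z0
    expected <- depth_dose(z, b) *
      vfadose:::lateral_edge_profile(ci - 0.5 - g$cx, b$field_side_mm,
                                     penumbra_sigma_mm(z, b)) *
      vfadose:::lateral_edge_profile(cj - 0.5 - g$cy, b$field_side_mm,
                                     penumbra_sigma_mm(z, b))
    expect_equal(dv$dose[ci, cj, k], expected, tolerance = 1e-12)
  }
  expect_true(all(dv$dose[!dv$mask] == 0))
  expect_error(phantom_spec(vial_diameter_mm = 8,
                            beam = beam_model(field_side_mm = 10)),
               "larger than the vial")
})

test_that("dose to R1 mapping is linear with depth-dependent sensitivity", {
  spec <- small_spec()
  zero <- dose_to_r1(array(0, dim = spec$grid_dim), spec)
  v <- zero$r1_per_s[zero$valid_mask]
  expect_equal(v, rep(spec$background_r1_per_s, length(v)))
  # direct arithmetic: 600 Gy at an entrance-plateau voxel with s = 1.08
  dose <- array(0, dim = spec$grid_dim)
  dose[8, 16, 7] <- 600   # depth 2.5 mm, on the entrance plateau
  r1 <- dose_to_r1(dose, spec)
  expect_equal(r1$r1_per_s[8, 16, 7] - spec$background_r1_per_s,
               1.08 * 0.6, tolerance = 1e-12)
  r1d <- dose_to_r1(2 * dose, spec)
  expect_equal(r1d$r1_per_s[8, 16, 7] - spec$background_r1_per_s,
               2 * (r1$r1_per_s[8, 16, 7] - spec$background_r1_per_s),
               tolerance = 1e-12)
  # sensitivity interpolates from entrance to peak value
  expect_equal(depth_sensitivity(0, spec), spec$entrance_sensitivity)
  expect_equal(depth_sensitivity(spec$beam$peak_depth_mm, spec),
               spec$peak_sensitivity)
  expect_equal(depth_sensitivity(100, spec), spec$peak_sensitivity)
})

test_that("uniform-gel truncation cancels in the VFA ratio: control map is exact", {
  nl <- small_noiseless()
  map <- fit_r1_volume(nl$control, nl$protocol)
  spec <- small_spec()
  g <- vfadose:::phantom_geometry(spec)
  # interior voxels, 4+ mm away from every gel boundary
  xc <- vfadose:::voxel_centres_mm(spec$grid_dim[1], 1)
  yc <- vfadose:::voxel_centres_mm(spec$grid_dim[2], 1)
  zc <- vfadose:::voxel_centres_mm(spec$grid_dim[3], 1)
  core <- outer((xc - g$cx)^2, (yc - g$cy)^2, `+`) <= (g$r - 4)^2
  core <- outer(core, zc >= g$z0 + 4 & zc <= g$z1 - 4, `&`)
  vals <- map$r1_per_s[core & map$valid_mask]
  expect_gt(length(vals), 100)
  expect_lt(max(abs(vals - spec$background_r1_per_s)), 1e-8)
})

test_that("seeded acquisitions are bit-reproducible", {
  nl <- small_noiseless()
  s1 <- simulate_acquisition(small_spec(), seed = 99, noiseless = nl)
  s2 <- simulate_acquisition(small_spec(), seed = 99, noiseless = nl)
  expect_identical(s1$irradiated$volumes, s2$irradiated$volumes)
  expect_identical(s1$control$volumes, s2$control$volumes)
  s3 <- simulate_acquisition(small_spec(), seed = 100, noiseless = nl)
  expect_false(identical(s1$irradiated$volumes, s3$irradiated$volumes))
})

test_that("measured plateau-ROI CV matches the calibrated target over seeds", {
  nl <- small_noiseless()
  spec <- small_spec()
  g <- vfadose:::phantom_geometry(spec)
  centre <- c(g$cx, g$cy, (g$z0 + g$z1) / 2)
  cvs <- vapply(1:20, function(s) {
    sim <- simulate_acquisition(spec, seed = 4000 + s, noiseless = nl)
    m <- fit_r1_volume(sim$control, nl$protocol)
    image_quality(m, centre, 10, "xy", n_slices = 7)$cv_percent
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 3.7) / 3.7, 0.10)
})

test_that("calibration vials: zero vial at background, noiseless slope exact", {
  vials <- default_calibration_vials()
  expect_equal(vials$truth$r1_true[1], vials$background_r1)
  f0 <- fit_calibration_series(vials, noise = FALSE)
  expect_equal(f0$slope, vials$relaxivity, tolerance = 1e-9)
  expect_equal(f0$intercept, vials$background_r1, tolerance = 1e-9)
  expect_equal(f0$r_squared, 1, tolerance = 1e-12)
  # one noisy realization: slope within 3 SE of truth, high linearity
  f1 <- fit_calibration_series(vials, seed = 21)
  expect_lt(abs(f1$slope - vials$relaxivity), 3 * f1$slope_se)
  expect_gt(f1$r_squared, 0.999)
  # the fast ROI-restricted path is statistically equivalent
  f_roi <- fit_calibration_series(vials, seed = 5, roi_only = TRUE)
  expect_lt(abs(f_roi$slope - vials$relaxivity), 4 * f_roi$slope_se)
})
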