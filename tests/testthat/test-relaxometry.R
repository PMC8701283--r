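test_that("SPGR signal matches the closed form, its limits and bounds", {
  p <- test_protocol()
  expect_equal(spgr_signal(1000, 1500, p, 0), 0)
  # saturation-free limit: TR >> T1 so E1 -> 0 and S -> m0 sin(a)
  expect_equal(spgr_signal(1000, 1e-3, p, 30), 1000 * sin(pi / 6),
               tolerance = 1e-12)
  # frozen high-precision evaluations of the closed form
  expect_equal(spgr_signal(1000, 1500, p, 7), 69.9729309345514,
               tolerance = 1e-12)
  expect_equal(spgr_signal(1000, 1500, p, 36), 29.3849015838483,
               tolerance = 1e-12)
  for (a in c(5, 20, 45, 80))
    expect_true(spgr_signal(1000, 800, p, a) > 0 &&
                  spgr_signal(1000, 800, p, a) < 1000)
  expect_error(spgr_signal(1000, -5, p, 7), "t1_ms")
  expect_error(spgr_signal(1000, 1500, p, 95), "angle")
})

test_that("E1 and T1 transforms are exact inverses with guarded domains", {
  expect_equal(e1_from_t1(15, 15), exp(-1), tolerance = 1e-15)
  expect_equal(t1_from_e1(exp(-1), 15), 15, tolerance = 1e-12)
  expect_equal(t1_from_e1(exp(-0.01), 15), 1500, tolerance = 1e-9)
  # frozen closed-form oracle: -15 / ln(0.99)
  expect_equal(t1_from_e1(0.99, 15), 1492.4874371013326, tolerance = 1e-12)
  # e1 -> 1 as t1 -> Inf
  expect_equal(e1_from_t1(1e12, 15), 1, tolerance = 1e-9)
  t1 <- c(200, 750, 1500, 4000)
  expect_equal(t1_from_e1(e1_from_t1(t1, 15), 15), t1, tolerance = 1e-12)
  expect_true(all(is.na(t1_from_e1(c(-0.5, 0, 1, 1.2), 15))))
  expect_error(e1_from_t1(-1, 15), "positive")
  expect_error(e1_from_t1(1000, 0), "positive")
})

test_that("noiseless two-point VFA fits recover T1 and M0 exactly", {
  p <- test_protocol()
  for (m0 in c(100, 1000, 5000)) {
    for (t1 in seq(200, 4000, length.out = 20)) {
      s <- vapply(p$flip_angles_deg, function(a) spgr_signal(m0, t1, p, a),
                  numeric(1))
      f <- vfa_fit_voxel(s, p)
      expect_true(f$valid)
      expect_lt(abs(f$t1_ms - t1) / t1, 1e-10)
      expect_lt(abs(f$m0 - m0) / m0, 1e-10)
    }
  }
})

test_that("degenerate voxels are flagged invalid, never raised", {
  p <- test_protocol()
  expect_false(vfa_fit_voxel(c(0, 0), p)$valid)
  # transformed slope >= 1 (unphysical E1): large high-angle signal
  f <- vfa_fit_voxel(c(10, 200), p)
  expect_false(f$valid)
  expect_true(is.na(f$t1_ms))
  expect_false(vfa_fit_voxel(c(NA, 50), p)$valid)
  expect_error(vfa_fit_voxel(c(1, 2, 3), p), "flip angles")
})

test_that("volume fitting recovers a uniform phantom and masks background", {
  p <- test_protocol()
  favs <- uniform_signal_set(1000, 1200, p, dim = c(5, 5, 6))
  map <- fit_r1_volume(favs, p)
  expect_true(all(map$valid_mask))
  expect_equal(unname(map$r1_per_s[1, 1, 1]), 1000 / 1200, tolerance = 1e-10)
  expect_equal(stats::sd(map$r1_per_s), 0, tolerance = 1e-12)
  # unit consistency: r1 [1/s] * t1 [ms] = 1000 wherever valid
  expect_equal(map$r1_per_s * 1200, array(1000, dim = c(5, 5, 6)),
               tolerance = 1e-10)

  zero <- flip_angle_volume_set(list(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))),
                                p$flip_angles_deg)
  map0 <- fit_r1_volume(zero, p)
  expect_false(any(map0$valid_mask))

  bad <- flip_angle_volume_set(favs$volumes, c(5, 30))
  expect_error(fit_r1_volume(bad, p), "do not match")
})

test_that("SPGR monotonicity: increasing in M0, decreasing in T1 below Ernst", {
  p <- test_protocol()
  t1 <- 1000
  ernst <- acos(exp(-p$tr_ms / t1)) * 180 / pi  # ~9.9 deg
  a <- 7
  expect_lt(a, ernst)
  s_m0 <- vapply(c(500, 1000, 2000), function(m) spgr_signal(m, t1, p, a),
                 numeric(1))
  expect_true(all(diff(s_m0) > 0))
  s_t1 <- vapply(c(600, 1000, 1800, 3000), function(t)
    spgr_signal(1000, t, p, a), numeric(1))
  expect_true(all(diff(s_t1) < 0))
})

test_that("median fitted R1 under calibrated noise is within 2% of truth", {
  p <- test_protocol()
  spec <- phantom_spec()  # background R1 0.65 1/s, CV target 3.7%
  bg <- spec$background_r1_per_s
  sigma <- noise_sigma_for_cv(spec, p)
  s0 <- vapply(p$flip_angles_deg, function(a)
    spgr_signal(spec$m0, 1000 / bg, p, a), numeric(1))
  n <- 1e4
  set.seed(101)
  sig <- lapply(s0, function(s) s + stats::rnorm(n, sd = sigma))
  f <- vfadose:::vfa_fit_arrays(sig, p$flip_angles_deg, p$tr_ms)
  r1 <- (1000 / f$t1_ms)[f$valid]
  expect_gt(length(r1), 0.99 * n)
  expect_lt(abs(stats::median(r1) - bg) / bg, 0.02)
  # and the injected noise level produces roughly the targeted CV
  expect_lt(abs(stats::sd(r1) / mean(r1) - spec$noise_cv) / spec$noise_cv, 0.1)
})
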