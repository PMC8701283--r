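make_map <- function(values, spacing = c(1, 1, 1), positive = FALSE) {
  r1_volume(values, valid_mask = array(TRUE, dim = dim(values)),
            voxel_spacing_mm = spacing, positive = positive)
}

test_that("delta-R1 is an antisymmetric voxel-wise difference", {
  a <- make_map(array(1.5, c(4, 4, 6)))
  b <- make_map(array(1.0, c(4, 4, 6)))
  d <- delta_r1(a, b)
  expect_equal(unique(as.vector(d$r1_per_s)), 0.5)
  expect_equal(as.vector(delta_r1(a, a)$r1_per_s), rep(0, 96))
  swap <- delta_r1(b, a)
  expect_equal(swap$r1_per_s, -d$r1_per_s)
  expect_error(delta_r1(a, make_map(array(1, c(4, 4, 5)))), "shapes")
  # validity is the intersection of the two masks
  m <- array(TRUE, c(4, 4, 6)); m[1, 1, 1] <- FALSE
  b2 <- r1_volume(array(1, c(4, 4, 6)), valid_mask = m)
  d2 <- delta_r1(a, b2)
  expect_false(d2$valid_mask[1, 1, 1])
  expect_true(is.na(d2$r1_per_s[1, 1, 1]))
})

test_that("depth profiles: flat input, parity guard, averaging modes", {
  u <- make_map(array(2.0, c(9, 9, 30)))
  for (n in c(1, 3, 7)) {
    p <- extract_depth_profile(u, "z", n_slices_avg = n)
    expect_equal(unique(p$value), 2.0)
    expect_equal(unique(p$value_sd), 0)
    expect_equal(p$depth_mm, 0:29)
  }
  expect_error(extract_depth_profile(u, "z", n_slices_avg = 2), "odd")
  expect_error(extract_depth_profile(u, "w"), "beam_axis")
  # slices mode averages along the first in-plane axis only
  arr <- array(rep(1:9, times = 9 * 30), c(9, 9, 30))  # varies along x only
  vx <- make_map(arr)
  ps <- extract_depth_profile(vx, "z", n_slices_avg = 3, mode = "slices")
  expect_equal(unique(ps$value), 5)  # mean of x = 4,5,6
  # line outside the valid region errors
  masked <- r1_volume(array(1, c(9, 9, 30)),
                      valid_mask = array(FALSE, c(9, 9, 30)),
                      positive = FALSE)
  expect_error(extract_depth_profile(masked, "z"), "no valid gel")
})

test_that("neighbourhood averaging shrinks profile noise as 1/n", {
  set.seed(77)
  arr <- array(5 + stats::rnorm(15 * 15 * 200, sd = 0.5), c(15, 15, 200))
  m <- make_map(arr)
  p1 <- extract_depth_profile(m, "z", n_slices_avg = 1)
  p7 <- extract_depth_profile(m, "z", n_slices_avg = 7)
  ratio <- stats::sd(p1$value) / stats::sd(p7$value)
  expect_gt(ratio, 7 * 0.75)
  expect_lt(ratio, 7 * 1.25)
  # the reported per-depth SD estimates the voxel noise, not the SE
  expect_equal(mean(p7$value_sd), 0.5, tolerance = 0.05)
})

test_that("Bragg-peak localization: maxima, tie rule, refinement", {
  d <- 0:20
  v <- exp(-0.5 * ((d - 13) / 2)^2)
  expect_equal(find_bragg_peak(depth_profile(d, v))$peak_depth_mm, 13)
  plateau <- c(1, 2, 5, 5, 5, 2, 1)
  expect_equal(find_bragg_peak(depth_profile(0:6, plateau))$peak_depth_mm, 2)
  expect_error(find_bragg_peak(depth_profile(0:5, rep(1, 6))), "flat")
  expect_error(find_bragg_peak(depth_profile(0:1, c(1, 2))), "three")
  # parabolic refinement recovers an off-grid vertex exactly
  vv <- -(d - 7.3)^2
  pk <- find_bragg_peak(depth_profile(d, vv), refine = TRUE)
  expect_equal(pk$peak_depth_mm, 7.3, tolerance = 1e-9)
})

test_that("PDD normalization anchors the entrance window at 100%", {
  d <- 0:60
  v <- 2.5 * exp(-((d - 48) / 3)^2) + 1 - 0.003 * d
  p <- depth_profile(d, v)
  pdd <- pdd_normalize(p)
  sel <- d >= 10 & d <= 20
  expect_equal(mean(pdd$value[sel]), 100, tolerance = 1e-10)
  # invariant under positive rescaling of the input
  pdd2 <- pdd_normalize(depth_profile(d, 37 * v))
  expect_equal(pdd2$value, pdd$value, tolerance = 1e-10)
  expect_error(pdd_normalize(p, entrance_depth_mm = 100), "no profile samples")
  expect_error(pdd_normalize(depth_profile(d, v - 10)), "not positive")
})

test_that("profile comparison: identity, translation, disjoint ranges", {
  d <- seq(0, 60, by = 1)
  v <- 100 * exp(-0.5 * ((d - 48) / 3)^2) + 20
  gel <- depth_profile(d, v)
  cmp <- compare_profiles(gel, gel)
  expect_equal(cmp$pointwise_diff, rep(0, length(cmp$common_depth_mm)))
  expect_equal(cmp$peak_depth_diff_mm, 0)
  ref <- depth_profile(d + 2, v)   # same curve shifted 2 mm deeper
  cmp2 <- compare_profiles(gel, ref)
  expect_equal(cmp2$peak_depth_diff_mm, -2)
  expect_error(compare_profiles(gel, depth_profile(d + 100, v)), "disjoint")
})

test_that("image quality reports CV% and SNR from the same ROI", {
  arr <- array(1.0, c(11, 11, 5))
  set.seed(5)
  noise <- array(stats::rnorm(length(arr), sd = 0.037), dim(arr))
  iq <- image_quality(make_map(arr + noise), c(5.5, 5.5, 2.5), 10,
                      n_slices = 5)
  expect_equal(iq$cv_percent, 3.7, tolerance = 0.6)
  expect_equal(iq$snr, iq$mean / iq$sd, tolerance = 1e-12)
  iq0 <- image_quality(make_map(arr), c(5.5, 5.5, 2.5), 10)
  expect_identical(iq0$snr, Inf)
  expect_identical(iq0$cv_percent, 0)
})

test_that("dose conversion inverts the generator's sensitivity model", {
  nl <- small_noiseless()
  spec <- small_spec()
  tr <- nl$truth
  p <- extract_depth_profile(delta_r1(tr$r1, tr$r1_control), "z",
                             n_slices_avg = 1)
  # central-axis ground-truth dose and per-voxel sensitivity at the same
  # absolute positions (profile depth 0 = first gel voxel centre)
  g <- vfadose:::phantom_geometry(spec)
  ci <- round(g$cx); cj <- round(g$cy)
  k0 <- which(tr$mask[ci, cj, ])[1]
  idx <- k0 + seq_along(p$depth_mm) - 1
  dose <- dose_from_delta_r1(p, depth_sensitivity(tr$depth_mm[idx], spec))
  truth <- tr$dose[ci, cj, idx]
  expect_equal(dose$value, truth, tolerance = 1e-9)
  expect_error(dose_from_delta_r1(p, -1), "positive")
})

test_that("truncation over/undershoot brackets the reconstructed Bragg peak", {
  nl <- small_noiseless()
  spec <- small_spec()
  pro <- nl$protocol
  m <- fit_r1_volume(nl$irradiated, pro)
  mc <- fit_r1_volume(nl$control, pro)
  rec <- delta_r1(m, mc)
  ideal <- delta_r1(nl$truth$r1, nl$truth$r1_control)
  ci <- spec$grid_dim[1] / 2; cj <- spec$grid_dim[2] / 2
  dev <- rec$r1_per_s[ci, cj, ] - ideal$r1_per_s[ci, cj, ]
  z <- (seq_len(spec$grid_dim[3]) - 0.5) * spec$voxel_mm
  zp_abs <- spec$gel_offset_mm + spec$beam$peak_depth_mm
  pre <- dev[z >= zp_abs - 5 & z <= zp_abs]
  post <- dev[z > zp_abs & z <= zp_abs + 5]
  expect_gt(max(pre, na.rm = TRUE), 0)
  expect_lt(min(post, na.rm = TRUE), 0)
})
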