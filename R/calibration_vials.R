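# Synthetic Fe3+ reference-gel series: one uniform cylindrical vial per
# concentration, acquired through the same truncation + Rician noise
# chain as the beam phantom, with the ground-truth relaxivity emitted
# alongside.

#' Generate a synthetic Fe3+ calibration-vial series
#'
#' Each concentration `c` yields a uniform gel column with
#' `R1 = background_r1 + relaxivity * c`, imaged with the simulated SPGR
#' acquisition (k-space truncation of the oversampled ideal image plus
#' calibrated Rician noise level). The noise sigma is calibrated once on
#' the lowest-concentration vial and shared by the whole series, as a
#' single scanner setting would be.
#'
#' @param fe_concentrations_mM Fe3+ concentrations in mM (>= 0); defaults
#'   to five levels spanning 0-0.5 mM.
#' @param relaxivity ground-truth relaxivity in 1/s per mM (default 5.7).
#' @param background_r1 unirradiated gel R1 in 1/s.
#' @param noise_cv target R1-map CV (fraction).
#' @param grid_dim simulation grid; the default is a slab through the
#'   vial core (x is the untruncated slice direction).
#' @param vial_diameter_mm,vial_length_mm,gel_offset_mm vial geometry.
#' @param voxel_mm voxel size.
#' @param oversample_factor in-plane oversampling before truncation.
#' @param m0 equilibrium magnetization of gel voxels.
#' @param roi_diameter_mm,roi_n_slices ROI used for the per-vial
#'   statistics (10 mm circle by default).
#' @return An object of class `calibration_vial_set`: per-level noiseless
#'   volume sets, the shared `sigma`, `protocol`, ROI definition and the
#'   ground-truth table.
#' @export
generate_calibration_vials <- function(fe_concentrations_mM = seq(0, 0.5, length.out = 5),
                                       relaxivity = 5.7, background_r1 = 0.65,
                                       noise_cv = 0.037,
                                       grid_dim = c(16, 48, 48),
                                       vial_diameter_mm = 35,
                                       vial_length_mm = 36, gel_offset_mm = 4,
                                       voxel_mm = 1, oversample_factor = 8,
                                       m0 = 1000, roi_diameter_mm = 10,
                                       roi_n_slices = 5L) {
  if (any(fe_concentrations_mM < 0)) stop("concentrations must be >= 0")
  if (relaxivity <= 0) stop("relaxivity must be positive")
  lv <- sort(fe_concentrations_mM)
  specs <- lapply(lv, function(cc)
    phantom_spec(vial_diameter_mm = vial_diameter_mm,
                 vial_length_mm = vial_length_mm, voxel_mm = voxel_mm,
                 grid_dim = grid_dim, gel_offset_mm = gel_offset_mm,
                 background_r1_per_s = background_r1 + relaxivity * cc,
                 beam = beam_model(entrance_dose_gy = 0,
                                   field_side_mm = min(10, vial_diameter_mm)),
                 noise_cv = noise_cv, oversample_factor = oversample_factor,
                 m0 = m0))
  protocol <- phantom_protocol(specs[[1L]])
  # uniform vial: the control branch of the simulator is the acquisition
  vols <- lapply(specs, function(sp)
    simulate_uniform_vial(sp, protocol))
  sigma <- noise_sigma_for_cv(specs[[1L]], protocol, control = vols[[1L]])
  g <- phantom_geometry(specs[[1L]])
  roi <- list(center_mm = c(g$cx, g$cy, (g$z0 + g$z1) / 2),
              diameter_mm = roi_diameter_mm, plane = "xy",
              n_slices = roi_n_slices)
  truth <- data.frame(level = lv,
                      r1_true = background_r1 + relaxivity * lv)
  structure(list(levels = lv, volumes = vols, sigma = sigma,
                 protocol = protocol, roi = roi, truth = truth,
                 relaxivity = relaxivity, background_r1 = background_r1,
                 spec = specs[[1L]]),
            class = "calibration_vial_set")
}

# noiseless truncated acquisition of a uniform (zero-dose) vial; the SPGR
# signal of uniform gel is a scalar per angle, so one truncation of the
# gel indicator per slice serves every angle
simulate_uniform_vial <- function(spec, protocol) {
  g <- phantom_geometry(spec)
  d <- spec$grid_dim
  os <- spec$oversample_factor
  fine <- spec$voxel_mm / os
  xc <- voxel_centres_mm(d[1L], spec$voxel_mm)
  yf <- voxel_centres_mm(d[2L] * os, fine)
  zf <- voxel_centres_mm(d[3L] * os, fine)
  gelz <- zf >= g$z0 & zf <= g$z1
  e1 <- exp(-protocol$tr_ms * spec$background_r1_per_s / 1000)
  a_rad <- protocol$flip_angles_deg * pi / 180
  s0 <- spec$m0 * (1 - e1) * sin(a_rad) / (1 - e1 * cos(a_rad))
  km <- spec$kspace_matrix
  rec <- array(0, dim = c(d[1L], km))
  for (i in seq_len(d[1L])) {
    inrow <- (xc[i] - g$cx)^2 + (yf - g$cy)^2 <= g$r^2
    rec[i, , ] <- ktrunc_core(outer(inrow, gelz) * 1, km, "target")
  }
  spacing <- c(spec$voxel_mm, d[2:3] * spec$voxel_mm / km)
  flip_angle_volume_set(lapply(s0, function(s) s * rec),
                        protocol$flip_angles_deg, spacing)
}

#' Fit one noisy realization of a calibration-vial series
#'
#' Adds the calibrated Rician noise to every vial, fits the R1 maps,
#' extracts the ROI statistics and fits the linear calibration curve.
#' With `roi_only = TRUE` (the default) noise is generated and the
#' voxel-wise fit evaluated only over the ROI voxels, which is exact --
#' the VFA fit is independent per voxel and the noise is i.i.d. -- and
#' orders of magnitude faster for replicate studies.
#'
#' @param vials a [generate_calibration_vials()] result.
#' @param seed integer seed (`NULL` continues the current RNG stream).
#' @param noise logical; `FALSE` runs the noiseless chain.
#' @param roi_only restrict noise + fit to ROI voxels (statistically
#'   identical to the full-volume path for the returned curve).
#' @return A `calibration_curve` (see [fit_linear_calibration()]).
#' @export
fit_calibration_series <- function(vials, seed = NULL, noise = TRUE,
                                   roi_only = TRUE) {
  stopifnot(inherits(vials, "calibration_vial_set"))
  if (!is.null(seed)) set.seed(seed)
  roi <- vials$roi
  pro <- vials$protocol
  if (roi_only) {
    dims <- dim(vials$volumes[[1L]]$volumes[[1L]])
    sp <- vials$volumes[[1L]]$voxel_spacing_mm
    rm <- roi_mask(dims, sp, roi$center_mm, roi$diameter_mm, roi$plane,
                   roi$n_slices)
    sel <- which(rm)
    pts <- lapply(seq_along(vials$levels), function(i) {
      sig <- lapply(vials$volumes[[i]]$volumes, function(v) {
        s <- v[sel]
        if (noise && vials$sigma > 0)
          s <- sqrt((s + stats::rnorm(length(s), sd = vials$sigma))^2 +
                      stats::rnorm(length(s), sd = vials$sigma)^2)
        s
      })
      f <- vfa_fit_arrays(sig, pro$flip_angles_deg, pro$tr_ms)
      r1 <- (1000 / f$t1_ms)[f$valid]
      if (!length(r1)) stop("ROI of vial ", i, " has no valid voxels")
      c(mean(r1), stats::sd(r1), length(r1))
    })
    pts <- do.call(rbind, pts)
    points <- calibration_points(vials$levels, pts[, 1L], pts[, 2L], pts[, 3L])
    return(fit_linear_calibration(points))
  }
  pts <- lapply(seq_along(vials$levels), function(i) {
    favs <- vials$volumes[[i]]
    if (noise) favs <- add_rician_noise(favs, vials$sigma)
    map <- fit_r1_volume(favs, pro)
    r <- roi_mean_r1(map, roi$center_mm, roi$diameter_mm, roi$plane,
                     roi$n_slices)
    c(r$mean, r$sd, r$n)
  })
  pts <- do.call(rbind, pts)
  points <- calibration_points(vials$levels, pts[, 1L], pts[, 2L], pts[, 3L])
  fit_linear_calibration(points)
}

#' Replicate calibration-slope study
#'
#' Repeats [fit_calibration_series()] over independently seeded noise
#' realizations and tabulates the fitted slope, its standard error and
#' R-squared per replicate.
#'
#' @param vials a [generate_calibration_vials()] result.
#' @param n_replicates number of replicates.
#' @param seed base seed; replicate `i` is drawn from one sequential RNG
#'   stream started here.
#' @return data.frame with columns `slope`, `slope_se`, `r_squared`.
#' @export
calibration_slope_replicates <- function(vials, n_replicates = 1000,
                                         seed = 1) {
  set.seed(seed)
  out <- vapply(seq_len(n_replicates), function(i) {
    fit <- fit_calibration_series(vials, seed = NULL)
    c(fit$slope, fit$slope_se, fit$r_squared)
  }, numeric(3L))
  data.frame(slope = out[1L, ], slope_se = out[2L, ], r_squared = out[3L, ])
}
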