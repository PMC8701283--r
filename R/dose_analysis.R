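# Depth-dose stage: delta-R1 maps, beam-axis profiles with neighbourhood
# averaging, Bragg-peak localization, PDD normalization and comparison
# against an ionization-chamber reference curve, plus image-quality
# metrics.

#' Dose-difference map delta-R1 = irradiated - control
#'
#' Voxel-wise difference of two co-registered R1 maps, valid only where
#' both inputs are valid. Negative values (noise) are preserved, not
#' clipped, so downstream noise statistics stay unbiased.
#'
#' @param irradiated,control [r1_volume()]s with identical shape and
#'   spacing.
#' @return An [r1_volume()] (with `positive = FALSE`).
#' @export
delta_r1 <- function(irradiated, control) {
  stopifnot(inherits(irradiated, "r1_volume"), inherits(control, "r1_volume"))
  if (!identical(dim(irradiated$r1_per_s), dim(control$r1_per_s)))
    stop("irradiated and control maps have different shapes")
  if (!isTRUE(all.equal(irradiated$voxel_spacing_mm,
                        control$voxel_spacing_mm)))
    stop("irradiated and control maps have different voxel spacing")
  valid <- irradiated$valid_mask & control$valid_mask
  if (!any(valid)) stop("the valid masks of the two maps do not overlap")
  d <- irradiated$r1_per_s - control$r1_per_s
  d[!valid] <- NA_real_
  r1_volume(d, valid_mask = valid,
            voxel_spacing_mm = irradiated$voxel_spacing_mm, positive = FALSE)
}

#' Depth profile container
#'
#' @param depth_mm strictly increasing depth samples (mm), measured from
#'   the gel entrance surface.
#' @param value profile values (R1, delta-R1, dose or percent).
#' @param value_sd per-depth SD over the averaged neighbourhood (optional).
#' @param n_averaged number of lines/voxels averaged per depth sample.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(depth_mm, value, value_sd = NULL, n_averaged = 1L) {
  if (length(depth_mm) != length(value))
    stop("depth_mm and value must have equal length")
  if (is.unsorted(depth_mm, strictly = TRUE))
    stop("depth_mm must be strictly increasing")
  if (!is.null(value_sd) && length(value_sd) != length(value))
    stop("value_sd length mismatch")
  structure(list(depth_mm = as.numeric(depth_mm), value = as.numeric(value),
                 value_sd = if (is.null(value_sd)) rep(NA_real_, length(value))
                            else as.numeric(value_sd),
                 n_averaged = as.integer(n_averaged)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth profile: %d samples, depth %.4g..%.4g mm, n_avg %d\n",
              length(x$depth_mm), min(x$depth_mm), max(x$depth_mm),
              x$n_averaged))
  invisible(x)
}

#' @export
as.data.frame.depth_profile <- function(x, ...) {
  data.frame(depth_mm = x$depth_mm, value = x$value, value_sd = x$value_sd)
}

#' Beam-axis depth profile with neighbourhood averaging
#'
#' Extracts the profile along the beam axis at an in-plane position. For
#' `n_slices_avg = 1` it is the single-voxel line; for odd `n > 1` each
#' depth sample is the mean over the in-plane `n x n` neighbourhood
#' (mode `"boxcar"`, the default) or over `n` voxels along the slice
#' direction only (mode `"slices"`), with the neighbourhood SD reported
#' per depth. Depth 0 is the first valid gel voxel along the axis at the
#' line centre.
#'
#' @param map an [r1_volume()].
#' @param beam_axis `"x"`, `"y"` or `"z"` (default `"z"`, the slowest
#'   array axis).
#' @param line_center_mm in-plane position of the line, two coordinates in
#'   mm in the order of the remaining axes; defaults to the volume centre.
#' @param n_slices_avg odd averaging width (1, 3, 5, 7, ...).
#' @param mode `"boxcar"` (in-plane `n x n`) or `"slices"` (`n` along the
#'   first in-plane axis only).
#' @return A [depth_profile()].
#' @export
extract_depth_profile <- function(map, beam_axis = "z", line_center_mm = NULL,
                                  n_slices_avg = 1L,
                                  mode = c("boxcar", "slices")) {
  stopifnot(inherits(map, "r1_volume"))
  mode <- match.arg(mode)
  n <- as.integer(n_slices_avg)
  if (n < 1L || n %% 2L == 0L)
    stop("n_slices_avg must be an odd integer >= 1 (got ", n_slices_avg, ")")
  ax <- match(beam_axis, c("x", "y", "z"))
  if (is.na(ax)) stop("beam_axis must be 'x', 'y' or 'z'")
  inplane <- setdiff(1:3, ax)
  d <- dim(map$r1_per_s)
  sp <- map$voxel_spacing_mm
  if (is.null(line_center_mm))
    line_center_mm <- d[inplane] * sp[inplane] / 2
  if (length(line_center_mm) != 2L)
    stop("line_center_mm must give two in-plane coordinates")
  ci <- pmin(pmax(round(line_center_mm / sp[inplane] + 0.5), 1L), d[inplane])
  half <- (n - 1L) %/% 2L
  i1 <- (ci[1L] - half):(ci[1L] + half)
  i2 <- if (mode == "boxcar") (ci[2L] - half):(ci[2L] + half) else ci[2L]
  if (any(i1 < 1L) || any(i1 > d[inplane[1L]]) ||
      any(i2 < 1L) || any(i2 > d[inplane[2L]]))
    stop("averaging neighbourhood falls outside the volume")
  # permute to (inplane1, inplane2, depth)
  arr <- aperm(map$r1_per_s, c(inplane, ax))
  msk <- aperm(map$valid_mask, c(inplane, ax))
  centre_valid <- msk[ci[1L], ci[2L], ]
  # depth origin: first valid voxel on the centre line followed by two
  # more valid voxels (guards against isolated noise voxels)
  run <- centre_valid & c(centre_valid[-1L], FALSE) &
    c(centre_valid[-(1:2)], FALSE, FALSE)
  k0 <- which(run)[1L]
  if (is.na(k0)) stop("line centre crosses no valid gel voxels")
  ks <- k0:max(which(centre_valid))
  ks <- ks[centre_valid[ks]]
  vals <- numeric(length(ks)); sds <- numeric(length(ks))
  for (t in seq_along(ks)) {
    v <- arr[i1, i2, ks[t]]
    v <- v[is.finite(v)]
    vals[t] <- mean(v)
    sds[t] <- if (length(v) > 1L) stats::sd(v) else 0
  }
  depth_profile((ks - k0) * sp[ax], vals, sds, n_averaged = n)
}

#' Locate the Bragg peak of a depth profile
#'
#' Depth of the global maximum; exact ties are broken toward the shallower
#' depth. With `refine = TRUE` a three-point parabolic interpolation
#' around the maximum refines the depth (off by default).
#'
#' @param profile a [depth_profile()] with at least three samples.
#' @param refine logical; parabolic sub-voxel refinement.
#' @return list with `peak_depth_mm` and `peak_value`.
#' @export
find_bragg_peak <- function(profile, refine = FALSE) {
  stopifnot(inherits(profile, "depth_profile"))
  v <- profile$value
  if (length(v) < 3L) stop("at least three profile samples are required")
  if (diff(range(v)) == 0)
    stop("profile is flat: no unique peak")
  k <- which(v == max(v))[1L]  # shallowest of any exact ties
  depth <- profile$depth_mm[k]
  if (refine && k > 1L && k < length(v)) {
    y0 <- v[k - 1L]; y1 <- v[k]; y2 <- v[k + 1L]
    den <- y0 - 2 * y1 + y2
    if (den < 0) {
      delta <- 0.5 * (y0 - y2) / den
      h <- (profile$depth_mm[k + 1L] - profile$depth_mm[k - 1L]) / 2
      depth <- depth + delta * h
    }
  }
  list(peak_depth_mm = depth, peak_value = v[k])
}

#' Percentage-depth-dose normalization
#'
#' Scales the profile so that its mean over the entrance window
#' `[entrance_depth_mm, entrance_depth_mm + entrance_window_mm]` equals
#' 100%. The window defaults to 10-20 mm: deep enough to avoid
#' entrance-edge ringing and meniscus effects, shallow enough to sit on
#' the plateau.
#'
#' @param profile a [depth_profile()].
#' @param entrance_depth_mm start of the entrance window (mm).
#' @param entrance_window_mm width of the entrance window (mm).
#' @return A [depth_profile()] in percent.
#' @export
pdd_normalize <- function(profile, entrance_depth_mm = 10,
                          entrance_window_mm = 10) {
  stopifnot(inherits(profile, "depth_profile"))
  lo <- entrance_depth_mm; hi <- entrance_depth_mm + entrance_window_mm
  sel <- profile$depth_mm >= lo & profile$depth_mm <= hi
  if (!any(sel))
    stop(sprintf("entrance window %g-%g mm contains no profile samples",
                 lo, hi))
  ref <- mean(profile$value[sel])
  if (ref <= 0) stop("entrance-window mean is not positive")
  depth_profile(profile$depth_mm, 100 * profile$value / ref,
                100 * profile$value_sd / ref, profile$n_averaged)
}

#' Compare a gel-derived PDD with a reference depth-dose curve
#'
#' Linearly interpolates both profiles onto the intersection of their
#' depth ranges at the gel sampling pitch (no extrapolation) and reports
#' the pointwise difference and the two Bragg-peak depths.
#'
#' @param gel gel-derived [depth_profile()] (typically percent PDD).
#' @param reference reference [depth_profile()] (e.g. ionization-chamber
#'   PDD).
#' @return An object of class `profile_comparison`: `common_depth_mm`,
#'   `gel_pdd`, `reference_pdd`, `pointwise_diff` (gel - reference),
#'   `peak_depth_gel_mm`, `peak_depth_ref_mm`, `peak_depth_diff_mm`.
#' @export
compare_profiles <- function(gel, reference) {
  stopifnot(inherits(gel, "depth_profile"),
            inherits(reference, "depth_profile"))
  lo <- max(min(gel$depth_mm), min(reference$depth_mm))
  hi <- min(max(gel$depth_mm), max(reference$depth_mm))
  if (lo > hi) stop("profiles have disjoint depth ranges")
  pitch <- stats::median(diff(gel$depth_mm))
  grid <- seq(lo, hi, by = pitch)
  gi <- stats::approx(gel$depth_mm, gel$value, xout = grid)$y
  ri <- stats::approx(reference$depth_mm, reference$value, xout = grid)$y
  pk_g <- find_bragg_peak(depth_profile(grid, gi))
  pk_r <- find_bragg_peak(depth_profile(grid, ri))
  structure(list(common_depth_mm = grid, gel_pdd = gi, reference_pdd = ri,
                 pointwise_diff = gi - ri,
                 peak_depth_gel_mm = pk_g$peak_depth_mm,
                 peak_depth_ref_mm = pk_r$peak_depth_mm,
                 peak_depth_diff_mm = pk_g$peak_depth_mm - pk_r$peak_depth_mm),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf(
    "profile comparison over %.4g-%.4g mm: mean |diff| %.3g, peaks %.4g vs %.4g mm (diff %.3g)\n",
    min(x$common_depth_mm), max(x$common_depth_mm),
    mean(abs(x$pointwise_diff)), x$peak_depth_gel_mm, x$peak_depth_ref_mm,
    x$peak_depth_diff_mm))
  invisible(x)
}

#' SNR and coefficient of variation of an R1-map ROI
#'
#' `cv_percent = 100 * sd / mean` and `snr = mean / sd`, both over the
#' valid voxels of the same circular ROI (the SNR definition mirrors the
#' CV definition; a uniform ROI reports `snr = Inf`, `cv = 0`).
#'
#' @inheritParams roi_mean_r1
#' @param roi_center_mm ROI centre, three coordinates in mm.
#' @param roi_diameter_mm ROI diameter in mm.
#' @return list with `snr`, `cv_percent`, `mean`, `sd`, `n`.
#' @export
image_quality <- function(map, roi_center_mm, roi_diameter_mm = 10,
                          plane = "xy", n_slices = 1L) {
  r <- roi_mean_r1(map, roi_center_mm, roi_diameter_mm, plane, n_slices)
  if (r$sd == 0)
    return(list(snr = Inf, cv_percent = 0, mean = r$mean, sd = 0, n = r$n))
  list(snr = r$mean / r$sd, cv_percent = 100 * r$sd / r$mean,
       mean = r$mean, sd = r$sd, n = r$n)
}

#' Convert a delta-R1 depth profile to absorbed dose
#'
#' `dose_Gy = 1000 * delta_R1 / sensitivity`, with either a single
#' entrance sensitivity or a per-depth sensitivity vector (e.g.
#' [depth_sensitivity()] evaluated on the profile depths).
#'
#' @param profile a delta-R1 [depth_profile()] (1/s).
#' @param sensitivity_per_kgy sensitivity in 1/s per kGy: scalar or one
#'   value per depth sample.
#' @return A [depth_profile()] in Gy.
#' @export
dose_from_delta_r1 <- function(profile, sensitivity_per_kgy) {
  stopifnot(inherits(profile, "depth_profile"))
  if (any(sensitivity_per_kgy <= 0)) stop("sensitivity must be positive")
  if (!length(sensitivity_per_kgy) %in% c(1L, length(profile$depth_mm)))
    stop("sensitivity must be scalar or one value per depth sample")
  depth_profile(profile$depth_mm,
                1000 * profile$value / sensitivity_per_kgy,
                1000 * profile$value_sd / sensitivity_per_kgy,
                profile$n_averaged)
}
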