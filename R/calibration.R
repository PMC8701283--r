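# R1 -> chemical/dose calibration: ROI statistics, linear calibration
# fits (Fe3+ concentration or entrance-surface dose on the abscissa), and
# the radiation-chemical-yield computation.

plane_axes <- function(plane) {
  switch(plane,
         xy = list(inplane = c(1L, 2L), normal = 3L),
         xz = list(inplane = c(1L, 3L), normal = 2L),
         yz = list(inplane = c(2L, 3L), normal = 1L),
         stop("plane must be one of 'xy', 'xz', 'yz'"))
}

# logical array selecting a circular ROI: voxels whose in-plane centre
# lies within diameter/2 of center_mm, over n_slices slices around the
# centre along the normal axis
roi_mask <- function(dim, spacing_mm, center_mm, diameter_mm,
                     plane = "xy", n_slices = 1L) {
  ax <- plane_axes(plane)
  if (length(center_mm) != 3L) stop("center_mm must give three coordinates")
  if (diameter_mm <= 0) stop("diameter_mm must be positive")
  co <- lapply(1:3, function(j) voxel_centres_mm(dim[j], spacing_mm[j]))
  i1 <- ax$inplane[1L]; i2 <- ax$inplane[2L]; nn <- ax$normal
  disc <- outer((co[[i1]] - center_mm[i1])^2,
                (co[[i2]] - center_mm[i2])^2, `+`) <= (diameter_mm / 2)^2
  kc <- round(center_mm[nn] / spacing_mm[nn] + 0.5)
  half <- (n_slices - 1L) %/% 2L
  ks <- (kc - half):(kc + half)
  ks <- ks[ks >= 1L & ks <= dim[nn]]
  if (!length(ks)) stop("ROI slices fall outside the volume")
  m <- array(FALSE, dim = dim)
  idx <- list(seq_len(dim[1L]), seq_len(dim[2L]), seq_len(dim[3L]))
  idx[[nn]] <- ks
  sub <- array(FALSE, dim = dim[ax$inplane])
  sub[disc] <- TRUE
  for (k in ks) {
    ix <- idx; ix[[nn]] <- k
    m <- do.call(`[<-`, c(list(m), ix, list(value = sub)))
  }
  m
}

#' Circular-ROI statistics of an R1 map
#'
#' Mean, SD and voxel count of the valid voxels whose in-plane centre lies
#' within `diameter_mm / 2` of `center_mm`, over `n_slices` slices around
#' the centre along the plane normal (voxel-centre inclusion, no
#' partial-volume weighting).
#'
#' @param map an [r1_volume()].
#' @param center_mm ROI centre, three physical coordinates in mm.
#' @param diameter_mm ROI diameter in mm (the reference analysis uses
#'   10 mm).
#' @param plane ROI plane: `"xy"`, `"xz"` or `"yz"`.
#' @param n_slices number of slices to pool along the plane normal.
#' @return list with `mean`, `sd` and `n` (valid voxel count).
#' @export
roi_mean_r1 <- function(map, center_mm, diameter_mm = 10, plane = "xy",
                        n_slices = 1L) {
  stopifnot(inherits(map, "r1_volume"))
  m <- roi_mask(dim(map$r1_per_s), map$voxel_spacing_mm, center_mm,
                diameter_mm, plane, n_slices)
  sel <- m & map$valid_mask
  n <- sum(sel)
  if (n == 0L)
    stop(sprintf(
      "ROI (centre %s mm, diameter %g mm, plane %s) contains no valid voxels",
      paste(signif(center_mm, 4), collapse = "/"), diameter_mm, plane))
  v <- map$r1_per_s[sel]
  list(mean = mean(v), sd = if (n > 1L) stats::sd(v) else 0, n = n)
}

#' Build a calibration point table
#'
#' @param level Fe3+ concentration in mM (calibration mode) or entrance
#'   surface dose in Gy (dose-response mode); >= 0.
#' @param r1_mean mean ROI R1, 1/s (> 0).
#' @param r1_sd ROI standard deviation, 1/s (>= 0).
#' @param n_voxels ROI voxel count (optional, enables propagated slope
#'   standard errors in [fit_linear_calibration()]).
#' @return A `data.frame` of class `calibration_points`.
#' @export
calibration_points <- function(level, r1_mean, r1_sd = 0, n_voxels = NA) {
  if (any(level < 0)) stop("levels must be >= 0")
  if (any(!is.finite(r1_mean)) || any(r1_mean <= 0))
    stop("r1_mean values must be positive and finite")
  if (any(r1_sd < 0, na.rm = TRUE)) stop("r1_sd must be >= 0")
  out <- data.frame(level = level, r1_mean = r1_mean,
                    r1_sd = rep_len(r1_sd, length(level)),
                    n_voxels = rep_len(n_voxels, length(level)))
  class(out) <- c("calibration_points", "data.frame")
  out
}

#' Ordinary least-squares linear calibration of R1 against level
#'
#' Fits `r1_mean = intercept + slope * level`. With two points this is the
#' exact line. The slope standard error is propagated from the per-point
#' ROI standard errors (`r1_sd / sqrt(n_voxels)`) when every point carries
#' them, and falls back to the residual-based OLS standard error
#' otherwise. R-squared is the usual coefficient of determination (equal
#' to the squared Pearson correlation for a simple linear fit).
#'
#' @param points a [calibration_points()] table (or any data frame with
#'   `level` and `r1_mean` columns) with at least two distinct levels.
#' @param weighted if `TRUE`, weight points by inverse ROI-mean variance
#'   (requires `r1_sd > 0` and `n_voxels`); default `FALSE`, matching
#'   simple unweighted calibration fits.
#' @return An object of class `calibration_curve` with `slope`,
#'   `slope_se`, `intercept`, `r_squared` and the input `points`.
#' @export
#' @examples
#' pts <- calibration_points(c(0, 0.25, 0.5), c(1, 2, 3))
#' fit_linear_calibration(pts)
fit_linear_calibration <- function(points, weighted = FALSE) {
  if (!all(c("level", "r1_mean") %in% names(points)))
    stop("points must have 'level' and 'r1_mean' columns")
  x <- points$level; y <- points$r1_mean
  if (length(unique(x)) < 2L)
    stop("at least two distinct levels are required")
  se_pt <- if (!is.null(points$r1_sd) && !is.null(points$n_voxels) &&
               all(is.finite(points$r1_sd)) && all(is.finite(points$n_voxels)) &&
               all(points$n_voxels >= 1))
    points$r1_sd / sqrt(points$n_voxels) else NULL
  w <- NULL
  if (weighted) {
    if (is.null(se_pt) || any(se_pt <= 0))
      stop("weighted fit requires positive r1_sd and n_voxels on every point")
    w <- 1 / se_pt^2
  }
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  # exact synthetic lines are legitimate input; silence lm's perfect-fit note
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  slope_se <- if (!weighted && !is.null(se_pt)) {
    xbar <- mean(x)
    sxx <- sum((x - xbar)^2)
    sqrt(sum(((x - xbar) / sxx)^2 * se_pt^2))
  } else sm$coefficients[2L, 2L]
  structure(list(slope = slope, slope_se = slope_se, intercept = intercept,
                 r_squared = sm$r.squared, points = points,
                 weighted = weighted,
                 se_method = if (!weighted && !is.null(se_pt))
                   "propagated" else "residual"),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("linear calibration: R1 = %.5g + %.5g * level  (R^2 = %.5f)\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  slope SE %.3g (%s), %d points\n", x$slope_se, x$se_method,
              nrow(x$points)))
  invisible(x)
}

#' Radiation chemical yield G(Fe3+)
#'
#' `G = dose_sensitivity / conc_slope / density`, in micromol/J: the
#' entrance-surface dose sensitivity (1/s per kGy) divided by the
#' per-millimolar relaxivity (1/s per mM) gives mM/kGy = umol/(L Gy);
#' dividing by the gel density (kg/L) converts to umol per absorbed joule.
#' When standard errors are supplied, the relative errors are combined in
#' quadrature.
#'
#' @param dose_sensitivity entrance dose sensitivity, 1/s per kGy (> 0).
#' @param conc_slope relaxivity slope, 1/s per mM (> 0).
#' @param density gel density, kg/L (> 0; default 1.007).
#' @param dose_sensitivity_se,conc_slope_se,density_se optional standard
#'   errors (the default density uncertainty is 0.004 kg/L).
#' @return An object of class `g_value_result` with `g_value` (umol/J),
#'   `g_value_se` and the inputs.
#' @export
#' @examples
#' g_value(1.08, 5.7, 1.007)  # 0.188 umol/J
g_value <- function(dose_sensitivity, conc_slope, density = 1.007,
                    dose_sensitivity_se = 0, conc_slope_se = 0,
                    density_se = 0.004) {
  if (dose_sensitivity <= 0 || conc_slope <= 0 || density <= 0)
    stop("all g_value inputs must be positive")
  g <- dose_sensitivity / conc_slope / density
  rel <- sqrt((dose_sensitivity_se / dose_sensitivity)^2 +
                (conc_slope_se / conc_slope)^2 +
                (density_se / density)^2)
  structure(list(g_value = g, g_value_se = g * rel,
                 inputs = list(dose_sensitivity = dose_sensitivity,
                               conc_slope = conc_slope, density = density)),
            class = "g_value_result")
}

#' @export
print.g_value_result <- function(x, ...) {
  cat(sprintf("G(Fe3+) = %.3f +/- %.3f umol/J\n", x$g_value, x$g_value_se))
  invisible(x)
}

#' Read or write calibration points as CSV
#'
#' The CSV schema is `level,unit,r1_mean,r1_sd,n_voxels`.
#'
#' @param path file path.
#' @return `read_calibration_csv` returns a [calibration_points()] table
#'   with a `unit` attribute.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "r1_mean")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("calibration CSV is missing column(s): ", paste(miss, collapse = ", "))
  pts <- calibration_points(df$level, df$r1_mean,
                            r1_sd = if (is.null(df$r1_sd)) 0 else df$r1_sd,
                            n_voxels = if (is.null(df$n_voxels)) NA
                                       else df$n_voxels)
  attr(pts, "unit") <- if (is.null(df$unit)) NA_character_ else df$unit[1L]
  pts
}

#' @param points a [calibration_points()] table.
#' @param unit level unit string stored in the CSV (`"mM"` or `"Gy"`).
#' @rdname read_calibration_csv
#' @export
write_calibration_csv <- function(points, path, unit = "mM") {
  df <- data.frame(level = points$level, unit = unit,
                   r1_mean = points$r1_mean, r1_sd = points$r1_sd,
                   n_voxels = points$n_voxels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
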