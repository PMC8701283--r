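#' Co-registered multi-flip-angle magnitude volumes
#'
#' Bundles one 3D non-negative magnitude volume per flip angle, all on the
#' same grid. This is the raw input of the VFA R1 fit.
#'
#' @param volumes list of 3D numeric arrays, identical dimensions, all
#'   intensities >= 0.
#' @param flip_angles_deg flip angle (degrees) of each volume, same length
#'   as `volumes`.
#' @param voxel_spacing_mm voxel spacing, three values in mm.
#' @return An object of class `flip_angle_volume_set`.
#' @export
flip_angle_volume_set <- function(volumes, flip_angles_deg,
                                  voxel_spacing_mm = c(1, 1, 1)) {
  if (!is.list(volumes) || length(volumes) < 2L)
    stop("volumes must be a list of at least two arrays")
  if (length(volumes) != length(flip_angles_deg))
    stop("number of volumes (", length(volumes),
         ") does not match number of flip angles (", length(flip_angles_deg), ")")
  d <- dim(volumes[[1L]])
  if (is.null(d) || length(d) != 3L)
    stop("each volume must be a 3D array")
  for (i in seq_along(volumes)) {
    if (!identical(dim(volumes[[i]]), d))
      stop("volume ", i, " has a different shape")
    if (any(volumes[[i]] < 0, na.rm = TRUE))
      stop("volume ", i, " contains negative intensities")
  }
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("voxel_spacing_mm must be three positive values")
  structure(list(volumes = volumes,
                 flip_angles_deg = as.numeric(flip_angles_deg),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
            class = "flip_angle_volume_set")
}

#' @export
print.flip_angle_volume_set <- function(x, ...) {
  cat(sprintf("flip-angle volume set: %d angles (%s deg), grid %s, spacing %s mm\n",
              length(x$volumes), paste(x$flip_angles_deg, collapse = "/"),
              paste(dim(x$volumes[[1L]]), collapse = "x"),
              paste(signif(x$voxel_spacing_mm, 4), collapse = "x")))
  invisible(x)
}

#' Voxel-wise longitudinal relaxation-rate map
#'
#' A fitted R1 (= 1/T1, in 1/s) volume with its equilibrium-magnetization
#' map and a validity mask. Voxels outside the mask are stored as `NA` and
#' must be excluded from all downstream statistics.
#'
#' @param r1_per_s 3D array of R1 in 1/s.
#' @param m0 3D array of fitted M0 (arbitrary units), or `NULL`.
#' @param valid_mask 3D logical array, `TRUE` where the fit is valid.
#' @param voxel_spacing_mm voxel spacing, three values in mm.
#' @param positive enforce r1 > 0 inside the mask (the contract for fitted
#'   maps). Difference maps (see [delta_r1()]) legitimately carry negative
#'   values and set this to `FALSE`.
#' @return An object of class `r1_volume`.
#' @export
r1_volume <- function(r1_per_s, m0 = NULL, valid_mask = NULL,
                      voxel_spacing_mm = c(1, 1, 1), positive = TRUE) {
  d <- dim(r1_per_s)
  if (is.null(d) || length(d) != 3L) stop("r1_per_s must be a 3D array")
  if (is.null(valid_mask)) valid_mask <- !is.na(r1_per_s)
  if (!identical(dim(valid_mask), d)) stop("valid_mask shape mismatch")
  if (!is.null(m0) && !identical(dim(m0), d)) stop("m0 shape mismatch")
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("voxel_spacing_mm must be three positive values")
  bad <- valid_mask & !is.finite(r1_per_s)
  if (any(bad)) stop("non-finite r1 values inside the valid mask")
  if (positive && any(valid_mask & (r1_per_s <= 0)))
    stop("non-positive r1 values inside the valid mask")
  r1_per_s[!valid_mask] <- NA_real_
  if (!is.null(m0)) m0[!valid_mask] <- NA_real_
  structure(list(r1_per_s = r1_per_s, m0 = m0,
                 valid_mask = valid_mask,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
            class = "r1_volume")
}

#' @export
print.r1_volume <- function(x, ...) {
  v <- x$r1_per_s[x$valid_mask]
  cat(sprintf("R1 volume: grid %s, spacing %s mm, %d/%d valid voxels\n",
              paste(dim(x$r1_per_s), collapse = "x"),
              paste(signif(x$voxel_spacing_mm, 4), collapse = "x"),
              sum(x$valid_mask), length(x$valid_mask)))
  if (length(v))
    cat(sprintf("  R1 range %.4g .. %.4g 1/s (median %.4g)\n",
                min(v), max(v), stats::median(v)))
  invisible(x)
}

# voxel-centre physical coordinates along one axis (mm); 1-based index i
# sits at (i - 0.5) * spacing
voxel_centres_mm <- function(n, spacing_mm) (seq_len(n) - 0.5) * spacing_mm
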