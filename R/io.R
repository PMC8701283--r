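# NIfTI / CSV / JSON readers and writers. Volumes travel as NIfTI-1 with
# spacing in the header (float32 on disk, float64 in memory for fitting).

#' Read a 3D volume from NIfTI-1
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return list with `data` (3D numeric array) and `spacing_mm` (three
#'   voxel sizes).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 3L) stop("expected a 3D volume in ", path,
                           " but found ", length(d), " dimensions")
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L)
      stop("expected a 3D volume in ", path, " but found dimensions ",
           paste(d, collapse = "x"))
    dim(img) <- d[1:3]
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid voxel spacing (pixdim) in ", path)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing_mm = as.numeric(spacing))
}

#' Write a 3D volume to NIfTI-1
#'
#' Data are stored as float32 (MR-typical precision); spacing goes to the
#' header exactly.
#'
#' @param volume 3D numeric array.
#' @param path output path.
#' @param spacing_mm voxel spacing, three values in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing_mm = c(1, 1, 1)) {
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be three positive values")
  img <- RNifti::asNifti(structure(volume, pixdim = spacing_mm),
                         datatype = "float")
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write an R1 map (and its mask) to NIfTI
#'
#' Invalid voxels are written as NaN; a companion `*_mask.nii.gz` carries
#' the validity mask.
#'
#' @param map an [r1_volume()].
#' @param path output path for the R1 map.
#' @return `path`, invisibly.
#' @export
write_r1_volume <- function(map, path) {
  stopifnot(inherits(map, "r1_volume"))
  x <- map$r1_per_s
  x[!map$valid_mask] <- NaN
  write_volume(x, path, map$voxel_spacing_mm)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  if (identical(mask_path, path)) mask_path <- paste0(path, "_mask.nii.gz")
  write_volume(array(as.numeric(map$valid_mask), dim = dim(x)),
               mask_path, map$voxel_spacing_mm)
  invisible(path)
}

#' Read a depth profile from CSV
#'
#' Accepts the pipeline's own `depth_mm,value,value_sd` schema and the
#' ionization-chamber reference schema `depth_mm,relative_dose`.
#'
#' @param path CSV path.
#' @return A [depth_profile()].
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"depth_mm" %in% names(df))
    stop("profile CSV is missing column 'depth_mm'")
  val <- if ("value" %in% names(df)) df$value
         else if ("relative_dose" %in% names(df)) df$relative_dose
         else stop("profile CSV needs a 'value' or 'relative_dose' column")
  o <- order(df$depth_mm)
  depth_profile(df$depth_mm[o], val[o],
                if ("value_sd" %in% names(df)) df$value_sd[o] else NULL)
}

#' @param profile a [depth_profile()].
#' @rdname read_profile_csv
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param x a list (or result object) to serialize.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  if (!is.list(x)) stop("report must be a list")
  x <- rapply(unclass(x), function(v) v, how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
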