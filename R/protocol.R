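#' Spoiled-gradient-echo acquisition protocol
#'
#' Container for the SPGR acquisition parameters used both by the signal
#' model and by the synthetic acquisition simulator. Defaults reproduce the
#' 3D VFA protocol used for gel-sample scanning: TR 15 ms, TE 3.38 ms, flip
#' angles 7 and 36 degrees, 256 mm field of view at a 256 x 256 matrix,
#' 1 mm slices.
#'
#' @param tr_ms repetition time in milliseconds (> 0).
#' @param te_ms echo time in milliseconds. Carried for provenance; the SPGR
#'   model used here has no TE dependence (full spoiling, TE << T2*).
#' @param flip_angles_deg ordered vector of at least two pairwise-distinct
#'   flip angles, each strictly between 0 and 90 degrees.
#' @param fov_mm in-plane field of view, two values in mm.
#' @param matrix in-plane acquisition matrix, two integers >= 8.
#' @param slice_thickness_mm slice thickness in mm.
#' @param n_slices number of slices (>= 1).
#' @param nex number of excitations (averages).
#' @param bandwidth_hz_px receiver bandwidth in Hz/pixel.
#'
#' @return An object of class `scan_protocol`.
#' @export
#' @examples
#' p <- scan_protocol()
#' p$flip_angles_deg
scan_protocol <- function(tr_ms = 15, te_ms = 3.38, flip_angles_deg = c(7, 36),
                          fov_mm = c(256, 256), matrix = c(256, 256),
                          slice_thickness_mm = 1, n_slices = 40,
                          nex = 4, bandwidth_hz_px = 130) {
  if (!is.numeric(tr_ms) || length(tr_ms) != 1L || tr_ms <= 0)
    stop("tr_ms must be a single positive number")
  if (length(flip_angles_deg) < 2L)
    stop("at least two flip angles are required")
  if (any(flip_angles_deg <= 0) || any(flip_angles_deg >= 90))
    stop("flip angles must lie strictly between 0 and 90 degrees")
  if (anyDuplicated(flip_angles_deg))
    stop("flip angles must be pairwise distinct")
  if (length(fov_mm) != 2L || any(fov_mm <= 0))
    stop("fov_mm must be two positive values")
  if (length(matrix) != 2L || any(matrix < 8))
    stop("matrix must be two values >= 8")
  if (slice_thickness_mm <= 0) stop("slice_thickness_mm must be positive")
  if (n_slices < 1) stop("n_slices must be >= 1")
  structure(list(
    tr_ms = tr_ms, te_ms = te_ms,
    flip_angles_deg = as.numeric(flip_angles_deg),
    fov_mm = as.numeric(fov_mm), matrix = as.integer(matrix),
    slice_thickness_mm = slice_thickness_mm, n_slices = as.integer(n_slices),
    nex = nex, bandwidth_hz_px = bandwidth_hz_px
  ), class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat("SPGR scan protocol\n")
  cat(sprintf("  TR %.4g ms, TE %.4g ms, FA %s deg\n", x$tr_ms, x$te_ms,
              paste(x$flip_angles_deg, collapse = "/")))
  cat(sprintf("  FOV %s mm, matrix %s, ST %.4g mm, Ns %d, NEX %.3g, BW %.4g Hz/px\n",
              paste(x$fov_mm, collapse = "x"), paste(x$matrix, collapse = "x"),
              x$slice_thickness_mm, x$n_slices, x$nex, x$bandwidth_hz_px))
  invisible(x)
}

#' Read or write a scan protocol as YAML
#'
#' The YAML block uses the short acquisition-table field names
#' (`tr_ms`, `te_ms`, `fa_deg`, `fov_mm`, `matrix`, `st_mm`, `ns`, `bw`,
#' `nex`).
#'
#' @param path file path.
#' @return `read_protocol_yaml` returns a [scan_protocol()];
#'   `write_protocol_yaml` returns `path` invisibly.
#' @export
read_protocol_yaml <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("tr_ms", "fa_deg")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("protocol YAML is missing field(s): ", paste(miss, collapse = ", "))
  scan_protocol(
    tr_ms = y$tr_ms,
    te_ms = if (is.null(y$te_ms)) 3.38 else y$te_ms,
    flip_angles_deg = unlist(y$fa_deg),
    fov_mm = if (is.null(y$fov_mm)) c(256, 256) else unlist(y$fov_mm),
    matrix = if (is.null(y$matrix)) c(256, 256) else unlist(y$matrix),
    slice_thickness_mm = if (is.null(y$st_mm)) 1 else y$st_mm,
    n_slices = if (is.null(y$ns)) 1 else y$ns,
    nex = if (is.null(y$nex)) 1 else y$nex,
    bandwidth_hz_px = if (is.null(y$bw)) 130 else y$bw
  )
}

#' @param protocol a [scan_protocol()].
#' @rdname read_protocol_yaml
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "scan_protocol"))
  y <- list(
    tr_ms = protocol$tr_ms, te_ms = protocol$te_ms,
    fa_deg = protocol$flip_angles_deg,
    fov_mm = protocol$fov_mm, matrix = protocol$matrix,
    st_mm = protocol$slice_thickness_mm, ns = protocol$n_slices,
    bw = protocol$bandwidth_hz_px, nex = protocol$nex
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
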