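#' Longitudinal recovery factor E1 = exp(-TR/T1)
#'
#' @param t1_ms longitudinal relaxation time in ms (> 0); vectorized.
#' @param tr_ms repetition time in ms (> 0).
#' @return E1, strictly inside (0, 1).
#' @export
#' @examples
#' e1_from_t1(1500, 15)
e1_from_t1 <- function(t1_ms, tr_ms) {
  if (any(!is.finite(tr_ms)) || any(tr_ms <= 0)) stop("tr_ms must be positive")
  if (any(t1_ms <= 0, na.rm = TRUE)) stop("t1_ms must be positive")
  exp(-tr_ms / t1_ms)
}

#' T1 recovered from the fitted recovery factor, T1 = -TR / ln(E1)
#'
#' Values of `e1` outside the open interval (0, 1) correspond to unfittable
#' voxels and yield `NA`; the caller is expected to mask them.
#'
#' @param e1 recovery factor; vectorized.
#' @param tr_ms repetition time in ms (> 0).
#' @return T1 in ms, `NA` where `e1` is not in (0, 1).
#' @export
#' @examples
#' t1_from_e1(exp(-0.01), 15)  # 1500
t1_from_e1 <- function(e1, tr_ms) {
  if (any(!is.finite(tr_ms)) || any(tr_ms <= 0)) stop("tr_ms must be positive")
  out <- rep(NA_real_, length(e1))
  ok <- is.finite(e1) & e1 > 0 & e1 < 1
  out[ok] <- -tr_ms / log(e1[ok])
  if (!is.null(dim(e1))) dim(out) <- dim(e1)
  out
}

#' Steady-state SPGR signal
#'
#' Spoiled gradient echo signal
#' `S = M0 (1 - E1) sin(a) / (1 - E1 cos(a))` with `E1 = exp(-TR/T1)`.
#' Ideal spoiling and nominal flip angles are assumed (no B1 correction),
#' and the TE-dependent T2* weighting is absorbed into M0.
#'
#' @param m0 equilibrium magnetization (arbitrary units); vectorized.
#' @param t1_ms longitudinal relaxation time in ms (> 0); vectorized.
#' @param protocol a [scan_protocol()] (only `tr_ms` is used).
#' @param angle_deg flip angle in degrees, `0 <= angle < 90`.
#' @return signal intensity, in `[0, m0]`.
#' @export
#' @examples
#' spgr_signal(1000, 1500, scan_protocol(), 7)
spgr_signal <- function(m0, t1_ms, protocol, angle_deg) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (length(angle_deg) != 1L || angle_deg < 0 || angle_deg >= 90)
    stop("angle_deg must be a single angle in [0, 90)")
  if (any(t1_ms <= 0, na.rm = TRUE)) stop("t1_ms must be positive")
  e1 <- exp(-protocol$tr_ms / t1_ms)
  a <- angle_deg * pi / 180
  m0 * (1 - e1) * sin(a) / (1 - e1 * cos(a))
}

# Vectorized linearized VFA fit over parallel arrays of signals.
# sig_list: one numeric array per flip angle (identical shape).
# Observations are transformed to (x, y) = (S/tan a, S/sin a) and
# y = E1 * x + M0 (1 - E1) is fitted by ordinary least squares; with two
# angles this is the exact two-point line.
# Returns list(e1, t1_ms, m0, valid) of the same shape.
vfa_fit_arrays <- function(sig_list, angles_deg, tr_ms) {
  n <- length(sig_list)
  a <- angles_deg * pi / 180
  sx <- 0; sy <- 0; sxx <- 0; sxy <- 0
  for (i in seq_len(n)) {
    x <- sig_list[[i]] / tan(a[i])
    y <- sig_list[[i]] / sin(a[i])
    sx <- sx + x; sy <- sy + y
    sxx <- sxx + x * x; sxy <- sxy + x * y
  }
  denom <- n * sxx - sx * sx
  e1 <- (n * sxy - sx * sy) / denom
  b <- (sy - e1 * sx) / n
  valid <- is.finite(e1) & e1 > 0 & e1 < 1 & is.finite(b)
  t1 <- rep(NA_real_, length(e1))
  t1[valid] <- -tr_ms / log(e1[valid])
  m0 <- b / (1 - e1)
  m0[!valid] <- NA_real_
  shape <- dim(sig_list[[1L]])
  if (!is.null(shape)) {
    dim(e1) <- shape; dim(t1) <- shape; dim(m0) <- shape; dim(valid) <- shape
  }
  list(e1 = e1, t1_ms = t1, m0 = m0, valid = valid)
}

#' Two-or-more-point VFA fit for a single voxel
#'
#' Linearizes the SPGR equation to `S/sin(a) = E1 * S/tan(a) + M0 (1 - E1)`
#' and fits by ordinary least squares (the exact two-point line when only
#' two angles are acquired). Degenerate data never raise: the voxel is
#' flagged invalid (`valid = FALSE`) when the fitted E1 falls outside
#' (0, 1) or the signals carry no information, and downstream code must
#' honor that flag.
#'
#' @param signals per-angle signal intensities (finite, >= 0), one per
#'   protocol flip angle.
#' @param protocol a [scan_protocol()].
#' @return list with `t1_ms`, `m0`, `e1` and logical `valid`.
#' @export
#' @examples
#' p <- scan_protocol()
#' s <- sapply(p$flip_angles_deg, function(a) spgr_signal(1000, 1200, p, a))
#' vfa_fit_voxel(s, p)
vfa_fit_voxel <- function(signals, protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (length(signals) != length(protocol$flip_angles_deg))
    stop("got ", length(signals), " signals for ",
         length(protocol$flip_angles_deg), " flip angles")
  if (any(!is.finite(signals)) || any(signals < 0))
    return(list(t1_ms = NA_real_, m0 = NA_real_, e1 = NA_real_, valid = FALSE))
  f <- vfa_fit_arrays(as.list(signals), protocol$flip_angles_deg, protocol$tr_ms)
  list(t1_ms = f$t1_ms, m0 = f$m0, e1 = f$e1, valid = f$valid)
}

#' Voxel-wise R1 mapping of a multi-flip-angle volume set
#'
#' Applies the linearized VFA fit to every voxel and returns the R1
#' (= 1000 / T1_ms, in 1/s) map. Voxels whose maximum signal across angles
#' falls below `background_threshold` times a robust global maximum (the
#' 99th percentile of the per-voxel maximum signal) are pre-masked as
#' background; voxels with out-of-range fits are masked as invalid.
#'
#' @param data a [flip_angle_volume_set()].
#' @param protocol a [scan_protocol()] whose angles match `data`.
#' @param background_threshold background cut as a fraction of the robust
#'   maximum signal; default 0.05.
#' @return An [r1_volume()].
#' @export
fit_r1_volume <- function(data, protocol, background_threshold = 0.05) {
  stopifnot(inherits(data, "flip_angle_volume_set"),
            inherits(protocol, "scan_protocol"))
  if (!isTRUE(all.equal(data$flip_angles_deg, protocol$flip_angles_deg)))
    stop("flip angles of data (", paste(data$flip_angles_deg, collapse = "/"),
         ") do not match protocol (",
         paste(protocol$flip_angles_deg, collapse = "/"), ")")
  smax <- Reduce(pmax, data$volumes)
  robust_max <- stats::quantile(smax, 0.99, names = FALSE, na.rm = TRUE)
  fg <- if (robust_max > 0) smax > background_threshold * robust_max
        else array(FALSE, dim = dim(smax))
  f <- vfa_fit_arrays(data$volumes, data$flip_angles_deg, protocol$tr_ms)
  valid <- f$valid & fg
  r1 <- 1000 / f$t1_ms
  r1[!valid] <- NA_real_
  r1_volume(r1, m0 = f$m0, valid_mask = valid,
            voxel_spacing_mm = data$voxel_spacing_mm)
}
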