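# Parametric carbon pencil-beam model.
#
# The depth-dose curve is a deliberately simple analytic stand-in for a
# measured pristine Bragg curve: a gently declining entrance plateau, a
# Gaussian Bragg peak, and a sigmoid-gated fragmentation tail of ~10% of
# the local plateau dose that dies out a few peak-widths beyond the peak.
# No particle-transport physics is implied; the curve only has to present
# the pipeline with the right qualitative features (plateau decline, sharp
# peak near 48 mm, distal tail) at controllable amplitudes.

#' Carbon pencil-beam description for the synthetic phantom
#'
#' @param entrance_dose_gy entrance surface dose (ESD) in Gy (>= 0).
#' @param peak_depth_mm depth of the Bragg peak below the gel entrance
#'   surface (default 48 mm).
#' @param peak_to_entrance_ratio dose at the peak relative to the entrance
#'   dose (> 1; default 3).
#' @param peak_width_mm Gaussian sigma of the Bragg peak (default 2.5 mm).
#' @param plateau_slope_per_mm fractional linear decline of the plateau per
#'   mm of depth (default 0.003).
#' @param tail_fraction post-peak fragmentation-tail dose as a fraction of
#'   the local plateau dose, in `[0, 1)` (default 0.10).
#' @param field_side_mm side of the square collimated field (default 10 mm).
#' @param penumbra_sigma0_mm lateral Gaussian blur of the field edge at
#'   shallow depth (default 1 mm).
#' @param penumbra_growth_start_mm depth beyond which the lateral blur
#'   starts growing (default `peak_depth_mm - 15`).
#' @param penumbra_growth_per_mm blur growth rate beyond that depth
#'   (default 0.08 mm per mm).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(entrance_dose_gy = 600, peak_depth_mm = 48,
                       peak_to_entrance_ratio = 3, peak_width_mm = 2.5,
                       plateau_slope_per_mm = 0.003, tail_fraction = 0.10,
                       field_side_mm = 10, penumbra_sigma0_mm = 1,
                       penumbra_growth_start_mm = peak_depth_mm - 15,
                       penumbra_growth_per_mm = 0.08) {
  if (entrance_dose_gy < 0) stop("entrance_dose_gy must be >= 0")
  if (peak_depth_mm <= 0 || peak_width_mm <= 0 || field_side_mm <= 0 ||
      penumbra_sigma0_mm < 0)
    stop("beam lengths must be positive")
  if (peak_to_entrance_ratio <= 1)
    stop("peak_to_entrance_ratio must exceed 1")
  if (tail_fraction < 0 || tail_fraction >= 1)
    stop("tail_fraction must lie in [0, 1)")
  if (plateau_slope_per_mm < 0 || plateau_slope_per_mm * peak_depth_mm >= 1)
    stop("plateau_slope_per_mm must be >= 0 and keep the plateau positive")
  b <- structure(list(
    entrance_dose_gy = entrance_dose_gy, peak_depth_mm = peak_depth_mm,
    peak_to_entrance_ratio = peak_to_entrance_ratio,
    peak_width_mm = peak_width_mm,
    plateau_slope_per_mm = plateau_slope_per_mm,
    tail_fraction = tail_fraction, field_side_mm = field_side_mm,
    penumbra_sigma0_mm = penumbra_sigma0_mm,
    penumbra_growth_start_mm = penumbra_growth_start_mm,
    penumbra_growth_per_mm = penumbra_growth_per_mm
  ), class = "beam_model")
  cal <- calibrate_peak(b)
  b$peak_amp <- cal$amp
  b$peak_centre_mm <- cal$centre
  b$norm0 <- relative_depth_dose(0, b)
  b
}

# plateau + tail background of the relative (entrance = 1) curve,
# without the Gaussian peak term
beam_background <- function(z, beam) {
  zp <- beam$peak_depth_mm; w <- beam$peak_width_mm
  gate <- 1 / (1 + exp((z - zp) / (w / 2)))          # proximal gate
  cut <- 1 / (1 + exp((z - (zp + 3 * w)) / (w / 2))) # tail extinction
  plateau <- pmax(0, 1 - beam$plateau_slope_per_mm * z)
  plateau * gate + beam$tail_fraction * plateau * (1 - gate) * cut
}

# Solve for the Gaussian amplitude and centre so the full relative curve
# attains exactly peak_to_entrance_ratio at peak_depth_mm with zero slope
# there (a centred Gaussian on the sloped background would shift the
# argmax). Fixed-point iteration; converges in a handful of steps.
calibrate_peak <- function(beam) {
  zp <- beam$peak_depth_mm; w <- beam$peak_width_mm
  target <- beam$peak_to_entrance_ratio
  h <- 1e-4 * w
  bp <- (beam_background(zp + h, beam) - beam_background(zp - h, beam)) / (2 * h)
  b0 <- beam_background(zp, beam)
  centre <- zp
  amp <- target - b0
  for (i in 1:60) {
    phi <- exp(-(zp - centre)^2 / (2 * w^2))
    amp_new <- (target - b0) / phi
    centre_new <- zp - bp * w^2 / (amp_new * phi)
    if (abs(centre_new - centre) < 1e-12 && abs(amp_new - amp) < 1e-12) {
      centre <- centre_new; amp <- amp_new; break
    }
    centre <- centre_new; amp <- amp_new
  }
  list(amp = amp, centre = centre)
}

relative_depth_dose <- function(z, beam) {
  beam_background(z, beam) +
    beam$peak_amp * exp(-(z - beam$peak_centre_mm)^2 / (2 * beam$peak_width_mm^2))
}

#' Relative depth-dose curve of the model beam
#'
#' Evaluates the parametric Bragg curve at depth `z_mm` (measured from the
#' gel entrance surface). The curve equals `entrance_dose_gy` exactly at
#' `z = 0`, declines linearly along the plateau, rises to
#' `peak_to_entrance_ratio` times the entrance dose at `peak_depth_mm`
#' (the true maximum of the curve), and decays through a ~`tail_fraction`
#' fragmentation tail to zero within about three peak-widths beyond the
#' peak.
#'
#' @param z_mm depth in mm (>= 0); vectorized.
#' @param beam a [beam_model()].
#' @return absorbed dose in Gy.
#' @export
#' @examples
#' b <- beam_model(entrance_dose_gy = 600)
#' depth_dose(c(0, 15, 48, 70), b)
depth_dose <- function(z_mm, beam) {
  stopifnot(inherits(beam, "beam_model"))
  if (any(z_mm < 0, na.rm = TRUE)) stop("z_mm must be >= 0")
  beam$entrance_dose_gy * relative_depth_dose(z_mm, beam) / beam$norm0
}

#' Depth-dependent lateral penumbra
#'
#' Gaussian sigma (mm) of the lateral field-edge blur at depth `z_mm`:
#' constant `penumbra_sigma0_mm` until `penumbra_growth_start_mm`, then
#' growing linearly -- a configurable stand-in for the lateral spread
#' observed near the Bragg peak, not a scattering model.
#'
#' @inheritParams depth_dose
#' @return penumbra sigma in mm.
#' @export
penumbra_sigma_mm <- function(z_mm, beam) {
  stopifnot(inherits(beam, "beam_model"))
  beam$penumbra_sigma0_mm +
    beam$penumbra_growth_per_mm * pmax(0, z_mm - beam$penumbra_growth_start_mm)
}

# unit square-field profile along one lateral axis, blurred by a Gaussian
# of sigma mm; u is the signed distance from the beam axis. The analytic
# convolution of an indicator with a Gaussian preserves the integral
# (= field_side_mm) at every depth.
lateral_edge_profile <- function(u, side_mm, sigma_mm) {
  half <- side_mm / 2
  if (all(sigma_mm <= 0)) return(as.numeric(abs(u) < half))
  stats::pnorm((half - u) / sigma_mm) - stats::pnorm((-half - u) / sigma_mm)
}
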