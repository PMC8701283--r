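# Shared fixtures, built in code and memoized so expensive simulations run
# once per test session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, force(expr), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

test_protocol <- function() scan_protocol()

# small fast phantom: 16x32x48 grid, peak at 24 mm, 4x oversampling
small_spec <- function(entrance_dose_gy = 600, noise_cv = 0.037) {
  phantom_spec(vial_diameter_mm = 24, vial_length_mm = 40, gel_offset_mm = 4,
               grid_dim = c(16, 32, 48), noise_cv = noise_cv,
               beam = beam_model(entrance_dose_gy = entrance_dose_gy,
                                 peak_depth_mm = 24, peak_width_mm = 2,
                                 field_side_mm = 8,
                                 penumbra_growth_start_mm = 14),
               oversample_factor = 4)
}

small_noiseless <- function(entrance_dose_gy = 600) {
  cached(paste0("small_nl_", entrance_dose_gy),
         simulate_noiseless_acquisition(small_spec(entrance_dose_gy)))
}

# default-geometry phantom series (the published study's dose levels)
series_esd <- c(150, 300, 450, 600)

default_noiseless <- function(entrance_dose_gy) {
  cached(paste0("default_nl_", entrance_dose_gy),
         simulate_noiseless_acquisition(
           phantom_spec(beam = beam_model(entrance_dose_gy = entrance_dose_gy))))
}

default_calibration_vials <- function() {
  cached("calib_vials", generate_calibration_vials())
}

# noiseless uniform signal set for a given T1 over an array shape
uniform_signal_set <- function(m0, t1_ms, protocol, dim = c(4, 4, 4),
                               spacing = c(1, 1, 1)) {
  vols <- lapply(protocol$flip_angles_deg, function(a)
    array(spgr_signal(m0, t1_ms, protocol, a), dim = dim))
  flip_angle_volume_set(vols, protocol$flip_angles_deg, spacing)
}
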