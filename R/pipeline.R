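# Pipeline driver: configuration, staged execution with stage-named
# errors, and fully regenerable output artifacts (config + seed give
# byte-identical numbers).

#' Pipeline configuration
#'
#' Paths and analysis parameters for a complete depth-dose analysis:
#' per-flip-angle irradiated and control volumes, optional calibration and
#' ionization-chamber reference CSVs, and the profile/ROI settings.
#'
#' @param protocol a [scan_protocol()], or a path to a protocol YAML.
#' @param irradiated_paths per-flip-angle NIfTI paths, in protocol angle
#'   order.
#' @param control_paths per-flip-angle NIfTI paths of the unirradiated
#'   control.
#' @param calibration_csv optional Fe3+ calibration CSV
#'   (`level,unit,r1_mean,r1_sd,n_voxels`).
#' @param ic_reference_csv optional ionization-chamber depth-dose CSV
#'   (`depth_mm,relative_dose`).
#' @param output_dir directory for the emitted artifacts.
#' @param line_center_mm in-plane beam-axis position (mm), `NULL` for the
#'   volume centre.
#' @param beam_axis `"x"`, `"y"` or `"z"`.
#' @param n_slices_avg odd profile averaging widths to emit.
#' @param entrance_depth_mm,entrance_window_mm PDD entrance window.
#' @param roi_center_mm,roi_diameter_mm,roi_plane,roi_n_slices ROI for the
#'   image-quality metrics; `roi_center_mm = NULL` centres it on the
#'   volume.
#' @param background_threshold background premask fraction for
#'   [fit_r1_volume()].
#' @param dose_sensitivity entrance dose sensitivity (1/s per kGy) used to
#'   convert the delta-R1 profile to dose; `NULL` skips the conversion.
#' @param seed integer seed recorded with (and reused by) the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(protocol, irradiated_paths, control_paths,
                            calibration_csv = NULL, ic_reference_csv = NULL,
                            output_dir = "vfadose-out",
                            line_center_mm = NULL, beam_axis = "z",
                            n_slices_avg = c(1L, 3L, 5L, 7L),
                            entrance_depth_mm = 10, entrance_window_mm = 10,
                            roi_center_mm = NULL, roi_diameter_mm = 10,
                            roi_plane = "xy", roi_n_slices = 1L,
                            background_threshold = 0.05,
                            dose_sensitivity = NULL, seed = 1L) {
  if (is.character(protocol)) protocol <- read_protocol_yaml(protocol)
  stopifnot(inherits(protocol, "scan_protocol"))
  if (length(irradiated_paths) != length(protocol$flip_angles_deg))
    stop("need one irradiated volume per protocol flip angle")
  if (length(control_paths) != length(protocol$flip_angles_deg))
    stop("need one control volume per protocol flip angle")
  if (any(n_slices_avg %% 2L == 0L))
    stop("n_slices_avg entries must be odd")
  structure(list(protocol = protocol,
                 irradiated_paths = irradiated_paths,
                 control_paths = control_paths,
                 calibration_csv = calibration_csv,
                 ic_reference_csv = ic_reference_csv,
                 output_dir = output_dir, line_center_mm = line_center_mm,
                 beam_axis = beam_axis,
                 n_slices_avg = as.integer(n_slices_avg),
                 entrance_depth_mm = entrance_depth_mm,
                 entrance_window_mm = entrance_window_mm,
                 roi_center_mm = roi_center_mm,
                 roi_diameter_mm = roi_diameter_mm, roi_plane = roi_plane,
                 roi_n_slices = as.integer(roi_n_slices),
                 background_threshold = background_threshold,
                 dose_sensitivity = dose_sensitivity,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML fields mirror the [pipeline_config()] arguments; `protocol`
#' may be an inline block (see [read_protocol_yaml()] for its field
#' names) or a path to a protocol YAML. Relative input paths are resolved
#' against the config file's directory.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(p, function(q)
      if (file.exists(q)) q else file.path(base, q), character(1L))
  }
  pro <- y$protocol
  if (is.character(pro)) pro <- read_protocol_yaml(resolve(pro))
  else if (is.list(pro)) {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(pro, tmp)
    pro <- read_protocol_yaml(tmp)
  } else stop("config is missing the 'protocol' block or path")
  take <- function(name, default = NULL)
    if (is.null(y[[name]])) default else y[[name]]
  pipeline_config(
    protocol = pro,
    irradiated_paths = resolve(unlist(y$irradiated_paths)),
    control_paths = resolve(unlist(y$control_paths)),
    calibration_csv = resolve(y$calibration_csv),
    ic_reference_csv = resolve(y$ic_reference_csv),
    output_dir = take("output_dir", "vfadose-out"),
    line_center_mm = unlist(take("line_center_mm")),
    beam_axis = take("beam_axis", "z"),
    n_slices_avg = unlist(take("n_slices_avg", c(1L, 3L, 5L, 7L))),
    entrance_depth_mm = take("entrance_depth_mm", 10),
    entrance_window_mm = take("entrance_window_mm", 10),
    roi_center_mm = unlist(take("roi_center_mm")),
    roi_diameter_mm = take("roi_diameter_mm", 10),
    roi_plane = take("roi_plane", "xy"),
    roi_n_slices = take("roi_n_slices", 1L),
    background_threshold = take("background_threshold", 0.05),
    dose_sensitivity = take("dose_sensitivity"),
    seed = take("seed", 1L))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full depth-dose analysis pipeline
#'
#' Stages: read volumes, fit the irradiated and control R1 maps, optional
#' calibration fit, delta-R1, depth profiles with the configured averaging
#' widths, PDD normalization, optional ionization-chamber comparison,
#' image-quality metrics. Every artifact (NIfTI maps, profile CSVs, JSON
#' report, parameter log) is written under `output_dir` and is a pure
#' function of the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the fitted maps, profiles, comparison and
#'   metrics.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  pro <- config$protocol
  run_stage("inputs", {
    missing_in <- c(config$irradiated_paths, config$control_paths,
                    config$calibration_csv, config$ic_reference_csv)
    missing_in <- missing_in[!file.exists(missing_in)]
    if (length(missing_in))
      stop("missing input file(s): ", paste(missing_in, collapse = ", "))
  })
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  load_set <- function(paths) {
    vols <- lapply(paths, read_volume)
    sp <- vols[[1L]]$spacing_mm
    flip_angle_volume_set(lapply(vols, `[[`, "data"), pro$flip_angles_deg, sp)
  }
  irr <- run_stage("read-irradiated", load_set(config$irradiated_paths))
  ctl <- run_stage("read-control", load_set(config$control_paths))

  r1_irr <- run_stage("fit-r1",
    fit_r1_volume(irr, pro, config$background_threshold))
  r1_ctl <- run_stage("fit-r1-control",
    fit_r1_volume(ctl, pro, config$background_threshold))
  write_r1_volume(r1_irr, file.path(config$output_dir, "r1_irradiated.nii.gz"))
  write_r1_volume(r1_ctl, file.path(config$output_dir, "r1_control.nii.gz"))

  calib <- NULL
  if (!is.null(config$calibration_csv)) {
    calib <- run_stage("calibration", {
      pts <- read_calibration_csv(config$calibration_csv)
      fit_linear_calibration(pts)
    })
  }

  dmap <- run_stage("delta-r1", delta_r1(r1_irr, r1_ctl))
  write_r1_volume(dmap, file.path(config$output_dir, "delta_r1.nii.gz"))

  profiles <- run_stage("profiles", {
    ps <- lapply(config$n_slices_avg, function(n)
      extract_depth_profile(dmap, config$beam_axis, config$line_center_mm, n))
    names(ps) <- paste0("n", config$n_slices_avg)
    ps
  })
  for (nm in names(profiles))
    write_profile_csv(profiles[[nm]],
                      file.path(config$output_dir,
                                paste0("delta_r1_profile_", nm, ".csv")))

  main <- profiles[[length(profiles)]]
  pdd <- run_stage("pdd", pdd_normalize(main, config$entrance_depth_mm,
                                        config$entrance_window_mm))
  write_profile_csv(pdd, file.path(config$output_dir, "pdd.csv"))

  dose_prof <- NULL
  if (!is.null(config$dose_sensitivity)) {
    dose_prof <- run_stage("dose-conversion",
      dose_from_delta_r1(main, config$dose_sensitivity))
    write_profile_csv(dose_prof, file.path(config$output_dir,
                                           "dose_profile.csv"))
  }

  comparison <- NULL
  if (!is.null(config$ic_reference_csv)) {
    comparison <- run_stage("ic-comparison", {
      ref <- read_profile_csv(config$ic_reference_csv)
      ref_pdd <- pdd_normalize(ref, config$entrance_depth_mm,
                               config$entrance_window_mm)
      compare_profiles(pdd, ref_pdd)
    })
    utils::write.csv(data.frame(depth_mm = comparison$common_depth_mm,
                                gel_pdd = comparison$gel_pdd,
                                reference_pdd = comparison$reference_pdd,
                                diff = comparison$pointwise_diff),
                     file.path(config$output_dir, "pdd_comparison.csv"),
                     row.names = FALSE)
  }

  metrics <- run_stage("image-quality", {
    centre <- config$roi_center_mm
    if (is.null(centre)) {
      d <- dim(r1_ctl$r1_per_s)
      centre <- d * r1_ctl$voxel_spacing_mm / 2
    }
    list(control = image_quality(r1_ctl, centre, config$roi_diameter_mm,
                                 config$roi_plane, config$roi_n_slices),
         irradiated = image_quality(r1_irr, centre, config$roi_diameter_mm,
                                    config$roi_plane, config$roi_n_slices))
  })

  peak <- run_stage("bragg-peak", find_bragg_peak(main))
  report <- list(
    seed = config$seed,
    peak_depth_mm = peak$peak_depth_mm,
    peak_delta_r1 = peak$peak_value,
    image_quality = metrics,
    calibration = if (!is.null(calib))
      list(slope = calib$slope, slope_se = calib$slope_se,
           intercept = calib$intercept, r_squared = calib$r_squared),
    comparison = if (!is.null(comparison))
      list(peak_depth_gel_mm = comparison$peak_depth_gel_mm,
           peak_depth_ref_mm = comparison$peak_depth_ref_mm,
           peak_depth_diff_mm = comparison$peak_depth_diff_mm,
           mean_abs_diff = mean(abs(comparison$pointwise_diff)))
  )
  write_json_report(report, file.path(config$output_dir, "report.json"))

  log_lines <- c(
    paste0("vfadose ", as.character(utils::packageVersion("vfadose"))),
    paste0("seed: ", config$seed),
    paste0("protocol: TR ", pro$tr_ms, " ms, FA ",
           paste(pro$flip_angles_deg, collapse = "/"), " deg"),
    paste0("beam_axis: ", config$beam_axis),
    paste0("n_slices_avg: ", paste(config$n_slices_avg, collapse = ",")),
    paste0("entrance_window_mm: ", config$entrance_depth_mm, "-",
           config$entrance_depth_mm + config$entrance_window_mm),
    paste0("background_threshold: ", config$background_threshold),
    paste0("inputs: ",
           paste(c(config$irradiated_paths, config$control_paths),
                 collapse = ", "))
  )
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))

  invisible(list(r1_irradiated = r1_irr, r1_control = r1_ctl,
                 delta_r1 = dmap, profiles = profiles, pdd = pdd,
                 dose_profile = dose_prof, calibration = calib,
                 comparison = comparison, metrics = metrics,
                 report = report))
}

#' Write a simulated phantom study to disk
#'
#' Emits per-flip-angle irradiated and control NIfTI volumes, the
#' ground-truth dose and R1 volumes, the protocol YAML and a JSON with the
#' generator parameters -- everything a [pipeline_config()] needs.
#'
#' @param sim result of [simulate_acquisition()].
#' @param dir output directory.
#' @return (invisibly) list of the written paths.
#' @export
write_phantom_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  angles <- sim$protocol$flip_angles_deg
  irr <- character(length(angles)); ctl <- character(length(angles))
  for (i in seq_along(angles)) {
    irr[i] <- file.path(dir, sprintf("irradiated_fa%02d.nii.gz", angles[i]))
    ctl[i] <- file.path(dir, sprintf("control_fa%02d.nii.gz", angles[i]))
    write_volume(sim$irradiated$volumes[[i]], irr[i],
                 sim$irradiated$voxel_spacing_mm)
    write_volume(sim$control$volumes[[i]], ctl[i],
                 sim$control$voxel_spacing_mm)
  }
  sp3 <- rep(sim$spec$voxel_mm, 3L)
  write_volume(sim$truth$dose, file.path(dir, "truth_dose.nii.gz"), sp3)
  write_r1_volume(sim$truth$r1, file.path(dir, "truth_r1.nii.gz"))
  write_protocol_yaml(sim$protocol, file.path(dir, "protocol.yaml"))
  write_json_report(list(
    entrance_dose_gy = sim$spec$beam$entrance_dose_gy,
    peak_depth_mm = sim$spec$beam$peak_depth_mm,
    noise_cv = sim$spec$noise_cv, sigma = sim$sigma,
    seed = sim$seed,
    grid_dim = sim$spec$grid_dim, voxel_mm = sim$spec$voxel_mm
  ), file.path(dir, "ground_truth.json"))
  invisible(list(irradiated = irr, control = ctl))
}
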