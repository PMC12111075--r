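#' End-to-end gel-dosimetry pipeline
#'
#' Composes the full analysis: simulate (or load) the phantom and scans, fit
#' R2 maps, correct inhomogeneity, calibrate, reconstruct dose, register,
#' normalize, run the 3D gamma comparison and the profile deficit analysis,
#' and collect a machine-readable summary.
#'
#' @name pipeline
NULL

#' Assemble a pipeline configuration
#'
#' All stage parameters with their defaults; any component can be overridden.
#'
#' @param seed RNG seed controlling every stochastic stage
#' @param phantom a [phantom_spec()]
#' @param beams a [beam_model()]
#' @param perturb a [perturbation_model()]
#' @param scanner a [scanner_model()]
#' @param truth a [calibration_truth()]
#' @param water_r2 cavity-water relaxation rate (1/s)
#' @param voxels_per_vial,vial_erosion_mm calibration-vial settings
#' @param r2_method,snr_floor,ref_smoothing_mm relaxometry settings
#' @param norm_percentile,norm_margin_mm,norm_presmooth_mm relative
#'   normalization settings (robust maximum; wall margin; smoothing of the
#'   copy used for the percentile)
#' @param gamma a [gamma_criteria()]; the pipeline default uses a coarser
#'   sub-voxel search (`interp_factor = 2`) suited to full-volume runs
#' @param wall_margin_mm erosion used for the wall-excluded gamma statistics
#' @param profile_step_mm sample spacing along dose profiles
#' @param profile_region_halfwidth_mm half-width (in z) of the vertical
#'   profile deficit region inside the port shadow
#' @param write_volumes write NIfTI intermediates when an output directory is
#'   given
#' @return a `run_config` list
#' @export
run_config <- function(seed = 1,
                       phantom = phantom_spec(),
                       beams = beam_model(),
                       perturb = perturbation_model(),
                       scanner = scanner_model(),
                       truth = calibration_truth(),
                       water_r2 = 2,
                       voxels_per_vial = 200,
                       vial_erosion_mm = 1.5,
                       r2_method = "loglinear_weighted",
                       snr_floor = 5,
                       ref_smoothing_mm = 20,
                       norm_percentile = 99.5,
                       norm_margin_mm = 14,
                       norm_presmooth_mm = 3,
                       gamma = gamma_criteria(interp_factor = 2,
                                              normalization = "value",
                                              norm_value = 100),
                       wall_margin_mm = 3,
                       profile_step_mm = 0.5,
                       profile_region_halfwidth_mm = 1,
                       write_volumes = FALSE) {
  cfg <- list(seed = seed, phantom = phantom, beams = beams,
              perturb = perturb, scanner = scanner, truth = truth,
              water_r2 = water_r2, voxels_per_vial = voxels_per_vial,
              vial_erosion_mm = vial_erosion_mm, r2_method = r2_method,
              snr_floor = snr_floor, ref_smoothing_mm = ref_smoothing_mm,
              norm_percentile = norm_percentile,
              norm_margin_mm = norm_margin_mm,
              norm_presmooth_mm = norm_presmooth_mm, gamma = gamma,
              wall_margin_mm = wall_margin_mm,
              profile_step_mm = profile_step_mm,
              profile_region_halfwidth_mm = profile_region_halfwidth_mm,
              write_volumes = write_volumes)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [run_config()]; the keys `phantom`,
#' `beams`, `perturb`, `scanner`, `truth` and `gamma` hold argument lists for
#' the corresponding constructors.
#'
#' @param path YAML (requires the yaml package) or JSON file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  }
  ctors <- list(phantom = phantom_spec, beams = beam_model,
                perturb = perturbation_model, scanner = scanner_model,
                truth = calibration_truth, gamma = gamma_criteria)
  args <- list()
  for (nm in names(raw)) {
    args[[nm]] <- if (nm %in% names(ctors)) do.call(ctors[[nm]], raw[[nm]])
    else raw[[nm]]
  }
  do.call(run_config, args)
}

#' Default fiducial marks on the phantom base
#'
#' Four marks on a ring at the phantom base, visible in both frames; in
#' synthetic mode both frames coincide, so the fitted transform is the
#' identity (up to floating point).
#'
#' @param spec a [phantom_spec()]
#' @param frame "measured" or "planned"
#' @return a [fiducial_set()]
#' @export
make_default_fiducials <- function(spec, frame = "measured") {
  r <- 0.85 * spec$outer_shell_mm[1]
  pts <- rbind(c(r, 0, 2), c(0, r, 2), c(-r, 0, 2), c(0, -r, 2))
  fiducial_set(pts, labels = paste0("M", 1:4), frame = frame)
}

# locate the lateral (+x) gel segment of the port shadow on the labels grid
shadow_gel_segment <- function(spec, labels) {
  ax <- spec_axes(spec)
  pc <- spec$port_center_mm
  jy <- which.min(abs(ax$y - pc[2]))
  kz <- which.min(abs(ax$z - pc[3]))
  gel_line <- labels$labels[, jy, kz] == GEL_LABELS[["gel"]]
  xs <- ax$x[gel_line & ax$x > pc[1]]
  if (length(xs) < 3) stop("port shadow does not cross the gel", call. = FALSE)
  range(xs)
}

#' Run the full pipeline on the synthetic phantom
#'
#' @param config a [run_config()]
#' @param out_dir optional output directory (summary JSON, CSV tables, and
#'   NIfTI volumes / PNG figures when enabled)
#' @param figures write report figures (requires `out_dir`)
#' @return a `gel_run_report`: all stage objects plus a `summary` list
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         figures = FALSE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  spec <- config$phantom
  labels <- make_phantom_labels(spec)
  planned <- planned_dose(spec, config$beams)
  delivered <- delivered_dose(planned, labels, spec, config$perturb)

  bias <- if (config$scanner$bias_amplitude > 0)
    make_bias_field(spec, config$scanner$bias_amplitude,
                    config$scanner$bias_scale_mm)
  else array(1, spec$grid_shape)
  echoes <- simulate_echoes(delivered, labels, config$truth, config$scanner,
                            water_r2 = config$water_r2, bias = bias)
  reference <- simulate_reference(spec, config$scanner, bias = bias)

  phantom_dist <- distance_to(labels$labels != GEL_LABELS[["outside"]],
                              spacing_mm(labels))
  bg_region <- phantom_dist > 8
  sigma_bg <- if (any(bg_region) && config$scanner$noise_sigma > 0)
    background_sigma(echoes, bg_region, labels) else 0

  r2_raw <- fit_r2(echoes, method = config$r2_method,
                   snr_floor = config$snr_floor, sigma = sigma_bg)
  inside <- labels$labels != GEL_LABELS[["outside"]]
  r2_raw$mask <- r2_raw$mask & inside
  r2_raw$r2[!r2_raw$mask] <- NA
  r2_raw$r2_sigma[!r2_raw$mask] <- NA
  r2_ref <- fit_r2(reference, method = config$r2_method,
                   snr_floor = config$snr_floor, sigma = sigma_bg)
  r2_corr <- correct_inhomogeneity(r2_raw, r2_ref,
                                   smoothing_mm = config$ref_smoothing_mm)

  vials <- simulate_calibration_vials(config$truth, config$scanner,
                                      voxels_per_vial = config$voxels_per_vial)
  per_vial <- vial_roi_stats(vials, erosion_mm = config$vial_erosion_mm,
                             method = config$r2_method)
  curve <- fit_calibration(per_vial)

  measured_abs <- r2_to_dose(r2_corr, curve)
  gel <- labels$labels == GEL_LABELS[["gel"]]
  measured_abs$dose[!gel] <- NA

  fid_m <- make_default_fiducials(spec, "measured")
  fid_p <- make_default_fiducials(spec, "planned")
  transform <- rigid_from_fiducials(fid_m, fid_p)
  measured_reg <- resample_to(measured_abs, transform, planned)

  rel <- normalize_relative(measured_reg, planned,
                            percentile = config$norm_percentile,
                            measured_mask = gel, planned_mask = gel,
                            margin_mm = config$norm_margin_mm,
                            presmooth_mm = config$norm_presmooth_mm)

  eval_mask <- gel & !is.na(rel$measured$dose)
  gamma_res <- gamma_3d(rel$planned, rel$measured, config$gamma,
                        norm_mask = eval_mask, slice_axis = "y")
  gel_core <- erode_mask(gel, config$wall_margin_mm, spacing_mm(labels))
  n_core <- sum(gamma_res$evaluated_mask & gel_core)
  rate_core <- if (n_core > 0)
    100 * sum(gamma_res$pass_mask & gel_core) / n_core else NA_real_

  ax <- spec_axes(spec)
  pc <- spec$port_center_mm
  band <- which(abs(ax$y - pc[2]) <=
                  spec$port_diameter_mm / 2 + config$perturb$shadow_softening_mm)
  rates <- gamma_res$pass_rate_per_slice
  in_band <- rates$slice %in% band & rates$evaluated_voxels > 0
  out_band <- !(rates$slice %in% band) & rates$evaluated_voxels > 0
  dip <- list(
    min_rate_in_band = if (any(in_band)) min(rates$pass_rate_pct[in_band])
    else NA_real_,
    median_rate_outside = if (any(out_band))
      median(rates$pass_rate_pct[out_band]) else NA_real_)

  # profile analysis: matched horizontal/vertical lines through the port
  # shadow and through the mirror slice without the port
  seg <- shadow_gel_segment(spec, labels)
  xspan <- range(ax$x)
  step <- config$profile_step_mm
  ns_h <- max(3, ceiling(diff(xspan) / step) + 1)
  line_h <- function(vol, ysign) {
    extract_profile(vol, c(xspan[1], ysign * pc[2], pc[3]),
                    c(xspan[2], ysign * pc[2], pc[3]), ns_h)
  }
  xv <- mean(seg)
  zspan <- c(spec$wall_thickness_mm + 1, max(ax$z))
  ns_v <- max(3, ceiling(diff(zspan) / step) + 1)
  line_v <- function(vol, ysign) {
    extract_profile(vol, c(xv, ysign * pc[2], zspan[1]),
                    c(xv, ysign * pc[2], zspan[2]), ns_v)
  }
  mk_pair <- function(pl, me, region) {
    profile_pair(pl$position_mm, pl$value, me$value, region)
  }
  red <- list()
  prof <- list()
  for (side in c("with", "without")) {
    ys <- if (side == "with") 1 else -1
    ph <- line_h(rel$planned, ys); mh <- line_h(rel$measured, ys)
    pv <- line_v(rel$planned, ys); mv <- line_v(rel$measured, ys)
    reg_v <- abs(pv$z - pc[3]) <= config$profile_region_halfwidth_mm
    red[[paste0(side, "_h")]] <- profile_reduction(mk_pair(ph, mh, NULL))
    red[[paste0(side, "_v")]] <- profile_reduction(mk_pair(pv, mv, reg_v))
    prof[[paste0(side, "_h")]] <- data.frame(
      position_mm = ph$position_mm, x = ph$x, y = ph$y, z = ph$z,
      planned_pct = ph$value, measured_pct = mh$value)
    prof[[paste0(side, "_v")]] <- data.frame(
      position_mm = pv$position_mm, x = pv$x, y = pv$y, z = pv$z,
      planned_pct = pv$value, measured_pct = mv$value)
  }
  metal <- metal_attributed_reduction(list(red$with_h, red$with_v),
                                      list(red$without_h, red$without_v))

  summary <- list(
    seed = config$seed,
    background_sigma = sigma_bg,
    calibration = list(
      slope = curve$slope, intercept = curve$intercept,
      slope_se = curve$slope_se, pearson_r = curve$pearson_r,
      mean_uncertainty_pct = mean_uncertainty(curve),
      dose_resolution_Gy_mean = dose_resolution(curve),
      dose_resolution_Gy_at_3Gy = dose_resolution(curve, at_dose_Gy = 3)),
    reconstruction = list(
      n_clipped = attr(measured_abs, "n_clipped"),
      fiducial_registration_error_mm = transform$fre_mm,
      normalization_Gy = rel$measured$normalization_value,
      planned_normalization_Gy = rel$planned$normalization_value),
    gamma = list(
      pass_rate_overall = gamma_res$pass_rate_overall,
      pass_rate_wall_excluded = rate_core,
      n_evaluated = sum(gamma_res$evaluated_mask),
      metal_slice_band = range(band),
      min_rate_in_band = dip$min_rate_in_band,
      median_rate_outside = dip$median_rate_outside),
    profiles = list(
      with_metal_horizontal = as.list(red$with_h),
      with_metal_vertical = as.list(red$with_v),
      without_metal_horizontal = as.list(red$without_h),
      without_metal_vertical = as.list(red$without_v)),
    metal_attributed_reduction = as.list(metal))

  report <- list(config = config, labels = labels, planned = planned,
                 delivered = delivered, curve = curve, r2 = r2_corr,
                 measured = measured_reg, relative = rel, gamma = gamma_res,
                 profiles = prof, reductions = red, summary = summary)
  class(report) <- "gel_run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(rates, file.path(out_dir, "slice_pass_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(per_vial, file.path(out_dir, "calibration_vials.csv"),
                     row.names = FALSE)
    for (nm in names(prof))
      utils::write.csv(prof[[nm]],
                       file.path(out_dir, paste0("profile_", nm, ".csv")),
                       row.names = FALSE)
    if (isTRUE(config$write_volumes)) {
      write_volume(labels, file.path(out_dir, "labels.nii.gz"))
      write_volume(planned, file.path(out_dir, "planned_Gy.nii.gz"))
      write_volume(measured_reg, file.path(out_dir, "measured_Gy.nii.gz"))
      write_volume(rel$planned, file.path(out_dir, "planned_rel.nii.gz"))
      write_volume(rel$measured, file.path(out_dir, "measured_rel.nii.gz"))
      export_fail_map(gamma_res, labels,
                      shadow_weight = attr(delivered, "shadow_weight"),
                      out_dir = out_dir)
    }
    if (isTRUE(figures)) write_report_figures(report, out_dir)
  }
  report
}

#' @export
print.gel_run_report <- function(x, ...) {
  s <- x$summary
  cat("<gel_run_report>\n")
  cat(sprintf("  calibration: r = %.4f, mean uncertainty %.2f%%\n",
              s$calibration$pearson_r, s$calibration$mean_uncertainty_pct))
  cat(sprintf("  gamma pass rate: %.1f%% (wall-excluded %.1f%%)\n",
              s$gamma$pass_rate_overall, s$gamma$pass_rate_wall_excluded))
  cat(sprintf("  deficits: with metal %.2f%%/%.2f%% (h/v), without %.2f%%/%.2f%%\n",
              s$profiles$with_metal_horizontal$mean_pct,
              s$profiles$with_metal_vertical$mean_pct,
              s$profiles$without_metal_horizontal$mean_pct,
              s$profiles$without_metal_vertical$mean_pct))
  cat(sprintf("  metal-attributed reduction: %.2f%% +/- %.2f%%\n",
              s$metal_attributed_reduction$mean_pct,
              s$metal_attributed_reduction$sd_pct))
  invisible(x)
}

#' Write the report figures
#'
#' Calibration curve with error bars, per-slice pass-rate profile with the
#' metal-slice band, and planned-vs-measured profile overlays.
#'
#' @param report a `gel_run_report`
#' @param out_dir output directory
#' @return invisibly, the paths written
#' @export
write_report_figures <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p1 <- file.path(out_dir, "calibration_curve.png")
  grDevices::png(p1, width = 700, height = 500)
  pv <- report$curve$per_vial
  graphics::plot(pv$dose_Gy, pv$R2_mean, pch = 19,
                 xlab = "Dose (Gy)", ylab = "R2 (1/s)",
                 main = sprintf("Calibration curve (r = %.4f)",
                                report$curve$pearson_r))
  graphics::arrows(pv$dose_Gy, pv$R2_mean - pv$R2_sd, pv$dose_Gy,
                   pv$R2_mean + pv$R2_sd, angle = 90, code = 3,
                   length = 0.04)
  graphics::abline(report$curve$intercept, report$curve$slope, col = "red")
  grDevices::dev.off()
  paths <- c(paths, p1)

  p2 <- file.path(out_dir, "slice_pass_rates.png")
  grDevices::png(p2, width = 700, height = 500)
  r <- report$gamma$pass_rate_per_slice
  graphics::plot(r$slice, r$pass_rate_pct, type = "l",
                 xlab = "slice (y)", ylab = "gamma pass rate (%)",
                 main = "Per-slice gamma pass rate")
  graphics::abline(v = report$summary$gamma$metal_slice_band, lty = 2)
  grDevices::dev.off()
  paths <- c(paths, p2)

  for (nm in names(report$profiles)) {
    p <- file.path(out_dir, paste0("profile_", nm, ".png"))
    grDevices::png(p, width = 700, height = 500)
    pr <- report$profiles[[nm]]
    graphics::plot(pr$position_mm, pr$planned_pct, type = "l", col = "blue",
                   xlab = "position (mm)", ylab = "relative dose (%)",
                   main = paste("Profile", nm))
    graphics::lines(pr$position_mm, pr$measured_pct, col = "red")
    graphics::legend("bottom", c("planned", "measured"),
                     col = c("blue", "red"), lty = 1, bty = "n")
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}
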