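#' Scanner model for multi-echo acquisition
#'
#' Emulates a 3D multi-spin-echo readout: eight echo times at multiples of
#' 35 ms by default, mono-exponential magnitude decay, Rician noise (Gaussian
#' noise of standard deviation `noise_sigma` on each quadrature channel), and
#' a smooth multiplicative bias field. The bias acts on the signal amplitude
#' S0 by default (`bias_mode = "s0"`); the alternative mode `"r2"` applies it
#' multiplicatively to the relaxation rate, the regime the reference-scan
#' inhomogeneity correction is designed to remove.
#'
#' The default `noise_sigma` is chosen so that the per-voxel dose uncertainty
#' of the default calibration batch is about 3% (the mean calibration
#' uncertainty of a well-behaved gel batch).
#'
#' @param echo_times_ms echo times (ms), strictly increasing
#' @param s0 baseline magnitude at TE = 0
#' @param noise_sigma Gaussian std of each quadrature channel
#' @param bias_amplitude peak fractional deviation of the bias field from 1
#' @param bias_scale_mm correlation length of the bias field (Gaussian blobs)
#' @param bias_mode "s0" (amplitude) or "r2" (multiplicative on R2)
#' @param seed optional RNG seed; when non-NULL every simulate_* call reseeds
#' @return a `scanner_model` object
#' @export
scanner_model <- function(echo_times_ms = 35 * (1:8),
                          s0 = 1000,
                          noise_sigma = 5.7,
                          bias_amplitude = 0.05,
                          bias_scale_mm = 60,
                          bias_mode = c("s0", "r2"),
                          seed = NULL) {
  stopifnot(all(diff(echo_times_ms) > 0), all(echo_times_ms > 0),
            s0 > 0, noise_sigma >= 0, bias_amplitude >= 0,
            bias_amplitude < 1, bias_scale_mm > 0)
  obj <- list(echo_times_ms = as.numeric(echo_times_ms), s0 = s0,
              noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
              bias_scale_mm = bias_scale_mm, bias_mode = match.arg(bias_mode),
              seed = seed)
  class(obj) <- "scanner_model"
  obj
}

#' Ground-truth linear R2-dose response of a gel batch
#'
#' @param slope R2 change per Gy (1/s/Gy), must be positive
#' @param intercept R2 at 0 Gy (1/s)
#' @param vial_doses_Gy calibration vial doses (default 0.5 to 4.5 Gy)
#' @return a `calibration_truth` object
#' @export
calibration_truth <- function(slope = 1.2, intercept = 3.0,
                              vial_doses_Gy = seq(0.5, 4.5, by = 0.5)) {
  stopifnot(slope > 0, all(vial_doses_Gy >= 0))
  obj <- list(slope = slope, intercept = intercept,
              vial_doses_Gy = as.numeric(vial_doses_Gy))
  class(obj) <- "calibration_truth"
  obj
}

#' Smooth positive multiplicative bias field on a grid
#'
#' Sum of a few random Gaussian blobs, rescaled so the field stays within
#' `1 +/- amplitude` (hence strictly positive for amplitude < 1).
#'
#' @param spec a [phantom_spec()] providing the grid
#' @param amplitude peak fractional deviation from 1
#' @param scale_mm blob width (mm)
#' @param n_blobs number of blobs
#' @return 3D array of bias values
#' @export
make_bias_field <- function(spec, amplitude = 0.05, scale_mm = 60,
                            n_blobs = 4) {
  if (amplitude <= 0) return(array(1, spec$grid_shape))
  ax <- spec_axes(spec)
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  f <- array(0, spec$grid_shape)
  for (b in seq_len(n_blobs)) {
    ctr <- c(stats::runif(1, min(ax$x), max(ax$x)),
             stats::runif(1, min(ax$y), max(ax$y)),
             stats::runif(1, min(ax$z), max(ax$z)))
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1)
    gx <- exp(-0.5 * ((ax$x - ctr[1]) / scale_mm)^2)
    gy <- exp(-0.5 * ((ax$y - ctr[2]) / scale_mm)^2)
    gz <- exp(-0.5 * ((ax$z - ctr[3]) / scale_mm)^2)
    f <- f + amp * array(rep(gx, times = ny * nz), spec$grid_shape) *
      array(rep(rep(gy, each = nx), times = nz), spec$grid_shape) *
      array(rep(gz, each = nx * ny), spec$grid_shape)
  }
  m <- max(abs(f))
  if (m > 0) f <- f / m
  1 + amplitude * f
}

rician <- function(s, sigma) {
  if (sigma <= 0) return(s)
  n <- length(s)
  sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Simulate the multi-echo acquisition of a dosed phantom
#'
#' Gel voxels decay with `R2 = intercept + slope * dose`; water voxels with a
#' fixed low rate; glass, metal and air give (near-)zero signal. Magnitude
#' noise is Rician.
#'
#' @param dose absolute [dose_volume()] (Gy) on the phantom grid
#' @param labels matching [label_volume()]
#' @param truth a [calibration_truth()]
#' @param scanner a [scanner_model()]
#' @param water_r2 relaxation rate of the cavity water (1/s)
#' @param bias optional precomputed bias field (3D array); when NULL and the
#'   scanner has positive bias amplitude, a field is drawn
#' @return an [echo_series()]
#' @export
simulate_echoes <- function(dose, labels, truth, scanner, water_r2 = 2,
                            bias = NULL) {
  stop_if_grid_mismatch(dose, labels, "dose and labels")
  if (!is.null(scanner$seed)) set.seed(scanner$seed)
  sh <- dim(dose$dose)
  lab <- labels$labels
  gel <- lab == GEL_LABELS[["gel"]]
  if (any(!is.finite(dose$dose[gel])))
    stop("dose must be defined on all gel voxels", call. = FALSE)
  r2 <- array(0, sh)
  r2[gel] <- truth$intercept + truth$slope * dose$dose[gel]
  r2[lab == GEL_LABELS[["water"]]] <- water_r2
  s0 <- array(0, sh)
  s0[gel | lab == GEL_LABELS[["water"]]] <- scanner$s0
  if (is.null(bias)) {
    bias <- if (scanner$bias_amplitude > 0)
      make_bias_field(list(grid_shape = sh,
                           origin_mm = origin_mm(dose),
                           spacing_mm = spacing_mm(dose)),
                      scanner$bias_amplitude, scanner$bias_scale_mm)
    else array(1, sh)
  }
  if (scanner$bias_mode == "s0") s0 <- s0 * bias else r2 <- r2 * bias
  ne <- length(scanner$echo_times_ms)
  data <- array(0, c(sh, ne))
  for (e in seq_len(ne)) {
    s <- s0 * exp(-r2 * scanner$echo_times_ms[e] / 1000)
    data[, , , e] <- rician(s, scanner$noise_sigma)
  }
  out <- echo_series(data, scanner$echo_times_ms,
                     spacing_mm = spacing_mm(dose),
                     origin_mm = origin_mm(dose))
  attr(out, "bias_field") <- bias
  out
}

#' Simulate the uniform reference-gel scan
#'
#' A second phantom of unirradiated gel filling the scanner vessel: spatially
#' uniform true R2, modulated only by the scanner bias field and noise. Used
#' to estimate and remove scanner spatial inhomogeneity.
#'
#' @param spec a [phantom_spec()] providing the grid
#' @param scanner a [scanner_model()]
#' @param uniform_R2 true relaxation rate of the reference gel (1/s)
#' @param bias optional precomputed bias field (3D array)
#' @return an [echo_series()] with attribute `mask` (the vessel interior)
#' @export
simulate_reference <- function(spec, scanner, uniform_R2 = 3, bias = NULL) {
  stopifnot(uniform_R2 > 0)
  if (!is.null(scanner$seed)) set.seed(scanner$seed)
  ax <- spec_axes(spec)
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  rad <- min(max(abs(ax$x)), max(abs(ax$y))) - 1
  cyl <- outer(ax$x^2, ax$y^2, "+") <= rad^2
  mask <- array(rep(as.numeric(cyl), times = nz), spec$grid_shape) > 0
  if (is.null(bias)) {
    bias <- if (scanner$bias_amplitude > 0)
      make_bias_field(spec, scanner$bias_amplitude, scanner$bias_scale_mm)
    else array(1, spec$grid_shape)
  }
  r2 <- array(uniform_R2, spec$grid_shape)
  s0 <- array(0, spec$grid_shape)
  s0[mask] <- scanner$s0
  if (scanner$bias_mode == "s0") s0 <- s0 * bias else r2 <- r2 * bias
  ne <- length(scanner$echo_times_ms)
  data <- array(0, c(spec$grid_shape, ne))
  for (e in seq_len(ne)) {
    s <- s0 * exp(-r2 * scanner$echo_times_ms[e] / 1000)
    data[, , , e] <- rician(s, scanner$noise_sigma)
  }
  out <- echo_series(data, scanner$echo_times_ms,
                     spacing_mm = spec$spacing_mm, origin_mm = spec$origin_mm)
  attr(out, "mask") <- mask
  attr(out, "bias_field") <- bias
  out
}

#' Simulate calibration-vial echo data
#'
#' One echo series per vial at each dose, sharing the scanner's noise model.
#' Vial voxels carry a radial coordinate (mm from the vial axis) so that ROI
#' erosion away from the susceptibility-artifact-prone vial edge can be
#' applied downstream.
#'
#' @param truth a [calibration_truth()]
#' @param scanner a [scanner_model()]
#' @param voxels_per_vial voxels simulated per vial (>= 1)
#' @param vial_radius_mm inner vial radius (default 6, a 12 mm test tube)
#' @return a `vial_echo_set`: list with `echo_times_ms`, `vial_radius_mm` and
#'   `vials` (per vial: `dose_Gy`, `r_mm`, `signal` voxels x echoes matrix)
#' @export
simulate_calibration_vials <- function(truth, scanner, voxels_per_vial = 200,
                                       vial_radius_mm = 6) {
  if (length(truth$vial_doses_Gy) == 0)
    stop("vial dose list is empty", call. = FALSE)
  stopifnot(voxels_per_vial >= 1, vial_radius_mm > 0)
  if (!is.null(scanner$seed)) set.seed(scanner$seed)
  te_s <- scanner$echo_times_ms / 1000
  r_mm <- vial_radius_mm * sqrt((seq_len(voxels_per_vial) - 0.5) /
                                  voxels_per_vial)
  vials <- lapply(seq_along(truth$vial_doses_Gy), function(v) {
    d <- truth$vial_doses_Gy[v]
    r2 <- truth$intercept + truth$slope * d
    s <- scanner$s0 * exp(-outer(rep(r2, voxels_per_vial), te_s))
    sig <- matrix(rician(s, scanner$noise_sigma), nrow = voxels_per_vial)
    list(vial_id = v, dose_Gy = d, r_mm = r_mm, signal = sig)
  })
  obj <- list(echo_times_ms = scanner$echo_times_ms,
              vial_radius_mm = vial_radius_mm, vials = vials)
  class(obj) <- "vial_echo_set"
  obj
}

#' Flatten a vial echo set to a long data frame
#'
#' Columns: vial_id, dose_Gy, voxel, r_mm, TE_ms, signal — the CSV exchange
#' format for calibration data.
#'
#' @param x a `vial_echo_set`
#' @param row.names,optional,... ignored (S3 signature)
#' @return a data.frame
#' @export
as.data.frame.vial_echo_set <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  do.call(rbind, lapply(x$vials, function(v) {
    nv <- length(v$r_mm); ne <- length(x$echo_times_ms)
    data.frame(vial_id = v$vial_id, dose_Gy = v$dose_Gy,
               voxel = rep(seq_len(nv), times = ne),
               r_mm = rep(v$r_mm, times = ne),
               TE_ms = rep(x$echo_times_ms, each = nv),
               signal = as.vector(v$signal))
  }))
}

#' Rebuild a vial echo set from its long data-frame form
#' @param df data.frame with columns vial_id, dose_Gy, voxel, r_mm, TE_ms, signal
#' @param vial_radius_mm inner vial radius (mm)
#' @return a `vial_echo_set`
#' @export
vial_echo_set_from_df <- function(df, vial_radius_mm = 6) {
  te <- sort(unique(df$TE_ms))
  vials <- lapply(sort(unique(df$vial_id)), function(id) {
    d <- df[df$vial_id == id, ]
    nv <- max(d$voxel)
    sig <- matrix(NA_real_, nv, length(te))
    sig[cbind(d$voxel, match(d$TE_ms, te))] <- d$signal
    list(vial_id = id, dose_Gy = d$dose_Gy[1],
         r_mm = d$r_mm[match(seq_len(nv), d$voxel)], signal = sig)
  })
  obj <- list(echo_times_ms = te, vial_radius_mm = vial_radius_mm,
              vials = vials)
  class(obj) <- "vial_echo_set"
  obj
}
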