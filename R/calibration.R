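#' R2-dose calibration from vial data
#'
#' Turns per-vial echo data into a linear R2-dose calibration with the usual
#' gel-dosimetry diagnostics: Pearson correlation of the vial means, mean
#' relative dose uncertainty, and dose resolution.
#'
#' @name calibration
NULL

#' Per-vial R2 statistics inside an eroded ROI
#'
#' Each vial's voxels are fitted with the voxelwise relaxometry core; voxels
#' within `erosion_mm` of the vial wall are discarded to avoid the
#' susceptibility artifacts at the vial edges.
#'
#' @param vials a `vial_echo_set` (see [simulate_calibration_vials()])
#' @param erosion_mm radial margin removed from the vial edge
#' @param method fit method passed to the relaxometry core
#' @param noise_floor_sigma when positive, the Rician noise floor is
#'   subtracted before fitting (see [fit_r2()])
#' @return data.frame with vial_id, dose_Gy, R2_mean, R2_sd, n_voxels
#' @export
vial_roi_stats <- function(vials, erosion_mm = 1.5,
                           method = "loglinear_weighted",
                           noise_floor_sigma = 0) {
  stopifnot(inherits(vials, "vial_echo_set"), erosion_mm >= 0)
  rows <- lapply(vials$vials, function(v) {
    keep <- v$r_mm <= vials$vial_radius_mm - erosion_mm
    if (sum(keep) < 2)
      stop(sprintf("vial %d has fewer than 2 voxels after %.1f mm erosion",
                   v$vial_id, erosion_mm), call. = FALSE)
    f <- fit_r2_matrix(v$signal[keep, , drop = FALSE], vials$echo_times_ms,
                       method, noise_floor_sigma = noise_floor_sigma)
    data.frame(vial_id = v$vial_id, dose_Gy = v$dose_Gy,
               R2_mean = mean(f$r2), R2_sd = stats::sd(f$r2),
               n_voxels = sum(keep))
  })
  do.call(rbind, rows)
}

#' Fit the linear R2-dose calibration curve
#'
#' Weighted least squares of vial-mean R2 on dose (inverse-variance weights
#' from the per-vial R2 standard deviations when all are positive, ordinary
#' least squares otherwise). The Pearson correlation is computed on the vial
#' (dose, R2_mean) pairs, matching a 9-point calibration curve.
#'
#' @param per_vial data.frame from [vial_roi_stats()]
#' @param weighted use inverse-variance weights when available
#' @return a `calibration_curve` object
#' @export
fit_calibration <- function(per_vial, weighted = TRUE) {
  stopifnot(all(c("dose_Gy", "R2_mean", "R2_sd") %in% names(per_vial)))
  if (length(unique(per_vial$dose_Gy)) < 3)
    stop("need at least 3 distinct doses to fit a calibration curve",
         call. = FALSE)
  use_w <- weighted && all(is.finite(per_vial$R2_sd)) &&
    all(per_vial$R2_sd > 0)
  if (use_w) {
    # inverse-variance weighting with the stated uncertainty of each vial
    # mean (R2_sd^2 / n); standard errors from the GLS covariance without
    # dispersion rescaling, as the weights are actual variance estimates
    n <- if ("n_voxels" %in% names(per_vial)) per_vial$n_voxels else 1
    w <- n / per_vial$R2_sd^2
    X <- cbind(1, per_vial$dose_Gy)
    xtwx <- crossprod(X, w * X)
    beta <- solve(xtwx, crossprod(X, w * per_vial$R2_mean))
    covb <- solve(xtwx)
    est <- c(beta[1], beta[2])
    ses <- sqrt(diag(covb))
    resid <- per_vial$R2_mean - as.vector(X %*% beta)
  } else {
    # ordinary least squares with the textbook dispersion-based errors
    X <- cbind(1, per_vial$dose_Gy)
    xtxi <- solve(crossprod(X))
    beta <- xtxi %*% crossprod(X, per_vial$R2_mean)
    resid <- per_vial$R2_mean - as.vector(X %*% beta)
    s2 <- sum(resid^2) / (nrow(X) - 2)
    est <- as.vector(beta)
    ses <- sqrt(pmax(s2 * diag(xtxi), 0))
  }
  obj <- list(slope = unname(est[2]),
              intercept = unname(est[1]),
              slope_se = unname(ses[2]),
              intercept_se = unname(ses[1]),
              pearson_r = stats::cor(per_vial$dose_Gy, per_vial$R2_mean),
              residual_sigma_R2 = stats::sd(resid),
              dose_range_Gy = range(per_vial$dose_Gy),
              weighted = use_w,
              per_vial = per_vial)
  class(obj) <- "calibration_curve"
  obj
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> R2 = %.3f + %.3f * D  (r = %.4f, %d vials, %.1f-%.1f Gy)\n",
    x$intercept, x$slope, x$pearson_r, nrow(x$per_vial),
    x$dose_range_Gy[1], x$dose_range_Gy[2]))
  invisible(x)
}

#' Mean relative dose uncertainty of a calibration batch
#'
#' Per vial, the dose uncertainty is sigma_D = R2_sd / slope; the diagnostic
#' is the mean over vials of 100 * sigma_D / dose. Zero-dose vials cannot
#' contribute a relative uncertainty and are excluded with a warning.
#'
#' @param curve a `calibration_curve`
#' @return mean relative dose uncertainty in percent
#' @export
mean_uncertainty <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0)
    stop("mean_uncertainty requires a positive calibration slope",
         call. = FALSE)
  pv <- curve$per_vial
  if (any(pv$dose_Gy == 0)) {
    warning("zero-dose vial(s) excluded from mean uncertainty")
    pv <- pv[pv$dose_Gy > 0, ]
  }
  mean(100 * (pv$R2_sd / abs(curve$slope)) / pv$dose_Gy)
}

#' Dose resolution of the dosimeter
#'
#' The minimal dose separation distinguishable with confidence p:
#' `D_delta_p = k_p * sqrt(2) * sigma_D`, with `sigma_D = sigma_R2 / |slope|`
#' taken at `at_dose_Gy` (interpolated from the per-vial standard deviations)
#' or averaged over the calibration range when `at_dose_Gy` is NULL. The
#' coverage factor defaults to the two-sided Gaussian value
#' `k_p = qnorm((1 + p) / 2)` (1.96 at p = 0.95) and can be overridden to
#' reproduce other conventions.
#'
#' @param curve a `calibration_curve`
#' @param p confidence level in (0, 1)
#' @param at_dose_Gy dose level at which to evaluate, or NULL for the mean
#' @param k_p optional explicit coverage factor
#' @return dose resolution in Gy
#' @export
dose_resolution <- function(curve, p = 0.95, at_dose_Gy = NULL, k_p = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (is.null(k_p)) k_p <- stats::qnorm((1 + p) / 2)
  pv <- curve$per_vial
  sigma_r2 <- if (is.null(at_dose_Gy)) mean(pv$R2_sd)
  else stats::approx(pv$dose_Gy, pv$R2_sd, xout = at_dose_Gy, rule = 2)$y
  sigma_d <- sigma_r2 / abs(curve$slope)
  k_p * sqrt(2) * sigma_d
}
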