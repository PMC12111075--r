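#' Voxelwise R2 relaxometry
#'
#' Fits the mono-exponential decay S(TE) = S0 exp(-R2 TE) across the echo
#' train for every voxel. Two fitters are provided:
#'
#' * `loglinear_weighted` (default): weighted least squares on log(S) with
#'   weights S^2 — the delta-method variance of log-magnitude noise — which is
#'   near maximum-likelihood at high SNR and fully vectorized.
#' * `nonlinear`: Gauss-Newton least squares on the exponential itself,
#'   started from the log-linear estimate; retained for validation.
#'
#' Voxels with fewer than three positive echo signals, or whose first-echo
#' signal falls below `snr_floor * sigma` (when a background noise level
#' `sigma` is supplied), are masked out rather than fitted.
#'
#' @name r2_fitting
NULL

# core fitter on an n_voxel x n_echo signal matrix; returns r2, r2_sigma,
# s0 and the count of usable echoes per voxel. noise_floor_sigma > 0 applies
# the second-moment Rician correction sqrt(max(S^2 - 2 sigma^2, 0)) before
# fitting, removing the magnitude noise floor bias of late echoes.
fit_r2_matrix <- function(sig, te_ms, method = c("loglinear_weighted",
                                                 "nonlinear"),
                          noise_floor_sigma = 0) {
  method <- match.arg(method)
  if (noise_floor_sigma > 0)
    sig <- sqrt(pmax(sig^2 - 2 * noise_floor_sigma^2, 0))
  t_s <- te_ms / 1000
  ok <- is.finite(sig) & sig > 0
  npos <- rowSums(ok)
  y <- log(pmax(sig, .Machine$double.xmin))
  y[!ok] <- 0
  wls_pass <- function(w) {
    w[!ok] <- 0
    sw <- rowSums(w)
    swt <- w %*% t_s
    swt2 <- w %*% t_s^2
    swy <- rowSums(w * y)
    swty <- (w * y) %*% t_s
    den <- sw * swt2 - swt^2
    slope <- (sw * swty - swt * swy) / den
    inter <- (swy - slope * swt) / sw
    list(slope = slope, inter = inter, sw = sw, den = den, w = w)
  }
  # two-pass WLS: start from observed-signal weights S^2, then reweight with
  # the fitted signal (the delta-method weight), decoupling weights from noise
  p1 <- wls_pass(sig^2)
  fit1 <- matrix(p1$inter, nrow(sig), length(t_s)) +
    matrix(p1$slope, nrow(sig), length(t_s)) *
    matrix(t_s, nrow(sig), length(t_s), byrow = TRUE)
  w2 <- exp(2 * fit1)
  bad <- !is.finite(w2) | matrix(!is.finite(p1$slope), nrow(sig),
                                 length(t_s))
  w2[bad] <- (sig^2)[bad]
  p2 <- wls_pass(w2)
  slope <- p2$slope
  inter <- p2$inter
  sw <- p2$sw
  den <- p2$den
  w <- p2$w
  r2 <- as.vector(-slope)
  s0 <- exp(as.vector(inter))
  # residual-based dispersion for the delta-method covariance
  fit <- matrix(inter, nrow(sig), length(t_s)) +
    matrix(slope, nrow(sig), length(t_s)) * matrix(t_s, nrow(sig),
                                                   length(t_s), byrow = TRUE)
  res2 <- (y - fit)^2
  res2[!ok] <- 0
  s2 <- rowSums(w * res2) / pmax(npos - 2, 1)
  r2_sigma <- sqrt(pmax(s2 * sw / den, 0))
  r2_sigma <- as.vector(r2_sigma)

  if (method == "nonlinear") {
    keep <- npos >= 3 & is.finite(r2)
    S0 <- s0; R2 <- r2
    S0[!keep] <- NA; R2[!keep] <- NA
    okn <- is.finite(sig)
    v <- sig; v[!okn] <- 0
    tm <- matrix(t_s, nrow(sig), length(t_s), byrow = TRUE)
    for (it in 1:30) {
      m <- S0 * exp(-R2 * tm)
      m[!okn] <- 0
      e <- v - m
      j1 <- exp(-R2 * tm); j1[!okn] <- 0
      j2 <- -S0 * tm * j1
      a11 <- rowSums(j1 * j1); a12 <- rowSums(j1 * j2)
      a22 <- rowSums(j2 * j2)
      b1 <- rowSums(j1 * e); b2 <- rowSums(j2 * e)
      det <- a11 * a22 - a12^2
      d1 <- (a22 * b1 - a12 * b2) / det
      d2 <- (a11 * b2 - a12 * b1) / det
      d1[!is.finite(d1)] <- 0; d2[!is.finite(d2)] <- 0
      # damp steps that would flip the sign of S0 or explode R2
      step <- pmin(1, 0.5 * abs(S0) / pmax(abs(d1), 1e-12),
                   10 / pmax(abs(d2), 1e-12))
      S0 <- S0 + step * d1
      R2 <- R2 + step * d2
    }
    m <- S0 * exp(-R2 * tm); m[!okn] <- 0
    e <- v - m
    nobs <- rowSums(okn)
    s2n <- rowSums(e^2) / pmax(nobs - 2, 1)
    j1 <- exp(-R2 * tm); j1[!okn] <- 0
    j2 <- -S0 * tm * j1
    a11 <- rowSums(j1 * j1); a12 <- rowSums(j1 * j2); a22 <- rowSums(j2 * j2)
    det <- a11 * a22 - a12^2
    sig_n <- sqrt(pmax(s2n * a11 / det, 0))
    r2 <- as.vector(R2); r2_sigma <- as.vector(sig_n); s0 <- as.vector(S0)
  }
  list(r2 = r2, r2_sigma = r2_sigma, s0 = s0, npos = npos)
}

#' Fit an R2 map from a multi-echo volume
#'
#' @param echoes an [echo_series()] with at least 3 echoes
#' @param method "loglinear_weighted" (default) or "nonlinear"
#' @param snr_floor voxels whose first-echo signal is below
#'   `snr_floor * sigma` are masked (requires `sigma > 0` to act)
#' @param sigma background noise level (e.g. from [background_sigma()]);
#'   0 disables the SNR floor
#' @param noise_floor subtract the Rician noise floor
#'   (`sqrt(max(S^2 - 2 sigma^2, 0))`) before fitting; off by default since
#'   gel first-echo SNR is high and the late-echo bias is small
#' @return an [r2_map()]
#' @export
fit_r2 <- function(echoes, method = c("loglinear_weighted", "nonlinear"),
                   snr_floor = 5, sigma = 0, noise_floor = FALSE) {
  stopifnot(inherits(echoes, "echo_series"), snr_floor >= 0, sigma >= 0)
  method <- match.arg(method)
  sh <- dim(echoes$data)[1:3]
  ne <- dim(echoes$data)[4]
  sig <- matrix(echoes$data, prod(sh), ne)
  f <- fit_r2_matrix(sig, echoes$echo_times_ms, method,
                     noise_floor_sigma = if (noise_floor) sigma else 0)
  mask <- f$npos >= 3 & is.finite(f$r2) & is.finite(f$r2_sigma)
  if (sigma > 0) mask <- mask & (sig[, 1] >= snr_floor * sigma)
  r2 <- f$r2; r2[!mask] <- NA
  rs <- f$r2_sigma; rs[!mask] <- NA
  r2_map(array(r2, sh), array(rs, sh), array(mask, sh),
         spacing_mm = spacing_mm(echoes), origin_mm = origin_mm(echoes))
}

#' Estimate the background noise level from a signal-free region
#'
#' In magnitude MR a signal-free region is Rayleigh distributed with mean
#' sigma * sqrt(pi/2); the estimator inverts that relation using all echoes
#' of the region.
#'
#' @param echoes an [echo_series()]
#' @param region logical 3D array selecting background voxels
#' @param labels optional [label_volume()]; a warning is issued if the region
#'   overlaps non-outside voxels
#' @return scalar sigma estimate
#' @export
background_sigma <- function(echoes, region, labels = NULL) {
  stopifnot(identical(dim(region), dim(echoes$data)[1:3]))
  if (!any(region)) stop("background region is empty", call. = FALSE)
  if (!is.null(labels) &&
      any(labels$labels[region] != GEL_LABELS[["outside"]]))
    warning("background region overlaps phantom labels; sigma may be inflated")
  vals <- apply(echoes$data, 4, function(a) a[region])
  mean(vals) / sqrt(pi / 2)
}

#' Correct scanner spatial inhomogeneity using a reference scan
#'
#' The correction field is the reference R2 map, Gaussian-smoothed inside its
#' mask and normalized to unit mean: `c(x) = smooth(ref R2) / mean(ref R2)`.
#' The input map (and its uncertainty) is divided by `c(x)`. This removes any
#' multiplicative R2 bias shared between the study and reference scans.
#'
#' @param r2 an [r2_map()] to correct
#' @param reference an [r2_map()] of the uniform reference phantom, same grid;
#'   its mask must cover the mask of `r2`
#' @param smoothing_mm Gaussian smoothing width applied to the reference
#' @return the corrected [r2_map()], with attribute `correction_field`
#' @export
correct_inhomogeneity <- function(r2, reference, smoothing_mm = 20) {
  stop_if_grid_mismatch(r2, reference, "R2 map and reference")
  if (any(r2$mask & !reference$mask))
    stop("reference mask must cover the mask of the map being corrected",
         call. = FALSE)
  sm <- gaussian_blur_masked(reference$r2, rep(smoothing_mm, 3),
                             spacing_mm(r2), mask = reference$mask)
  cfield <- sm / mean(reference$r2[reference$mask])
  if (any(cfield[r2$mask] <= 0, na.rm = TRUE))
    stop("non-positive correction field inside the mask", call. = FALSE)
  out <- r2
  out$r2 <- r2$r2 / cfield
  out$r2_sigma <- r2$r2_sigma / cfield
  attr(out, "correction_field") <- cfield
  out
}
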