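#' Dose reconstruction and spatial alignment
#'
#' Converts corrected R2 maps to dose through the calibration curve, aligns
#' the measured frame to the planned frame with fiducial-based rigid
#' registration, resamples onto the comparison grid, and produces the
#' relative (normalized) distributions the gamma comparison consumes.
#'
#' @name dose_reconstruction
NULL

#' Convert an R2 map to absolute dose
#'
#' `D = (R2 - intercept) / slope` on masked voxels; negative doses are
#' clipped to zero (count recorded in attribute `n_clipped`).
#'
#' @param r2 an [r2_map()]
#' @param curve a `calibration_curve` with positive slope
#' @return a measured-kind [dose_volume()] (Gy; NA outside the mask)
#' @export
r2_to_dose <- function(r2, curve) {
  stopifnot(inherits(r2, "r2_map"), inherits(curve, "calibration_curve"))
  if (curve$slope <= 0)
    stop("calibration slope must be positive", call. = FALSE)
  d <- (r2$r2 - curve$intercept) / curve$slope
  d[!r2$mask] <- NA
  n_clip <- sum(d < 0, na.rm = TRUE)
  d[d < 0] <- 0
  out <- dose_volume(d, spacing_mm = spacing_mm(r2), origin_mm = origin_mm(r2),
                     kind = "measured")
  attr(out, "n_clipped") <- n_clip
  out
}

#' Labeled fiducial point set
#'
#' @param points_mm n x 3 matrix of marker coordinates (mm)
#' @param labels marker names (length n)
#' @param frame "measured" or "planned"
#' @return a `fiducial_set`
#' @export
fiducial_set <- function(points_mm, labels = NULL,
                         frame = c("measured", "planned")) {
  points_mm <- matrix(points_mm, ncol = 3)
  if (is.null(labels)) labels <- paste0("F", seq_len(nrow(points_mm)))
  stopifnot(nrow(points_mm) == length(labels))
  obj <- list(points_mm = points_mm, labels = as.character(labels),
              frame = match.arg(frame))
  class(obj) <- "fiducial_set"
  obj
}

check_not_collinear <- function(p) {
  if (nrow(p) < 3)
    stop("at least 3 fiducial pairs are required", call. = FALSE)
  c0 <- sweep(p, 2, colMeans(p))
  sv <- svd(c0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("fiducial points are collinear; the rotation is not identifiable",
         call. = FALSE)
  invisible(TRUE)
}

#' Rigid transform from matched fiducials (orthogonal Procrustes)
#'
#' Closed-form least-squares rotation + translation mapping the moving point
#' set onto the fixed one, with a proper rotation enforced (Kabsch SVD).
#'
#' @param moving,fixed `fiducial_set`s sharing the same labels
#' @return a `rigid_transform` (rotation `R`, translation `t`, `fre_mm`)
#' @export
rigid_from_fiducials <- function(moving, fixed) {
  stopifnot(inherits(moving, "fiducial_set"), inherits(fixed, "fiducial_set"))
  common <- intersect(moving$labels, fixed$labels)
  if (length(common) < 3)
    stop("at least 3 matched fiducial pairs are required", call. = FALSE)
  pm <- moving$points_mm[match(common, moving$labels), , drop = FALSE]
  pf <- fixed$points_mm[match(common, fixed$labels), , drop = FALSE]
  check_not_collinear(pm)
  check_not_collinear(pf)
  cm <- colMeans(pm); cf <- colMeans(pf)
  h <- t(sweep(pm, 2, cm)) %*% sweep(pf, 2, cf)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cf - as.vector(rot %*% cm)
  mapped <- sweep(pm %*% t(rot), 2, tr, "+")
  fre <- sqrt(mean(rowSums((pf - mapped)^2)))
  obj <- list(R = rot, t = tr, fre_mm = fre)
  class(obj) <- "rigid_transform"
  obj
}

#' Identity rigid transform
#' @return a `rigid_transform`
#' @export
identity_transform <- function() {
  obj <- list(R = diag(3), t = c(0, 0, 0), fre_mm = 0)
  class(obj) <- "rigid_transform"
  obj
}

#' Apply a rigid transform to points
#' @param tf a `rigid_transform`
#' @param points_mm n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(tf, points_mm) {
  points_mm <- matrix(points_mm, ncol = 3)
  sweep(points_mm %*% t(tf$R), 2, tf$t, "+")
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
invert_transform <- function(tf) {
  obj <- list(R = t(tf$R), t = as.vector(-t(tf$R) %*% tf$t),
              fre_mm = tf$fre_mm)
  class(obj) <- "rigid_transform"
  obj
}

as_target_grid <- function(target) {
  if (inherits(target, c("dose_volume", "r2_map", "label_volume",
                         "echo_series")))
    list(shape = grid_shape(target), spacing_mm = spacing_mm(target),
         origin_mm = origin_mm(target))
  else {
    stopifnot(all(c("shape", "spacing_mm", "origin_mm") %in% names(target)))
    target
  }
}

#' Resample a volume through a rigid transform onto a target grid
#'
#' The transform maps the source (moving) frame into the target (fixed)
#' frame; each target voxel centre is pulled back through the inverse and
#' sampled with trilinear interpolation. Points falling outside the source
#' grid become NA (invalid), never zero.
#'
#' @param volume a [dose_volume()] or [r2_map()]
#' @param transform a `rigid_transform` (moving -> fixed)
#' @param target a volume supplying the target grid, or a list with `shape`,
#'   `spacing_mm`, `origin_mm`
#' @return the resampled object on the target grid
#' @export
resample_to <- function(volume, transform, target) {
  tg <- as_target_grid(target)
  ax <- list(x = tg$origin_mm[1] + (seq_len(tg$shape[1]) - 1) * tg$spacing_mm[1],
             y = tg$origin_mm[2] + (seq_len(tg$shape[2]) - 1) * tg$spacing_mm[2],
             z = tg$origin_mm[3] + (seq_len(tg$shape[3]) - 1) * tg$spacing_mm[3])
  pts <- cbind(rep(ax$x, times = tg$shape[2] * tg$shape[3]),
               rep(rep(ax$y, each = tg$shape[1]), times = tg$shape[3]),
               rep(ax$z, each = tg$shape[1] * tg$shape[2]))
  src_pts <- apply_transform(invert_transform(transform), pts)
  idx <- world_to_index(src_pts, volume)
  if (inherits(volume, "dose_volume")) {
    vals <- interp_trilinear(volume$dose, idx)
    dose_volume(array(vals, tg$shape), spacing_mm = tg$spacing_mm,
                origin_mm = tg$origin_mm, kind = volume$kind,
                relative = volume$relative,
                normalization_value = volume$normalization_value)
  } else if (inherits(volume, "r2_map")) {
    r2v <- interp_trilinear(volume$r2, idx)
    sgv <- interp_trilinear(volume$r2_sigma, idx)
    mk <- interp_trilinear(array(as.numeric(volume$mask), dim(volume$mask)),
                           idx)
    mask <- !is.na(mk) & mk > 0.999 & !is.na(r2v)
    r2v[!mask] <- NA; sgv[!mask] <- NA
    r2_map(array(r2v, tg$shape), array(sgv, tg$shape), array(mask, tg$shape),
           spacing_mm = tg$spacing_mm, origin_mm = tg$origin_mm)
  } else stop("resample_to supports dose_volume and r2_map", call. = FALSE)
}

robust_max <- function(arr, mask, percentile, presmooth_mm = 0, spacing = NULL) {
  if (presmooth_mm > 0) {
    arr <- gaussian_blur_masked(arr, rep(presmooth_mm, 3), spacing,
                                mask = mask & !is.na(arr))
  }
  v <- arr[mask & !is.na(arr)]
  if (length(v) == 0) stop("empty mask in normalization", call. = FALSE)
  if (percentile >= 100) max(v) else
    as.numeric(stats::quantile(v, percentile / 100, names = FALSE))
}

#' Normalize measured and planned volumes to their own robust maxima
#'
#' Each volume is expressed in percent of its own robust maximum — the given
#' percentile of its masked voxels (100 reproduces the literal
#' maximum-normalization rule; the default 99.5 is stable against single
#' noisy voxels). Optionally the maximum is estimated on a margin-eroded mask
#' and/or on a Gaussian-presmoothed copy, to keep wall artifacts and noise
#' out of the normalization; the volumes themselves are never smoothed.
#'
#' @param measured,planned [dose_volume()]s on a common grid
#' @param percentile robust-maximum percentile (default 99.5)
#' @param measured_mask,planned_mask logical arrays of voxels eligible for
#'   normalization (default: finite voxels)
#' @param margin_mm erosion applied to the masks before taking the percentile
#' @param presmooth_mm Gaussian smoothing of the copy used for the percentile
#' @return list with relative `measured` and `planned` [dose_volume()]s (in
#'   percent, `normalization_value` set)
#' @export
normalize_relative <- function(measured, planned, percentile = 99.5,
                               measured_mask = NULL, planned_mask = NULL,
                               margin_mm = 0, presmooth_mm = 0) {
  stop_if_grid_mismatch(measured, planned, "measured and planned volumes")
  sp <- spacing_mm(measured)
  mk_m <- (measured_mask %||% !is.na(measured$dose)) & !is.na(measured$dose)
  mk_p <- (planned_mask %||% !is.na(planned$dose)) & !is.na(planned$dose)
  if (!any(mk_m) || !any(mk_p))
    stop("empty mask in normalization", call. = FALSE)
  nm_m <- erode_mask(mk_m, margin_mm, sp)
  nm_p <- erode_mask(mk_p, margin_mm, sp)
  if (!any(nm_m)) nm_m <- mk_m
  if (!any(nm_p)) nm_p <- mk_p
  norm_m <- robust_max(measured$dose, nm_m, percentile, presmooth_mm, sp)
  norm_p <- robust_max(planned$dose, nm_p, percentile, presmooth_mm, sp)
  rel <- function(vol, norm) {
    dose_volume(100 * vol$dose / norm, spacing_mm = sp,
                origin_mm = origin_mm(vol), kind = vol$kind, relative = TRUE,
                normalization_value = norm)
  }
  list(measured = rel(measured, norm_m), planned = rel(planned, norm_p))
}
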