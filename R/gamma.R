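#' 3D global gamma-index comparison
#'
#' The gamma index combines a dose-difference criterion (percent of a global
#' normalization dose) with a distance-to-agreement criterion (mm). For each
#' reference voxel above the low-dose threshold,
#' `gamma(r) = min_c sqrt(|c - r|^2 / dta^2 + (D_eval(c) - D_ref(r))^2 / dd^2)`
#' over candidate points `c` of the evaluated distribution within the search
#' radius, sampled at sub-voxel resolution by trilinear interpolation. A voxel
#' passes when gamma <= 1.
#'
#' @name gamma_analysis
NULL

#' Gamma criteria
#'
#' @param dose_diff_pct dose-difference criterion, percent of the
#'   normalization dose (global normalization)
#' @param dta_mm distance-to-agreement criterion (mm)
#' @param threshold_pct low-dose threshold: reference voxels below this
#'   percent of the normalization dose are excluded from all statistics
#' @param normalization "global_max" (robust max of the reference) or "value"
#' @param norm_value explicit normalization dose when `normalization="value"`
#' @param norm_percentile percentile defining the robust maximum (100 =
#'   literal maximum)
#' @param search_radius_mm cap on the spatial search (default 3 x dta)
#' @param interp_factor sub-voxel sampling density of the searched
#'   distribution (candidate step = spacing / interp_factor)
#' @param cap gamma values are clipped at this cap
#' @return a `gamma_criteria` object
#' @export
gamma_criteria <- function(dose_diff_pct = 3, dta_mm = 3, threshold_pct = 10,
                           normalization = c("global_max", "value"),
                           norm_value = NULL, norm_percentile = 100,
                           search_radius_mm = 3 * dta_mm, interp_factor = 10,
                           cap = Inf) {
  normalization <- match.arg(normalization)
  stopifnot(dose_diff_pct > 0, dta_mm > 0, threshold_pct > 0,
            threshold_pct < 100, search_radius_mm > 0, interp_factor >= 1)
  if (normalization == "value" && is.null(norm_value))
    stop("norm_value required when normalization = 'value'", call. = FALSE)
  obj <- list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
              threshold_pct = threshold_pct, normalization = normalization,
              norm_value = norm_value, norm_percentile = norm_percentile,
              search_radius_mm = search_radius_mm,
              interp_factor = as.integer(interp_factor), cap = cap)
  class(obj) <- "gamma_criteria"
  obj
}

#' Compute the 3D global gamma volume
#'
#' Gamma is evaluated at reference-grid voxels, searching the evaluated
#' distribution with a radially sorted candidate list and early termination
#' once the distance term alone exceeds the running minimum. Invalid (NA)
#' voxels of the evaluated volume never contribute candidates; reference
#' voxels below the threshold, outside `norm_mask`, or without any valid
#' candidate are excluded from all rates.
#'
#' @param reference the reference (planned) [dose_volume()]
#' @param evaluated the evaluated (measured) [dose_volume()], same grid
#' @param criteria a [gamma_criteria()]
#' @param norm_mask optional logical array restricting evaluation (e.g. the
#'   gel region, or a wall-margin-eroded copy of it)
#' @param slice_axis axis along which per-slice pass rates are reported
#' @return a `gamma_result`: gamma volume, masks, overall and per-slice rates
#' @export
gamma_3d <- function(reference, evaluated, criteria = gamma_criteria(),
                     norm_mask = NULL, slice_axis = c("y", "x", "z")) {
  stop_if_grid_mismatch(reference, evaluated, "reference and evaluated")
  slice_axis <- match.arg(slice_axis)
  if (isTRUE(reference$relative) != isTRUE(evaluated$relative))
    stop("reference and evaluated must both be relative or both absolute",
         call. = FALSE)
  ref <- reference$dose
  ev <- evaluated$dose
  d_norm <- if (criteria$normalization == "value") criteria$norm_value
  else robust_max(ref, !is.na(ref), criteria$norm_percentile)
  evaluate <- !is.na(ref) & ref >= criteria$threshold_pct / 100 * d_norm
  if (!is.null(norm_mask)) evaluate <- evaluate & norm_mask
  if (!any(evaluate)) stop("no voxels to evaluate", call. = FALSE)
  g <- cpp_gamma3d(as.numeric(ref), as.numeric(ev), as.integer(dim(ref)),
                   spacing_mm(reference), as.logical(evaluate),
                   criteria$dta_mm, criteria$dose_diff_pct / 100 * d_norm,
                   criteria$search_radius_mm, criteria$interp_factor,
                   criteria$cap)
  g <- array(g, dim(ref))
  eval_mask <- evaluate & !is.na(g)
  if (!any(eval_mask)) stop("evaluated mask is empty", call. = FALSE)
  pass <- eval_mask & (g <= 1)
  obj <- list(gamma = g, evaluated_mask = eval_mask, pass_mask = pass,
              pass_rate_overall = 100 * sum(pass) / sum(eval_mask),
              d_norm = d_norm, criteria = criteria, slice_axis = slice_axis)
  obj <- new_grid_attrs(obj, spacing_mm(reference), origin_mm(reference))
  class(obj) <- "gamma_result"
  obj$pass_rate_per_slice <- slice_pass_rates(obj, slice_axis)
  obj
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %.1f%%/%.1f mm/%g%% threshold: pass rate %.2f%% over %d voxels\n",
    x$criteria$dose_diff_pct, x$criteria$dta_mm, x$criteria$threshold_pct,
    x$pass_rate_overall, sum(x$evaluated_mask)))
  invisible(x)
}

#' Per-slice gamma pass rates
#'
#' @param result a `gamma_result`
#' @param axis "x", "y" or "z"
#' @return data.frame with slice index, evaluated voxel count and pass rate
#'   in percent (NA for slices with no evaluated voxels)
#' @export
slice_pass_rates <- function(result, axis = c("y", "x", "z")) {
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  other <- setdiff(1:3, a)
  n_eval <- apply(result$evaluated_mask, a, sum)
  n_pass <- apply(result$pass_mask, a, sum)
  rate <- ifelse(n_eval > 0, 100 * n_pass / n_eval, NA_real_)
  data.frame(slice = seq_along(rate), evaluated_voxels = n_eval,
             pass_rate_pct = rate)
}

#' Connected fail regions and gamma export
#'
#' Labels the 6-connected components of the fail mask (evaluated voxels with
#' gamma > 1) and summarizes each: size, centroid, and overlap with the metal
#' port's geometric shadow when a shadow weight is supplied. Optionally
#' writes the gamma volume and pass/fail mask as NIfTI.
#'
#' @param result a `gamma_result`
#' @param labels optional [label_volume()] used to report the tissue of each
#'   component centroid
#' @param shadow_weight optional 3D array (see [port_shadow_weight()])
#' @param out_dir optional directory for NIfTI export
#' @return list with `components` (data.frame) and `component_labels`
#'   (integer 3D array)
#' @export
export_fail_map <- function(result, labels = NULL, shadow_weight = NULL,
                            out_dir = NULL) {
  fail <- result$evaluated_mask & !result$pass_mask
  comp <- cpp_label_components(as.logical(fail), as.integer(dim(fail)))
  ncomp <- max(comp)
  sp <- spacing_mm(result); or <- origin_mm(result)
  rows <- if (ncomp == 0) {
    data.frame(component = integer(0), n_voxels = integer(0),
               volume_mm3 = numeric(0), centroid_x = numeric(0),
               centroid_y = numeric(0), centroid_z = numeric(0),
               shadow_overlap_frac = numeric(0))
  } else {
    do.call(rbind, lapply(seq_len(ncomp), function(k) {
      idx <- which(comp == k, arr.ind = TRUE)
      ctr <- or + (colMeans(idx) - 1) * sp
      overlap <- if (is.null(shadow_weight)) NA_real_
      else mean(shadow_weight[comp == k] > 0.5)
      data.frame(component = k, n_voxels = nrow(idx),
                 volume_mm3 = nrow(idx) * prod(sp),
                 centroid_x = ctr[1], centroid_y = ctr[2], centroid_z = ctr[3],
                 shadow_overlap_frac = overlap)
    }))
  }
  if (!is.null(rows) && nrow(rows) > 0)
    rows <- rows[order(-rows$n_voxels), ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gv <- dose_volume(result$gamma, sp, or, kind = "measured")
    write_volume(gv, file.path(out_dir, "gamma.nii.gz"))
    pm <- label_volume(array(as.integer(result$pass_mask), dim(fail)), sp, or)
    write_volume(pm, file.path(out_dir, "gamma_pass_mask.nii.gz"))
    utils::write.csv(rows, file.path(out_dir, "gamma_fail_components.csv"),
                     row.names = FALSE)
  }
  list(components = rows, component_labels = comp)
}
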