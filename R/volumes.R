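#' Volume containers
#'
#' Dense axis-aligned 3D/4D grids are the package's working currency. All
#' volumes carry `spacing_mm` (voxel pitch per axis) and `origin_mm` (world
#' coordinate of the centre of voxel `[1,1,1]`). World coordinates are in mm;
#' by convention the synthetic phantom's base centre sits at x = y = 0, z = 0.
#'
#' @name volumes
NULL

new_grid_attrs <- function(x, spacing_mm, origin_mm) {
  stopifnot(length(spacing_mm) == 3, all(spacing_mm > 0),
            length(origin_mm) == 3)
  attr(x, "spacing_mm") <- as.numeric(spacing_mm)
  attr(x, "origin_mm") <- as.numeric(origin_mm)
  x
}

#' Voxel spacing of a volume (mm)
#' @param x a volume object
#' @return numeric length-3 vector
#' @export
spacing_mm <- function(x) attr(x, "spacing_mm")

#' World coordinate of the first voxel centre (mm)
#' @param x a volume object
#' @return numeric length-3 vector
#' @export
origin_mm <- function(x) attr(x, "origin_mm")

grid_shape <- function(x) {
  d <- dim(x$data %||% x$dose %||% x$r2 %||% x$labels %||% x$gamma)
  d[1:3]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxel-centre coordinates along each axis
#' @param x a volume object
#' @return list with numeric vectors `x`, `y`, `z` (mm)
#' @export
grid_axes <- function(x) {
  sp <- spacing_mm(x); or <- origin_mm(x); sh <- grid_shape(x)
  list(x = or[1] + (seq_len(sh[1]) - 1) * sp[1],
       y = or[2] + (seq_len(sh[2]) - 1) * sp[2],
       z = or[3] + (seq_len(sh[3]) - 1) * sp[3])
}

#' Convert world coordinates (mm) to fractional 1-based voxel indices
#' @param points_mm n x 3 matrix of world coordinates
#' @param x a volume object supplying the grid
#' @return n x 3 matrix of fractional indices
#' @export
world_to_index <- function(points_mm, x) {
  points_mm <- matrix(points_mm, ncol = 3)
  sp <- spacing_mm(x); or <- origin_mm(x)
  sweep(sweep(points_mm, 2, or, "-"), 2, sp, "/") + 1
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_shape(a), grid_shape(b)) &&
    max(abs(spacing_mm(a) - spacing_mm(b))) < tol &&
    max(abs(origin_mm(a) - origin_mm(b))) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch: %s must share shape, spacing and origin", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Multi-echo magnitude MR volume
#'
#' @param data 4D array (x, y, z, echo) of magnitude signal, non-negative
#' @param echo_times_ms strictly increasing positive echo times
#' @param spacing_mm,origin_mm grid geometry
#' @return an `echo_series` object
#' @export
echo_series <- function(data, echo_times_ms, spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 4,
            dim(data)[4] == length(echo_times_ms),
            length(echo_times_ms) >= 3,
            all(diff(echo_times_ms) > 0), all(echo_times_ms > 0))
  if (min(data, na.rm = TRUE) < 0)
    stop("magnitude data must be non-negative", call. = FALSE)
  obj <- list(data = data, echo_times_ms = as.numeric(echo_times_ms))
  obj <- new_grid_attrs(obj, spacing_mm, origin_mm)
  class(obj) <- "echo_series"
  obj
}

#' Per-voxel transverse relaxation rate map
#'
#' @param r2 3D array of R2 (1/s)
#' @param r2_sigma 3D array of fit standard errors (1/s)
#' @param mask logical 3D array of valid fits
#' @param spacing_mm,origin_mm grid geometry
#' @return an `r2_map` object
#' @export
r2_map <- function(r2, r2_sigma, mask, spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(identical(dim(r2), dim(r2_sigma)), identical(dim(r2), dim(mask)))
  if (any(!is.finite(r2[mask])))
    stop("r2 must be finite inside the mask", call. = FALSE)
  if (any(r2_sigma[mask] < 0, na.rm = TRUE))
    stop("r2_sigma must be non-negative", call. = FALSE)
  obj <- list(r2 = r2, r2_sigma = r2_sigma, mask = mask)
  obj <- new_grid_attrs(obj, spacing_mm, origin_mm)
  class(obj) <- "r2_map"
  obj
}

#' Scalar 3D dose grid
#'
#' @param dose 3D array, Gy (absolute) or percent (relative); NA = invalid
#' @param spacing_mm,origin_mm grid geometry
#' @param kind "planned" or "measured"
#' @param relative logical; TRUE when dose is % of `normalization_value`
#' @param normalization_value Gy used for normalization when relative
#' @return a `dose_volume` object
#' @export
dose_volume <- function(dose, spacing_mm, origin_mm = c(0, 0, 0),
                        kind = c("planned", "measured"), relative = FALSE,
                        normalization_value = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(length(dim(dose)) == 3)
  if (isTRUE(relative) && !is.finite(normalization_value))
    stop("relative dose volumes must carry their normalization_value",
         call. = FALSE)
  obj <- list(dose = dose, kind = kind, relative = isTRUE(relative),
              normalization_value = normalization_value)
  obj <- new_grid_attrs(obj, spacing_mm, origin_mm)
  class(obj) <- "dose_volume"
  obj
}

#' Integer tissue-label volume
#'
#' Labels: 0 outside, 1 wall (glass), 2 gel, 3 water, 4 metal. Every voxel
#' carries exactly one label.
#'
#' @param labels 3D integer array with values in 0:4
#' @param spacing_mm,origin_mm grid geometry
#' @return a `label_volume` object
#' @export
label_volume <- function(labels, spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3, all(labels %in% 0:4))
  obj <- list(labels = labels)
  obj <- new_grid_attrs(obj, spacing_mm, origin_mm)
  class(obj) <- "label_volume"
  obj
}

#' Label codes used by `label_volume`
#' @format named integer vector
#' @export
GEL_LABELS <- c(outside = 0L, wall = 1L, gel = 2L, water = 3L, metal = 4L)

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<echo_series> %d x %d x %d voxels, %d echoes (TE %s ms)\n",
              d[1], d[2], d[3], d[4],
              paste(x$echo_times_ms, collapse = ", ")))
  invisible(x)
}

#' @export
print.dose_volume <- function(x, ...) {
  d <- dim(x$dose)
  cat(sprintf("<dose_volume:%s%s> %d x %d x %d, range [%.3g, %.3g]\n",
              x$kind, if (x$relative) " (relative %)" else " (Gy)",
              d[1], d[2], d[3],
              min(x$dose, na.rm = TRUE), max(x$dose, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.r2_map <- function(x, ...) {
  d <- dim(x$r2)
  cat(sprintf("<r2_map> %d x %d x %d, %d valid voxels, median R2 %.3g 1/s\n",
              d[1], d[2], d[3], sum(x$mask), median(x$r2[x$mask])))
  invisible(x)
}

#' Trilinear interpolation of a 3D array at fractional voxel indices
#'
#' @param arr 3D numeric array
#' @param idx n x 3 matrix of fractional 1-based indices
#' @return numeric vector; NA outside the grid or where a corner is NA
#' @export
interp_trilinear <- function(arr, idx) {
  idx <- matrix(idx, ncol = 3)
  cpp_trilinear(as.numeric(arr), as.integer(dim(arr)), idx)
}

gaussian_blur_masked <- function(arr, sigma_mm, spacing, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(arr))
  sig_vox <- rep_len(sigma_mm, 3) / spacing
  cpp_gaussian_blur3(as.numeric(arr), as.integer(dim(arr)), sig_vox,
                     as.logical(mask))
}

#' Distance (mm) from every voxel to the nearest feature voxel
#' @param feature logical 3D array
#' @param spacing_mm voxel pitch (mm)
#' @return 3D numeric array of Euclidean distances
#' @export
distance_to <- function(feature, spacing_mm) {
  cpp_edt3(as.logical(feature), as.integer(dim(feature)),
           as.numeric(spacing_mm))
}

#' Erode a logical mask by a physical margin
#' @param mask logical 3D array
#' @param margin_mm erosion depth (mm)
#' @param spacing_mm voxel pitch (mm)
#' @return logical 3D array
#' @export
erode_mask <- function(mask, margin_mm, spacing_mm) {
  if (margin_mm <= 0) return(mask)
  d <- distance_to(!mask, spacing_mm)
  mask & (d > margin_mm)
}

#' Write a volume to NIfTI
#'
#' Stores the 3D (or 4D, for echo series) array with voxel dimensions taken
#' from the object's grid. Masked/invalid voxels are written as NaN (or 0 for
#' integer labels).
#'
#' @param x an `echo_series`, `dose_volume`, `r2_map` or `label_volume`
#' @param path output file (.nii or .nii.gz)
#' @return `path`, invisibly
#' @export
write_volume <- function(x, path) {
  arr <- switch(class(x)[1],
                echo_series = x$data,
                dose_volume = x$dose,
                r2_map = x$r2,
                label_volume = x$labels,
                stop("unsupported volume type", call. = FALSE))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(spacing_mm(x),
                                   if (length(dim(arr)) == 4) 1 else NULL))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file into a `dose_volume`
#' @param path NIfTI file
#' @param kind "planned" or "measured"
#' @param origin_mm world coordinate of the first voxel centre
#' @return a `dose_volume`
#' @export
read_dose_volume <- function(path, kind = c("planned", "measured"),
                             origin_mm = c(0, 0, 0)) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  dose_volume(array(as.numeric(img), dim(img)[1:3]), spacing_mm = sp,
              origin_mm = origin_mm, kind = kind)
}
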