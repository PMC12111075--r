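#' Dose-profile extraction and deficit statistics
#'
#' Profiles are trilinear samples of a dose volume along a straight segment.
#' The deficit statistic compares a measured against a planned profile over a
#' stated region and underlies the quantification of the metal-port
#' underdose: matched profiles through the port shadow and through the
#' mirror-symmetric region without the port.
#'
#' @name profile_analysis
NULL

#' Sample a dose volume along a line segment
#'
#' @param volume a [dose_volume()]
#' @param start_mm,end_mm segment endpoints (world mm)
#' @param n_samples number of equally spaced samples (>= 2)
#' @return data.frame with position_mm (distance from start), x/y/z (mm) and
#'   `value` (NA where the volume is invalid)
#' @export
extract_profile <- function(volume, start_mm, end_mm, n_samples = 100) {
  stopifnot(n_samples >= 2)
  f <- seq(0, 1, length.out = n_samples)
  pts <- cbind(start_mm[1] + f * (end_mm[1] - start_mm[1]),
               start_mm[2] + f * (end_mm[2] - start_mm[2]),
               start_mm[3] + f * (end_mm[3] - start_mm[3]))
  vals <- interp_trilinear(volume$dose, world_to_index(pts, volume))
  if (all(is.na(vals)))
    stop("profile line lies fully outside the valid volume", call. = FALSE)
  data.frame(position_mm = f * sqrt(sum((end_mm - start_mm)^2)),
             x = pts[, 1], y = pts[, 2], z = pts[, 3], value = vals)
}

#' Matched planned/measured profile pair
#'
#' @param positions_mm strictly increasing sample positions
#' @param planned,measured profile values (same length; percent or Gy)
#' @param region logical vector (same length) or numeric `c(lo, hi)` interval
#'   of positions selecting the deficit region
#' @return a `profile_pair`
#' @export
profile_pair <- function(positions_mm, planned, measured, region = NULL) {
  stopifnot(length(positions_mm) == length(planned),
            length(planned) == length(measured),
            all(diff(positions_mm) > 0))
  if (is.null(region)) region <- rep(TRUE, length(planned))
  if (is.numeric(region) && length(region) == 2) {
    if (region[1] < min(positions_mm) - 1e-9 ||
        region[2] > max(positions_mm) + 1e-9)
      stop("region interval must lie within the sampled positions",
           call. = FALSE)
    region <- positions_mm >= region[1] & positions_mm <= region[2]
  }
  stopifnot(is.logical(region), length(region) == length(planned))
  obj <- list(positions_mm = positions_mm, planned = planned,
              measured = measured, region = region)
  class(obj) <- "profile_pair"
  obj
}

#' Mean and SD of the pointwise measured-vs-planned deficit
#'
#' Over the pair's region, the pointwise deficit is
#' `d_i = 100 * (planned_i - measured_i) / planned_i`; the statistic is its
#' mean and standard deviation (percent). Positive values are underdoses.
#'
#' @param pair a [profile_pair()]
#' @return named numeric vector `c(mean_pct, sd_pct)`
#' @export
profile_reduction <- function(pair) {
  stopifnot(inherits(pair, "profile_pair"))
  sel <- pair$region & !is.na(pair$planned) & !is.na(pair$measured)
  if (sum(sel) < 3)
    stop("deficit region must contain at least 3 valid samples",
         call. = FALSE)
  if (any(pair$planned[sel] == 0))
    stop("planned profile is zero inside the deficit region", call. = FALSE)
  d <- 100 * (pair$planned[sel] - pair$measured[sel]) / pair$planned[sel]
  c(mean_pct = mean(d), sd_pct = stats::sd(d))
}

#' Metal-attributed mean dose reduction
#'
#' Pairs matched profile orientations with and without the metal port,
#' differences their mean deficits, and returns the average difference with a
#' propagated uncertainty (root-sum-square of the per-profile SDs divided by
#' the number of pairs).
#'
#' @param with_metal list of `c(mean_pct, sd_pct)` for profiles crossing the
#'   port shadow
#' @param without list of matched no-metal profile statistics (same length
#'   and order)
#' @return named numeric vector `c(mean_pct, sd_pct)`
#' @export
metal_attributed_reduction <- function(with_metal, without) {
  if (length(with_metal) == 0 || length(without) == 0)
    stop("both profile lists must be nonempty", call. = FALSE)
  if (length(with_metal) != length(without))
    stop("with-metal and without-metal profile lists must match in length",
         call. = FALSE)
  wm <- do.call(rbind, lapply(with_metal, function(x) x[1:2]))
  wo <- do.call(rbind, lapply(without, function(x) x[1:2]))
  diffs <- wm[, 1] - wo[, 1]
  k <- length(diffs)
  sd_prop <- sqrt(sum(wm[, 2]^2 + wo[, 2]^2)) / k
  c(mean_pct = mean(diffs), sd_pct = sd_prop)
}
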