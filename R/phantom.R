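#' Synthetic breast-phantom specification
#'
#' Describes a dome-shaped (hemiellipsoidal) glass phantom filled with polymer
#' gel, with a water-filled inner dome (the prosthesis space) carved into its
#' base and a metal-port disk fixed inside the inner dome. Default dimensions
#' reconstruct a ~0.28 L gel shell inside a 140 mm footprint. The port is a
#' disk (diameter x thickness in mm) whose axis is vertical (z).
#'
#' @param grid_shape voxel counts (x, y, z)
#' @param spacing_mm voxel pitch (mm)
#' @param origin_mm world coordinate of the first voxel centre
#' @param outer_shell_mm semi-axes of the outer glass surface (a, b, c)
#' @param inner_dome_mm semi-axes of the water cavity (a, b, c)
#' @param wall_thickness_mm glass wall thickness
#' @param port_center_mm centre of the metal-port disk (mm, world)
#' @param port_diameter_mm,port_thickness_mm port disk dimensions
#' @param gel_volume_target_L nominal gel fill volume
#' @return a `phantom_spec` object
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         spacing_mm = c(1.25, 1.25, 0.75),
                         origin_mm = NULL,
                         outer_shell_mm = c(56, 56, 64),
                         inner_dome_mm = c(35, 35, 28),
                         wall_thickness_mm = 2,
                         port_center_mm = c(0, -14, 20),
                         port_diameter_mm = 17.9,
                         port_thickness_mm = 3.9,
                         gel_volume_target_L = 0.282) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            all(outer_shell_mm > 0), all(inner_dome_mm > 0),
            wall_thickness_mm > 0, port_diameter_mm >= 0,
            port_thickness_mm >= 0)
  if (is.null(origin_mm)) {
    # centre the grid on x = y = 0 with the base plane just below z = 0
    ext <- grid_shape * spacing_mm
    origin_mm <- c(-ext[1] / 2 + spacing_mm[1] / 2,
                   -ext[2] / 2 + spacing_mm[2] / 2,
                   -2 + spacing_mm[3] / 2)
  }
  obj <- list(grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              origin_mm = as.numeric(origin_mm),
              outer_shell_mm = outer_shell_mm,
              inner_dome_mm = inner_dome_mm,
              wall_thickness_mm = wall_thickness_mm,
              port_center_mm = port_center_mm,
              port_diameter_mm = port_diameter_mm,
              port_thickness_mm = port_thickness_mm,
              gel_volume_target_L = gel_volume_target_L)
  class(obj) <- "phantom_spec"
  obj
}

spec_axes <- function(spec) {
  list(x = spec$origin_mm[1] + (seq_len(spec$grid_shape[1]) - 1) * spec$spacing_mm[1],
       y = spec$origin_mm[2] + (seq_len(spec$grid_shape[2]) - 1) * spec$spacing_mm[2],
       z = spec$origin_mm[3] + (seq_len(spec$grid_shape[3]) - 1) * spec$spacing_mm[3])
}

# squared scaled radius of an axis-aligned ellipsoid, evaluated on the grid;
# returns a 3D array of (x/a)^2 + (y/b)^2 + ((z-z0)/c)^2
ellipsoid_u2 <- function(ax, semi, z0 = 0) {
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  ux <- (ax$x / semi[1])^2
  uy <- (ax$y / semi[2])^2
  uz <- ((ax$z - z0) / semi[3])^2
  array(rep(ux, times = ny * nz), c(nx, ny, nz)) +
    array(rep(rep(uy, each = nx), times = nz), c(nx, ny, nz)) +
    array(rep(uz, each = nx * ny), c(nx, ny, nz))
}

#' Voxelize the phantom geometry into tissue labels
#'
#' Partitions the grid into outside / wall / gel / water / metal. The gel is
#' the shell between the outer glass and the inner dome; the water cavity is
#' the inner dome interior; the metal port disk sits inside the water cavity
#' against the dome surface.
#'
#' @param spec a [phantom_spec()]
#' @return a [label_volume()] with attribute `gel_volume_L`
#' @export
make_phantom_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- spec_axes(spec)
  w <- spec$wall_thickness_mm
  lab <- array(GEL_LABELS[["outside"]], spec$grid_shape)

  zpos <- rep(ax$z >= 0, each = prod(spec$grid_shape[1:2]))
  inside_glass <- (ellipsoid_u2(ax, spec$outer_shell_mm) <= 1) & zpos
  lab[inside_glass] <- GEL_LABELS[["wall"]]

  cavity_semi <- spec$outer_shell_mm - w
  zin <- rep(ax$z >= w, each = prod(spec$grid_shape[1:2]))
  in_cavity <- (ellipsoid_u2(ax, cavity_semi) <= 1) & zin
  lab[in_cavity] <- GEL_LABELS[["gel"]]

  dome_wall_semi <- spec$inner_dome_mm + w
  in_dome_wall <- (ellipsoid_u2(ax, dome_wall_semi, z0 = w) <= 1) & inside_glass
  lab[in_dome_wall] <- GEL_LABELS[["wall"]]
  in_water <- (ellipsoid_u2(ax, spec$inner_dome_mm, z0 = w) <= 1) & zin
  lab[in_water] <- GEL_LABELS[["water"]]

  if (spec$port_diameter_mm > 0 && spec$port_thickness_mm > 0) {
    pc <- spec$port_center_mm
    r <- spec$port_diameter_mm / 2
    t2 <- spec$port_thickness_mm / 2
    lo <- pc - c(r, r, t2); hi <- pc + c(r, r, t2)
    gmin <- spec$origin_mm - spec$spacing_mm / 2
    gmax <- spec$origin_mm + (spec$grid_shape - 0.5) * spec$spacing_mm
    if (any(lo < gmin) || any(hi > gmax)) {
      bad <- which(lo < gmin | hi > gmax)[1]
      stop(sprintf(
        "metal port extends outside the grid along axis %s (port spans [%.1f, %.1f] mm)",
        c("x", "y", "z")[bad], lo[bad], hi[bad]), call. = FALSE)
    }
    nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
    r2a <- array(rep((ax$x - pc[1])^2, times = ny * nz), spec$grid_shape) +
      array(rep(rep((ax$y - pc[2])^2, each = nx), times = nz), spec$grid_shape)
    zslab <- rep(abs(ax$z - pc[3]) <= t2, each = nx * ny)
    lab[(r2a <= r^2) & zslab] <- GEL_LABELS[["metal"]]
  }

  out <- label_volume(lab, spacing_mm = spec$spacing_mm,
                      origin_mm = spec$origin_mm)
  attr(out, "gel_volume_L") <-
    sum(lab == GEL_LABELS[["gel"]]) * prod(spec$spacing_mm) / 1e6
  out
}

#' Beam model for the analytic two-tangent surrogate plan
#'
#' A parallel-beam surrogate for a pair of opposed tangential 6 MV fields:
#' per-beam dose = prescription/2 x buildup x exp(-mu_eff * depth) x wedge
#' gradient x aperture, renormalized so that the total at the isocenter equals
#' the prescription. Gantry 90 deg enters from +x, 270 deg from -x.
#'
#' @param gantry_angles_deg two opposed angles (must differ by 180)
#' @param field_size_cm field width (y) and length (z) in cm
#' @param wedge_angle_deg linear across-field gradient tilt (deg), along z
#' @param prescription_Gy dose at the isocenter
#' @param mu_eff_per_cm effective attenuation of the 6 MV surrogate beam
#' @param isocenter_mm plan isocenter (world mm)
#' @param bolus_mm tissue-equivalent bolus thickness added along the beam axis
#' @param buildup_mm exponential dose-buildup length; 0 disables buildup
#' @return a `beam_model` object
#' @export
beam_model <- function(gantry_angles_deg = c(90, 270),
                       field_size_cm = c(19, 20),
                       wedge_angle_deg = 15,
                       prescription_Gy = 3.0,
                       mu_eff_per_cm = 0.05,
                       isocenter_mm = c(0, 0, 40),
                       bolus_mm = 10,
                       buildup_mm = 10) {
  stopifnot(length(gantry_angles_deg) == 2, prescription_Gy > 0,
            all(field_size_cm > 0), mu_eff_per_cm >= 0,
            bolus_mm >= 0, buildup_mm >= 0)
  if (abs(abs(diff(gantry_angles_deg %% 360)) - 180) > 1e-9)
    stop("the two beams must be opposed (gantry angles differing by 180 deg)",
         call. = FALSE)
  obj <- list(gantry_angles_deg = gantry_angles_deg,
              field_size_cm = field_size_cm,
              wedge_angle_deg = wedge_angle_deg,
              prescription_Gy = prescription_Gy,
              mu_eff_per_cm = mu_eff_per_cm,
              isocenter_mm = isocenter_mm,
              bolus_mm = bolus_mm,
              buildup_mm = buildup_mm)
  class(obj) <- "beam_model"
  obj
}

#' Measured-vs-planned perturbation model
#'
#' Encodes the two dose deficits the gel measurement exhibits relative to the
#' plan: a near-wall polymerization-inhibition deficit (full within an oxygen
#' penetration plateau, then decaying exponentially with distance from the
#' glass), and an additional deficit confined to the geometric shadow of the
#' metal port along the beam axis. `shadow_deficit_frac` is the *total*
#' fractional deficit inside the shadow where the wall effect is fully
#' expressed.
#'
#' @param wall_deficit_frac fractional near-wall deficit (default 0.045)
#' @param wall_range_mm exponential decay length beyond the plateau
#' @param wall_plateau_mm depth over which the wall deficit is fully expressed
#' @param shadow_deficit_frac total fractional deficit in the port shadow
#' @param shadow_softening_mm Gaussian edge blur of the shadow
#' @return a `perturbation_model` object
#' @export
perturbation_model <- function(wall_deficit_frac = 0.045,
                               wall_range_mm = 1.5,
                               wall_plateau_mm = 10,
                               shadow_deficit_frac = 0.098,
                               shadow_softening_mm = 0.5) {
  stopifnot(wall_deficit_frac >= 0, wall_deficit_frac < 1,
            shadow_deficit_frac >= 0, shadow_deficit_frac < 1,
            wall_range_mm > 0, wall_plateau_mm >= 0, shadow_softening_mm >= 0)
  if (shadow_deficit_frac < wall_deficit_frac)
    stop("shadow_deficit_frac must be >= wall_deficit_frac", call. = FALSE)
  obj <- list(wall_deficit_frac = wall_deficit_frac,
              wall_range_mm = wall_range_mm,
              wall_plateau_mm = wall_plateau_mm,
              shadow_deficit_frac = shadow_deficit_frac,
              shadow_softening_mm = shadow_softening_mm)
  class(obj) <- "perturbation_model"
  obj
}

beam_entry_sign <- function(angle_deg) {
  a <- angle_deg %% 360
  if (abs(a - 90) < 1e-9) +1
  else if (abs(a - 270) < 1e-9) -1
  else stop("only lateral gantry angles (90/270 deg) are supported by the surrogate",
            call. = FALSE)
}

#' Analytic surrogate planned dose
#'
#' @param spec a [phantom_spec()]
#' @param beams a [beam_model()]
#' @return a planned [dose_volume()] (Gy)
#' @export
planned_dose <- function(spec, beams) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(beams, "beam_model"))
  ax <- spec_axes(spec)
  iso <- beams$isocenter_mm
  gmin <- spec$origin_mm - spec$spacing_mm / 2
  gmax <- spec$origin_mm + (spec$grid_shape - 0.5) * spec$spacing_mm
  if (any(iso < gmin) || any(iso > gmax))
    stop("isocenter lies outside the grid", call. = FALSE)
  fs_mm <- beams$field_size_cm * 10  # aperture is centred on the isocenter

  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  mu <- beams$mu_eff_per_cm / 10  # per mm
  a <- spec$outer_shell_mm
  # entry x of the outer surface for each (y, z) ray (parallel beam along x)
  uy <- (ax$y / a[2])^2
  uz <- (ax$z / a[3])^2
  s2 <- outer(uy, uz, function(p, q) 1 - p - q)
  s2[s2 < 0] <- NA  # ray misses the phantom
  zneg <- ax$z < 0
  s2[, zneg] <- NA
  xe <- a[1] * sqrt(s2)            # ny x nz matrix

  aperture_yz <- outer(abs(ax$y - iso[2]) <= fs_mm[1] / 2,
                       abs(ax$z - iso[3]) <= fs_mm[2] / 2, "&")
  wedge <- if (beams$wedge_angle_deg != 0) {
    wl <- 120  # mm lever arm of the linear wedge gradient
    pmax(0.1, 1 + tan(beams$wedge_angle_deg * pi / 180) * (ax$z - iso[3]) / wl)
  } else rep(1, nz)
  wedge_yz <- matrix(rep(wedge, each = ny), ny, nz)

  total <- array(0, spec$grid_shape)
  for (ang in beams$gantry_angles_deg) {
    sgn <- beam_entry_sign(ang)
    # depth of each voxel along this beam, including bolus
    entry <- if (sgn > 0) xe + beams$bolus_mm else -(xe + beams$bolus_mm)
    # depth = (entry - x) * sgn
    depth <- array(NA_real_, spec$grid_shape)
    em <- array(rep(as.numeric(entry), each = nx), spec$grid_shape)
    xs <- array(rep(ax$x, times = ny * nz), spec$grid_shape)
    depth <- (em - xs) * sgn
    depth[depth < 0] <- NA
    b <- if (beams$buildup_mm > 0) 1 - exp(-depth / beams$buildup_mm) else 1
    beam <- 0.5 * beams$prescription_Gy * b * exp(-mu * depth)
    ap <- array(rep(as.numeric(aperture_yz * wedge_yz), each = nx),
                spec$grid_shape)
    beam <- beam * ap
    beam[is.na(beam)] <- 0
    total <- total + beam
  }
  vol <- dose_volume(total, spacing_mm = spec$spacing_mm,
                     origin_mm = spec$origin_mm, kind = "planned")
  iso_dose <- interp_trilinear(total, world_to_index(iso, vol))
  if (!is.finite(iso_dose) || iso_dose <= 0)
    stop("surrogate dose vanishes at the isocenter; check beam geometry",
         call. = FALSE)
  vol$dose <- total * (beams$prescription_Gy / iso_dose)
  vol
}

#' Geometric shadow of the metal port along the beam axis
#'
#' With two opposed lateral beams the union of the two shadows is the full
#' x-column through the port's (y, z) footprint.
#'
#' @param spec a [phantom_spec()]
#' @param softening_mm Gaussian edge blur (mm); 0 for the crisp indicator
#' @return 3D array in `[0, 1]` (shadow weight), on the spec grid
#' @export
port_shadow_weight <- function(spec, softening_mm = 0) {
  ax <- spec_axes(spec)
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  pc <- spec$port_center_mm
  r <- spec$port_diameter_mm / 2
  t2 <- spec$port_thickness_mm / 2
  if (r <= 0 || t2 <= 0) return(array(0, spec$grid_shape))
  foot <- outer(abs(ax$y - pc[2]) <= r, abs(ax$z - pc[3]) <= t2, "&")
  ind <- array(rep(as.numeric(foot), each = nx), spec$grid_shape)
  if (softening_mm > 0) {
    ind <- gaussian_blur_masked(ind, c(0, softening_mm, softening_mm),
                                spec$spacing_mm)
    ind <- array(ind, spec$grid_shape)
  }
  ind
}

#' Delivered (measured-truth) dose
#'
#' Applies the perturbation model to the planned dose on gel voxels:
#' `delivered = planned * (1 - wall(d)) * (1 - extra * shadow_weight)`, with
#' `extra = 1 - (1 - shadow_deficit_frac) / (1 - wall_deficit_frac)` so that
#' the total deficit deep in the shadow (where the wall effect is fully
#' expressed) equals `shadow_deficit_frac` exactly.
#'
#' @param planned planned [dose_volume()]
#' @param labels matching [label_volume()]
#' @param spec the [phantom_spec()] used to build `labels`
#' @param perturb a [perturbation_model()]
#' @return a measured-kind [dose_volume()] with attribute `shadow_weight`
#' @export
delivered_dose <- function(planned, labels, spec, perturb) {
  stop_if_grid_mismatch(planned, labels, "planned dose and labels")
  gel <- labels$labels == GEL_LABELS[["gel"]]
  dwall <- distance_to(labels$labels == GEL_LABELS[["wall"]],
                       spacing_mm(labels))
  w <- perturb$wall_deficit_frac *
    ifelse(dwall <= perturb$wall_plateau_mm, 1,
           exp(-(dwall - perturb$wall_plateau_mm) / perturb$wall_range_mm))
  extra_max <- if (perturb$wall_deficit_frac < 1)
    1 - (1 - perturb$shadow_deficit_frac) / (1 - perturb$wall_deficit_frac)
  else 0
  shadow <- port_shadow_weight(spec, perturb$shadow_softening_mm)
  fac <- (1 - w) * (1 - extra_max * shadow)
  dose <- planned$dose
  dose[gel] <- dose[gel] * fac[gel]
  out <- dose_volume(dose, spacing_mm = spacing_mm(planned),
                     origin_mm = origin_mm(planned), kind = "measured")
  attr(out, "shadow_weight") <- shadow
  out
}
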