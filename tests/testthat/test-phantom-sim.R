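test_that("labels partition the grid and reproduce the gel fill volume", {
  spec <- phantom_spec()
  lab <- make_phantom_labels(spec)
  expect_true(all(lab$labels %in% 0:4))
  expect_equal(sum(table(lab$labels)), prod(spec$grid_shape))
  # voxelized gel volume close to the nominal 0.282 L fill
  expect_lt(abs(attr(lab, "gel_volume_L") - 0.282) / 0.282, 0.05)
  # all five tissue classes are present
  expect_setequal(sort(unique(as.vector(lab$labels))), 0:4)
})

test_that("degenerate port yields no metal and out-of-grid port errors", {
  spec0 <- small_spec()
  spec0$port_diameter_mm <- 0
  lab0 <- make_phantom_labels(spec0)
  expect_equal(sum(lab0$labels == GEL_LABELS[["metal"]]), 0)

  spec_bad <- small_spec()
  spec_bad$port_center_mm <- c(0, -14, 200)
  expect_error(make_phantom_labels(spec_bad), "axis z")
})

test_that("voxelized gel volume matches the closed-form shell volume", {
  spec <- phantom_spec(grid_shape = c(120, 120, 70),
                       spacing_mm = c(1, 1, 1),
                       port_diameter_mm = 0)
  lab <- make_phantom_labels(spec)
  closed <- gel_volume_closed_form(spec)
  expect_lt(abs(attr(lab, "gel_volume_L") - closed) / closed, 0.02)
})

test_that("planned dose is normalized to the prescription at the isocenter", {
  spec <- small_spec()
  beams <- beam_model()
  pl <- planned_dose(spec, beams)
  iso <- interp_trilinear(pl$dose, world_to_index(beams$isocenter_mm, pl))
  expect_equal(iso, beams$prescription_Gy, tolerance = 1e-12)
})

test_that("no attenuation and no wedge give a uniform dose in the phantom", {
  spec <- small_spec()
  b0 <- beam_model(mu_eff_per_cm = 0, wedge_angle_deg = 0, buildup_mm = 0)
  pl <- planned_dose(spec, b0)
  lab <- make_phantom_labels(spec)
  inside <- lab$labels != GEL_LABELS[["outside"]]
  expect_equal(max(pl$dose[inside]) - min(pl$dose[inside]), 0,
               tolerance = 1e-12)
})

test_that("opposed beams give a mirror-symmetric dose on the symmetric phantom", {
  spec <- small_spec()
  for (wedge in c(0, 15)) {
    pl <- planned_dose(spec, beam_model(wedge_angle_deg = wedge))
    asym <- max(abs(pl$dose - pl$dose[rev(seq_len(dim(pl$dose)[1])), , ]))
    expect_lt(asym, 0.01 * 3)
  }
})

test_that("isocenter outside the grid is rejected", {
  expect_error(planned_dose(small_spec(),
                            beam_model(isocenter_mm = c(0, 0, 500))),
               "isocenter")
})

test_that("zero perturbation leaves the delivered dose identical", {
  spec <- small_spec()
  lab <- make_phantom_labels(spec)
  pl <- planned_dose(spec, beam_model())
  p0 <- perturbation_model(wall_deficit_frac = 0, shadow_deficit_frac = 0)
  del <- delivered_dose(pl, lab, spec, p0)
  expect_identical(del$dose, pl$dose)
})

test_that("the total deficit deep in the shadow equals the shadow fraction", {
  spec <- phantom_spec()
  lab <- make_phantom_labels(spec)
  pl <- planned_dose(spec, beam_model())
  perturb <- perturbation_model()
  del <- delivered_dose(pl, lab, spec, perturb)
  ax <- grid_axes(pl)
  pc <- spec$port_center_mm
  # gel voxel in the shadow core, within the wall-deficit plateau
  i <- which.min(abs(ax$x - 30)); j <- which.min(abs(ax$y - pc[2]))
  k <- which.min(abs(ax$z - pc[3]))
  expect_equal(lab$labels[i, j, k], GEL_LABELS[["gel"]])
  deficit <- 1 - del$dose[i, j, k] / pl$dose[i, j, k]
  expect_equal(deficit, perturb$shadow_deficit_frac, tolerance = 0.01)
})

test_that("line-averaged deficit difference recovers the extra shadow deficit", {
  spec <- phantom_spec()
  lab <- make_phantom_labels(spec)
  pl <- planned_dose(spec, beam_model())
  perturb <- perturbation_model()
  del <- delivered_dose(pl, lab, spec, perturb)
  ax <- grid_axes(pl)
  pc <- spec$port_center_mm
  j1 <- which.min(abs(ax$y - pc[2]))   # crosses the shadow
  j2 <- which.min(abs(ax$y + pc[2]))   # mirror line without the shadow
  k <- which.min(abs(ax$z - pc[3]))
  gel1 <- lab$labels[, j1, k] == GEL_LABELS[["gel"]]
  gel2 <- lab$labels[, j2, k] == GEL_LABELS[["gel"]]
  d1 <- mean(1 - del$dose[gel1, j1, k] / pl$dose[gel1, j1, k])
  d2 <- mean(1 - del$dose[gel2, j2, k] / pl$dose[gel2, j2, k])
  expect_equal(d1 - d2,
               perturb$shadow_deficit_frac - perturb$wall_deficit_frac,
               tolerance = 0.004)
})

test_that("shadow weight vanishes away from the port column", {
  spec <- phantom_spec()
  soft <- 0.5
  w <- port_shadow_weight(spec, softening_mm = soft)
  lab <- make_phantom_labels(spec)
  ax <- grid_axes(lab)
  pc <- spec$port_center_mm
  sh <- spec$grid_shape
  yarr <- array(rep(rep(ax$y, each = sh[1]), times = sh[3]), sh)
  zarr <- array(rep(ax$z, each = sh[1] * sh[2]), sh)
  far <- abs(yarr - pc[2]) > spec$port_diameter_mm / 2 + 5 * soft |
    abs(zarr - pc[3]) > spec$port_thickness_mm / 2 + 5 * soft
  expect_true(all(w[far] < 1e-6))
  # and is (near) full inside the core of the footprint
  core <- abs(yarr - pc[2]) < spec$port_diameter_mm / 2 - 3 * soft &
    abs(zarr - pc[3]) < 0.5
  expect_gt(min(w[core]), 0.99)
})

test_that("noiseless echoes decay at exactly the prescribed rate", {
  te <- 35 * (1:8)
  spec <- small_spec()
  lab <- make_phantom_labels(spec)
  truth <- calibration_truth()
  dose <- dose_volume(array(2, spec$grid_shape), spec$spacing_mm,
                      spec$origin_mm, kind = "measured")
  ech <- simulate_echoes(dose, lab, truth, quiet_scanner())
  gel_idx <- which(lab$labels == GEL_LABELS[["gel"]], arr.ind = TRUE)[1, ]
  sig <- ech$data[gel_idx[1], gel_idx[2], gel_idx[3], ]
  r2_true <- truth$intercept + truth$slope * 2
  # log slope reproduces R2 exactly
  sl <- coef(lm(log(sig) ~ I(te / 1000)))[2]
  expect_equal(unname(sl), -r2_true, tolerance = 1e-10)
  # closed-form ratio of the first two echoes
  expect_equal(sig[2] / sig[1], exp(-0.035 * r2_true), tolerance = 1e-12)
})

test_that("Rician mean matches its high-SNR expansion", {
  set.seed(7)
  s <- 500; sigma <- 10
  m <- sqrt((s + rnorm(1e5, 0, sigma))^2 + rnorm(1e5, 0, sigma)^2)
  expected <- s * (1 + sigma^2 / (2 * s^2))
  expect_equal(mean(m), expected, tolerance = 3 * sigma / sqrt(1e5) / s * 5)
})

test_that("identical seeds reproduce identical simulated volumes", {
  spec <- small_spec()
  lab <- make_phantom_labels(spec)
  pl <- planned_dose(spec, beam_model())
  sc <- scanner_model(seed = 99)
  e1 <- simulate_echoes(pl, lab, calibration_truth(), sc)
  e2 <- simulate_echoes(pl, lab, calibration_truth(), sc)
  expect_identical(e1$data, e2$data)
  v1 <- simulate_calibration_vials(calibration_truth(), sc)
  v2 <- simulate_calibration_vials(calibration_truth(), sc)
  expect_identical(v1$vials, v2$vials)
})

test_that("calibration vials cover the stated dose range", {
  v <- simulate_calibration_vials(calibration_truth(), quiet_scanner())
  doses <- vapply(v$vials, `[[`, numeric(1), "dose_Gy")
  expect_equal(doses, seq(0.5, 4.5, by = 0.5))
  expect_error(
    simulate_calibration_vials(calibration_truth(vial_doses_Gy = numeric(0)),
                               quiet_scanner()),
    "empty")
})

test_that("zero-noise vials fit back to the exact linear response", {
  truth <- calibration_truth()
  v <- simulate_calibration_vials(truth, quiet_scanner(),
                                  voxels_per_vial = 20)
  st <- vial_roi_stats(v, erosion_mm = 1)
  expect_equal(st$R2_mean, truth$intercept + truth$slope * st$dose_Gy,
               tolerance = 1e-9)
  expect_equal(st$R2_sd, rep(0, nrow(st)), tolerance = 1e-10)
})

test_that("the reference scan is uniform without bias and noise", {
  spec <- small_spec()
  ref <- simulate_reference(spec, quiet_scanner(), uniform_R2 = 3)
  r2 <- fit_r2(ref)
  expect_lt(diff(range(r2$r2[r2$mask])), 1e-9)
  expect_equal(median(r2$r2[r2$mask]), 3, tolerance = 1e-9)
})

test_that("an amplitude (S0) bias leaves the fitted decay rate unchanged", {
  spec <- small_spec()
  set.seed(5)
  bias <- make_bias_field(spec, amplitude = 0.1, scale_mm = 50)
  sc <- quiet_scanner(bias_mode = "s0")
  ref_b <- simulate_reference(spec, sc, uniform_R2 = 3, bias = bias)
  r2 <- fit_r2(ref_b)
  expect_lt(diff(range(r2$r2[r2$mask])), 1e-8)
})
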