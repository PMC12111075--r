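mk_curve <- function(slope = 1.2, intercept = 3) {
  d <- seq(0.5, 4.5, by = 0.5)
  fit_calibration(data.frame(dose_Gy = d, R2_mean = intercept + slope * d,
                             R2_sd = 0))
}

test_that("R2 at the intercept maps to zero dose and clipping is counted", {
  cc <- mk_curve()
  cc$slope <- 1.2; cc$intercept <- 3  # exact coefficients for exact zeros
  r2 <- array(c(3, 3.6, 2.4, 4.2), c(4, 1, 1))
  m <- r2_map(r2, array(0, c(4, 1, 1)), array(TRUE, c(4, 1, 1)), c(1, 1, 1))
  d <- r2_to_dose(m, cc)
  expect_equal(d$dose[1, 1, 1], 0)
  expect_equal(d$dose[2, 1, 1], 0.5, tolerance = 1e-12)
  expect_equal(d$dose[3, 1, 1], 0)            # clipped negative
  expect_equal(attr(d, "n_clipped"), 1L)
})

test_that("noiseless simulate-fit-convert round trip recovers the dose", {
  spec <- small_spec()
  lab <- make_phantom_labels(spec)
  pl <- planned_dose(spec, beam_model())
  truth <- calibration_truth()
  ech <- simulate_echoes(pl, lab, truth, quiet_scanner())
  r2 <- fit_r2(ech)
  dose <- r2_to_dose(r2, mk_curve(truth$slope, truth$intercept))
  gel <- lab$labels == GEL_LABELS[["gel"]] & pl$dose > 0.1
  rel <- abs(dose$dose[gel] - pl$dose[gel]) / pl$dose[gel]
  expect_lt(max(rel), 0.001)
})

test_that("doubling the true dose doubles the reconstruction (noiseless)", {
  spec <- small_spec()
  lab <- make_phantom_labels(spec)
  pl <- planned_dose(spec, beam_model())
  truth <- calibration_truth()
  cc <- mk_curve(truth$slope, truth$intercept)
  rec <- function(vol) {
    ech <- simulate_echoes(vol, lab, truth, quiet_scanner())
    r2_to_dose(fit_r2(ech), cc)
  }
  d1 <- rec(pl)
  pl2 <- pl; pl2$dose <- 2 * pl$dose
  d2 <- rec(pl2)
  gel <- lab$labels == GEL_LABELS[["gel"]] & pl$dose > 0.1
  expect_equal(d2$dose[gel], 2 * d1$dose[gel], tolerance = 1e-6)
})

test_that("identical fiducials give the identity transform with zero FRE", {
  p <- fiducial_set(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10)))
  tf <- rigid_from_fiducials(p, p)
  expect_equal(tf$R, diag(3), tolerance = 1e-12)
  expect_equal(tf$t, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(tf$fre_mm, 0, tolerance = 1e-12)
})

test_that("a synthesized rigid transform is recovered to 1e-6", {
  set.seed(201)
  pts <- matrix(runif(15, -50, 50), 5, 3)
  th <- 17 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(3, -2, 1)
  moved <- sweep(pts %*% t(R), 2, tr, "+")
  tf <- rigid_from_fiducials(fiducial_set(pts), fiducial_set(moved))
  expect_lt(max(abs(tf$R - R)), 1e-9)
  expect_lt(max(abs(tf$t - tr)), 1e-9)
  expect_lt(tf$fre_mm, 1e-9)
  # round trip through the inverse
  back <- apply_transform(invert_transform(tf), moved)
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("a perturbed fiducial yields bounded error, degenerate sets fail", {
  set.seed(211)
  pts <- matrix(runif(12, -40, 40), 4, 3)
  moved <- pts
  moved[1, ] <- moved[1, ] + c(1, 0, 0)
  tf <- rigid_from_fiducials(fiducial_set(pts), fiducial_set(moved))
  expect_gt(tf$fre_mm, 0)
  expect_lt(tf$fre_mm, 1)
  ang <- acos((sum(diag(tf$R)) - 1) / 2) * 180 / pi
  expect_lt(ang, 2)
  line <- fiducial_set(cbind(1:4, 2 * (1:4), 3 * (1:4)))
  expect_error(rigid_from_fiducials(line, line), "collinear")
  two <- fiducial_set(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(rigid_from_fiducials(two, two), "3 matched")
})

test_that("resampling through the identity preserves values exactly", {
  set.seed(221)
  arr <- array(runif(6 * 7 * 8), c(6, 7, 8))
  v <- dose_volume(arr, c(1.5, 2, 1), c(0, 0, 0), kind = "planned")
  out <- resample_to(v, identity_transform(), v)
  expect_equal(out$dose, arr, tolerance = 1e-12)
})

test_that("a one-voxel-pitch translation shifts values by one index", {
  set.seed(231)
  arr <- array(runif(8 * 8 * 8), c(8, 8, 8))
  v <- dose_volume(arr, c(2, 2, 2), c(0, 0, 0), kind = "planned")
  tf <- identity_transform()
  tf$t <- c(2, 0, 0)  # move the volume +x by one pitch
  out <- resample_to(v, tf, v)
  expect_equal(out$dose[2:8, , ], arr[1:7, , ], tolerance = 1e-12)
  expect_true(all(is.na(out$dose[1, , ])))
})

test_that("trilinear resampling is exact on affine fields at any offset", {
  ax <- list(x = 0:9 * 2, y = 0:9 * 2, z = 0:9 * 2)
  ramp <- outer(ax$x, ax$y, function(a, b) 0.3 * a + 0.1 * b)
  arr <- array(rep(ramp, 10), c(10, 10, 10)) +
    rep(0.05 * ax$z, each = 100)
  v <- dose_volume(arr, c(2, 2, 2), c(0, 0, 0), kind = "planned")
  tf <- identity_transform()
  tf$t <- c(0.7, -0.3, 1.1)
  out <- resample_to(v, tf, v)
  inner <- !is.na(out$dose)
  ax3 <- grid_axes(v)
  world <- list(
    x = array(rep(ax3$x, 100), c(10, 10, 10)),
    y = array(rep(rep(ax3$y, each = 10), 10), c(10, 10, 10)),
    z = array(rep(ax3$z, each = 100), c(10, 10, 10)))
  truth <- 0.3 * (world$x - 0.7) + 0.1 * (world$y + 0.3) +
    0.05 * (world$z - 1.1)
  expect_equal(out$dose[inner], truth[inner], tolerance = 1e-10)
})

test_that("transform round trip returns a smooth field within 0.5% RMS", {
  n <- 48
  ax <- (seq_len(n) - 1) * 2.5 - 59
  bump <- function(c0, w) exp(-0.5 * ((ax - c0) / w)^2)
  arr <- (outer(bump(5, 40), bump(-8, 45)) %o% bump(10, 50)) * 3 + 0.5
  pl <- dose_volume(arr, c(2.5, 2.5, 2.5), c(-59, -59, -59), kind = "planned")
  th <- 5 * pi / 180
  tf <- identity_transform()
  tf$R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tf$t <- c(2.3, -1.1, 0.7)
  fwd <- resample_to(pl, tf, pl)
  back <- resample_to(fwd, invert_transform(tf), pl)
  ok <- !is.na(back$dose)
  rel <- (back$dose[ok] - pl$dose[ok]) / pl$dose[ok]
  expect_lt(sqrt(mean(rel^2)), 0.005)
})

test_that("relative normalization obeys max rule, scale invariance, idempotence", {
  set.seed(241)
  arr <- array(runif(5^3, 1, 2), c(5, 5, 5))
  m <- dose_volume(arr, c(1, 1, 1), kind = "measured")
  p <- dose_volume(2 * arr, c(1, 1, 1), kind = "planned")
  rel <- normalize_relative(m, p, percentile = 100)
  expect_equal(max(rel$measured$dose), 100, tolerance = 1e-12)
  expect_equal(max(rel$planned$dose), 100, tolerance = 1e-12)
  # scaling a volume leaves its relative version unchanged
  m2 <- m; m2$dose <- 7 * m$dose
  rel2 <- normalize_relative(m2, p, percentile = 100)
  expect_equal(rel2$measured$dose, rel$measured$dose, tolerance = 1e-12)
  # idempotence
  rel3 <- normalize_relative(rel$measured, rel$planned, percentile = 100)
  expect_equal(rel3$measured$dose, rel$measured$dose, tolerance = 1e-12)
  # empty mask errors
  expect_error(normalize_relative(m, p, measured_mask = array(FALSE, dim(arr))),
               "empty mask")
})

test_that("relative measured and planned agree away from walls and shadow", {
  spec <- phantom_spec()
  lab <- make_phantom_labels(spec)
  pl <- planned_dose(spec, beam_model())
  del <- delivered_dose(pl, lab, spec, perturbation_model())
  gel <- lab$labels == GEL_LABELS[["gel"]]
  rel <- normalize_relative(del, pl, percentile = 99.5,
                            measured_mask = gel, planned_mask = gel,
                            margin_mm = 14, presmooth_mm = 0)
  dwall <- distance_to(lab$labels == GEL_LABELS[["wall"]], spacing_mm(lab))
  shadow <- port_shadow_weight(spec, 0.5)
  clean <- gel & dwall > 14 & shadow < 1e-6
  rel_err <- (rel$measured$dose[clean] - rel$planned$dose[clean]) /
    rel$planned$dose[clean]
  expect_lt(sqrt(mean(rel_err^2)), 0.01)
})
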