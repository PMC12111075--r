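test_that("identical volumes give gamma zero and a 100% pass rate", {
  ref <- random_dose_fixture(301)
  res <- gamma_3d(ref, ref, gamma_criteria(interp_factor = 2))
  expect_equal(max(res$gamma[res$evaluated_mask]), 0, tolerance = 1e-12)
  expect_equal(res$pass_rate_overall, 100)
})

test_that("a uniform +3% offset saturates gamma at exactly 1", {
  # on a flat field no spatial search can reduce the dose term, so the
  # closed form gives gamma = dose offset / criterion = 1 everywhere
  ref <- dose_volume(array(3, c(16, 16, 16)), c(2, 2, 2), kind = "planned")
  ev <- ref
  ev$dose <- 1.03 * ref$dose
  res <- gamma_3d(ref, ev, gamma_criteria(dose_diff_pct = 3, dta_mm = 3,
                                          interp_factor = 4,
                                          normalization = "value",
                                          norm_value = 3))
  g <- res$gamma[res$evaluated_mask]
  expect_lte(max(g), 1 + 1e-9)
  expect_equal(max(g), 1, tolerance = 1e-9)
  expect_equal(min(g), 1, tolerance = 1e-9)
  expect_equal(res$pass_rate_overall, 100)
})

test_that("the fast engine equals the exhaustive brute-force oracle", {
  for (seed in 311:313) {
    ref <- random_dose_fixture(seed)
    ev <- random_dose_fixture(seed + 100)
    crit <- gamma_criteria(dose_diff_pct = 3, dta_mm = 3, threshold_pct = 10,
                           search_radius_mm = 6, interp_factor = 2,
                           normalization = "value", norm_value = 3)
    res <- gamma_3d(ref, ev, crit)
    brute <- gamma_brute(ref$dose, ev$dose, spacing_mm(ref),
                         res$evaluated_mask, dta = 3, dd_abs = 0.09,
                         search_radius = 6, interp = 2)
    dmax <- max(abs(res$gamma[res$evaluated_mask] -
                      brute[res$evaluated_mask]))
    expect_lt(dmax, 1e-6)
  }
})

test_that("loosening either criterion never decreases the pass rate", {
  ref <- random_dose_fixture(321)
  ev <- random_dose_fixture(322)
  base <- gamma_3d(ref, ev, gamma_criteria(dose_diff_pct = 2, dta_mm = 2,
                                           interp_factor = 2,
                                           normalization = "value",
                                           norm_value = 3))
  for (crit in list(gamma_criteria(dose_diff_pct = 3, dta_mm = 2,
                                   interp_factor = 2,
                                   normalization = "value", norm_value = 3),
                    gamma_criteria(dose_diff_pct = 2, dta_mm = 3,
                                   interp_factor = 2,
                                   normalization = "value", norm_value = 3))) {
    res <- gamma_3d(ref, ev, crit)
    expect_gte(res$pass_rate_overall, base$pass_rate_overall)
  }
})

test_that("sub-DTA shifts pass while supra-DTA shifts across gradients fail", {
  n <- 24
  ax <- (seq_len(n) - 1) * 1.0
  ramp <- 1 + 0.06 * pmax(ax - 8, 0)          # steep 6%/mm gradient region
  arr <- array(rep(ramp, n * n), c(n, n, n))
  ref <- dose_volume(arr, c(1, 1, 1), kind = "planned")
  shift_by <- function(d_mm) {
    tf <- identity_transform(); tf$t <- c(d_mm, 0, 0)
    resample_to(ref, tf, ref)
  }
  crit <- gamma_criteria(dose_diff_pct = 3, dta_mm = 3, threshold_pct = 10,
                         interp_factor = 4, normalization = "value",
                         norm_value = max(arr))
  core <- array(FALSE, c(n, n, n)); core[8:17, 4:21, 4:21] <- TRUE
  res_small <- gamma_3d(ref, shift_by(2), crit, norm_mask = core)
  expect_equal(res_small$pass_rate_overall, 100)
  res_big <- gamma_3d(ref, shift_by(4.5), crit, norm_mask = core)
  expect_gt(max(res_big$gamma[res_big$evaluated_mask]), 1)
})

test_that("voxels below the threshold never affect reported rates", {
  ref <- random_dose_fixture(331)
  ev <- random_dose_fixture(332)
  crit <- gamma_criteria(threshold_pct = 20, interp_factor = 2,
                         normalization = "value", norm_value = 3)
  r1 <- gamma_3d(ref, ev, crit)
  # scrambling sub-threshold reference voxels (downward, so they stay below
  # the threshold) must not move any reported rate
  ref2 <- ref
  low <- ref$dose < 0.2 * 3
  set.seed(333)
  ref2$dose[low] <- ref$dose[low] * runif(sum(low))
  r2 <- gamma_3d(ref2, ev, crit)
  expect_equal(r1$pass_rate_overall, r2$pass_rate_overall)
  expect_equal(sum(r1$evaluated_mask), sum(r2$evaluated_mask))
})

test_that("slice rates are consistent with the overall rate", {
  ref <- random_dose_fixture(341)
  res <- gamma_3d(ref, ref, gamma_criteria(interp_factor = 2))
  sr <- slice_pass_rates(res, "y")
  expect_true(all(sr$pass_rate_pct[sr$evaluated_voxels > 0] == 100))
  # a confined artificial fail region changes only its own slices
  ev <- ref
  ev$dose[, 6:8, ] <- ev$dose[, 6:8, ] * 0.80
  res2 <- gamma_3d(ref, ev, gamma_criteria(interp_factor = 2,
                                           normalization = "value",
                                           norm_value = max(ref$dose)))
  sr2 <- slice_pass_rates(res2, "y")
  outside <- sr2$evaluated_voxels > 0 & !(sr2$slice %in% 4:10)
  expect_true(all(sr2$pass_rate_pct[outside] == 100))
  # evaluated-count weighted mean of slice rates equals the overall rate
  w <- sr2$evaluated_voxels
  expect_equal(sum(w * sr2$pass_rate_pct, na.rm = TRUE) / sum(w),
               res2$pass_rate_overall, tolerance = 1e-9)
})

test_that("fail-region export summarizes connected components exactly", {
  ref <- random_dose_fixture(351)
  res <- gamma_3d(ref, ref, gamma_criteria(interp_factor = 2))
  out <- export_fail_map(res)
  expect_equal(nrow(out$components), 0)
  # carve a cubic fail region into an otherwise identical volume
  ev <- ref
  ev$dose[5:7, 5:7, 5:7] <- 0
  res2 <- gamma_3d(ref, ev, gamma_criteria(interp_factor = 2, dta_mm = 1,
                                           search_radius_mm = 2,
                                           normalization = "value",
                                           norm_value = max(ref$dose)))
  out2 <- export_fail_map(res2)
  expect_equal(nrow(out2$components), 1)
  n_fail <- sum(res2$evaluated_mask & !res2$pass_mask)
  expect_equal(out2$components$n_voxels[1], n_fail)
  expect_equal(out2$components$volume_mm3[1], n_fail * prod(spacing_mm(ref)))
})
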