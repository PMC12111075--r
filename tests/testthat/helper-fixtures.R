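# shared fixtures and independent oracles for the test suite

# a coarse phantom grid that keeps simulator tests fast
small_spec <- function(grid_shape = c(48, 48, 48),
                       spacing_mm = c(2.5, 2.5, 1.5)) {
  phantom_spec(grid_shape = grid_shape, spacing_mm = spacing_mm)
}

quiet_scanner <- function(...) {
  scanner_model(noise_sigma = 0, bias_amplitude = 0, ...)
}

# closed-form gel volume of the voxelized geometry: half-ellipsoid cavity
# above the base floor minus the upper half of the dome-wall ellipsoid
gel_volume_closed_form <- function(spec) {
  w <- spec$wall_thickness_mm
  cav <- spec$outer_shell_mm - w
  dw <- spec$inner_dome_mm + w
  v_cav <- pi * cav[1] * cav[2] *
    (2 * cav[3] / 3 - w + w^3 / (3 * cav[3]^2))
  v_dome <- 2 / 3 * pi * prod(dw)
  (v_cav - v_dome) / 1e6
}

# R-native trilinear interpolation (independent of the compiled path)
r_trilinear <- function(arr, idx) {
  d <- dim(arr)
  out <- rep(NA_real_, nrow(idx))
  x <- idx[, 1] - 1; y <- idx[, 2] - 1; z <- idx[, 3] - 1
  ok <- x >= 0 & y >= 0 & z >= 0 & x <= d[1] - 1 & y <= d[2] - 1 &
    z <= d[3] - 1
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  i0 <- pmin(floor(x), d[1] - 2); j0 <- pmin(floor(y), d[2] - 2)
  k0 <- pmin(floor(z), d[3] - 2)
  i0[d[1] == 1] <- 0; j0[d[2] == 1] <- 0; k0[d[3] == 1] <- 0
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  g <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  v <- g(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(i1, j0, k0) * fx * (1 - fy) * (1 - fz) +
    g(i0, j1, k0) * (1 - fx) * fy * (1 - fz) +
    g(i1, j1, k0) * fx * fy * (1 - fz) +
    g(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
    g(i1, j0, k1) * fx * (1 - fy) * fz +
    g(i0, j1, k1) * (1 - fx) * fy * fz +
    g(i1, j1, k1) * fx * fy * fz
  out[ok] <- v
  out
}

# exhaustive brute-force gamma (no early termination, no sorting) used as
# the independent oracle for the fast engine
gamma_brute <- function(ref, ev, spacing, evaluate, dta, dd_abs,
                        search_radius, interp) {
  d <- dim(ref)
  s <- spacing / interp
  m <- floor(search_radius / s)
  offs <- expand.grid(x = (-m[1]:m[1]) * s[1], y = (-m[2]:m[2]) * s[2],
                      z = (-m[3]:m[3]) * s[3])
  dist2 <- offs$x^2 + offs$y^2 + offs$z^2
  keep <- dist2 <= search_radius^2
  offs <- as.matrix(offs[keep, ])
  dist2 <- dist2[keep]
  off_idx <- sweep(offs, 2, spacing, "/")
  g <- array(NA_real_, d)
  vox <- which(evaluate, arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    ctr <- vox[r, ]
    idx <- sweep(off_idx, 2, as.numeric(ctr), "+")
    vals <- r_trilinear(ev, idx)
    dd <- (vals - ref[ctr[1], ctr[2], ctr[3]]) / dd_abs
    g2 <- dist2 / dta^2 + dd^2
    if (any(!is.na(g2)))
      g[ctr[1], ctr[2], ctr[3]] <- sqrt(min(g2, na.rm = TRUE))
  }
  g
}

# smooth random dose fixture on a 16^3 grid with an interior maximum
random_dose_fixture <- function(seed, n = 16, spacing = c(2, 2, 2)) {
  set.seed(seed)
  ax <- (seq_len(n) - 1) * spacing[1]
  ctr <- runif(3, 0.3, 0.7) * max(ax)
  wd <- runif(1, 10, 18)
  bump <- function(x, c0) exp(-0.5 * ((x - c0) / wd)^2)
  base <- outer(bump(ax, ctr[1]), bump(ax, ctr[2])) %o% bump(ax, ctr[3])
  ripple <- array(runif(n^3, -0.03, 0.03), c(n, n, n))
  dose <- 3 * base * (1 + ripple)
  dose_volume(dose, spacing_mm = spacing, kind = "planned")
}

# cached full-pipeline runs shared between test files (deterministic seeds)
.pipeline_cache <- new.env(parent = emptyenv())
pipeline_run_cached <- function(seed) {
  key <- as.character(seed)
  if (is.null(.pipeline_cache[[key]])) {
    t0 <- Sys.time()
    rep <- run_pipeline(run_config(seed = seed))
    attr(rep, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))
    .pipeline_cache[[key]] <- rep
  }
  .pipeline_cache[[key]]
}

acceptance_seeds <- function() 1:12
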