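---
title: "Methods: gel dosimetry of a metal-port dose shadow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gel dosimetry of a metal-port dose shadow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Tissue expanders used in two-stage breast reconstruction contain a magnetic
injection valve — a titanium-encased samarium-cobalt disk, about 17.9 mm in
diameter and 3.9 mm thick. When chest-wall radiotherapy is delivered with
the expander in place, this high-Z disk perturbs the dose behind it along
the beam direction. Point detectors and film sample the perturbation only on
a plane or at a handful of points; a polymer-gel dosimeter records it in 3D:
absorbed dose drives radical polymerization of the gel (MAGIC-f: methacrylic
acid, ascorbic acid, copper, gelatin, formaldehyde), cross-linking shortens
T2, and the transverse relaxation rate R2 = 1/T2 grows linearly with dose
over the working range. A multi-echo spin-echo MR acquisition therefore
turns the irradiated phantom into a dense 3D dosimeter.

`geldose` implements this measurement chain — relaxometry, calibration,
registration, normalization, 3D gamma comparison, profile statistics — and a
synthetic phantom/scanner generator that stands in for the (non-public) raw
data. Everything the analysis consumes can be simulated under known ground
truth, so every stage is testable, and the headline quantities (the ~9.8%
in-shadow deficit, the ~4.5% wall-related deficit, and their ~5.3%
difference attributed to the metal) become parameter-recovery experiments.

# The synthetic phantom

`phantom_spec()` voxelizes an idealized breast-shaped flask on a default
96^3 grid (1.25 x 1.25 x 0.75 mm): a hemiellipsoidal glass shell (outer
semi-axes 56, 56, 64 mm; 2 mm walls) whose interior is gel except for a
water-filled inner dome (semi-axes 35, 35, 28 mm) that models the prosthesis
space. The resulting gel shell is ~0.28 L, matching the nominal fill volume.
The exact silhouette of the physical flask is not published; the
hemiellipsoid is a plausible reconstruction, chosen once, and the 2% closed
form / 5% nominal volume checks in the tests pin its scale. The port disk
(axis vertical) sits inside the water dome against its surface, centred at
(0, -14, 20) mm; every voxel carries exactly one label in
{outside, wall, gel, water, metal}.

## Planned dose: an analytic two-tangent surrogate

The clinical plan (TPS-computed opposed tangents, 19 x 20 cm^2, 15-degree
wedges, 6 MV, 3 Gy) is replaced by an analytic parallel-beam surrogate: per
beam, dose = prescription/2 x buildup x exp(-mu_eff depth) x wedge x
aperture, summed over the two opposed beams (gantry 90/270 deg, i.e. along
±x) and renormalized so the total at the isocenter is exactly the
prescription. Parameters, with defaults:

* `mu_eff_per_cm` = 0.05 — effective attenuation of a 6 MV beam beyond
  buildup (~0.5%/mm).
* `buildup_mm` = 10 — exponential dose buildup length, with depth counted
  from the outer surface plus a 10 mm bolus (`bolus_mm`). Buildup is part of
  this surrogate (not just exponential falloff) because without it the
  hottest voxels sit on the beam-entry surfaces, inside the near-wall
  artifact zone; with it the hot region is interior, as in the measured
  study geometry, which keeps the maximum-normalization clean.
* `wedge_angle_deg` = 15 — a linear across-field gradient along z with lever
  arm 120 mm, the standard first-order wedge model.

The surrogate is smooth, mirror-symmetric in x on the symmetric phantom, and
exact closed-form cases (no attenuation/wedge → uniform; isocenter = 3 Gy)
anchor the tests.

## Delivered dose: the two deficits

`delivered_dose()` multiplies the planned dose on gel voxels by two factors:

* **Near-wall deficit.** Oxygen diffusing from the glass quenches
  polymerization near the walls. The deficit is `wall_deficit_frac` (0.045)
  within a plateau of `wall_plateau_mm` (10 mm) of the nearest wall, then
  decays exponentially with length `wall_range_mm` (1.5 mm). A plateau +
  sharp front is what a reaction–diffusion inhibition process produces and
  is required for consistency: the comparison profiles run through gel
  pockets up to ~9 mm from the dome wall and measure the full ~4.5%, while
  the hot interior (>14 mm from any wall) must be essentially unaffected or
  the maximum-normalization would absorb the deficit and hide it from the
  relative comparison. Distances are exact Euclidean distance transforms of
  the voxelized wall.
* **Port shadow.** With opposed lateral beams, the union of the two
  geometric shadows of the disk is the full x-column through the disk's
  (y, z) footprint (a 17.9 x 3.9 mm rectangle), edge-softened by a 0.5 mm
  Gaussian blur. Inside it the *total* deficit is `shadow_deficit_frac`
  (0.098): the extra factor is 1 - (1-0.098)/(1-0.045), so that
  (1-wall)(1-extra) equals 1-0.098 exactly where the wall effect is fully
  expressed. (A naive additive "shadow minus wall" extra would undershoot
  the stated total by the product term.) The line-averaged difference
  between a shadow-crossing profile and its mirror is then
  (shadow - wall deficit) x (1 - wall) ≈ 5.3%.

## Scanner model

`simulate_echoes()` produces magnitude images S(TE) = S0 exp(-R2 TE) at
eight echoes (multiples of 35 ms), with R2 = intercept + slope x dose on gel
(defaults 3.0 + 1.2 D s^-1), a fixed low rate in water, and near-zero signal
in glass/metal/air. Noise is Rician — Gaussian sigma on each quadrature
channel, magnitude taken — with `noise_sigma` = 5.7 on S0 = 1000. That value
was tuned once so the default nine-vial batch yields a mean relative dose
uncertainty of 3.0%, the stated calibration quality; it corresponds to
first-echo SNR ≈ 140-170 in gel and per-voxel dose noise of ~1.7% at 3 Gy.
The bias field is a sum of random Gaussian blobs scaled to 1 ± 5% over a
60 mm correlation length. By default it multiplies S0 (amplitude shading, as
receive-coil sensitivity does), which provably leaves fitted decay rates
unchanged; the alternative `bias_mode = "r2"` multiplies R2 instead and is
the regime the reference-scan correction is designed to remove — the
simulator supports both because the physical mechanism of the scanner
inhomogeneity is not observable from the published analysis.

What the generator does **not** emulate: susceptibility distortion and
signal voids around the metal, B1/slice-profile and stimulated-echo effects
in the echo train, gel diffusion and temporal instability, partial-volume
mixing at interfaces beyond voxelization, and TPS heterogeneity-correction
errors. Passing tests therefore demonstrate that the *analysis chain*
recovers known ground truth under realistic noise — not that it would be
unbiased against every artifact of a physical scan.

# Relaxometry

`fit_r2()` fits each voxel's echo train by weighted least squares on
log S with delta-method weights S^2 (near maximum-likelihood at high SNR),
in two passes: the second pass reweights with the *fitted* signal, because
observed-signal weights are correlated with the noise and bias the fit. A
vectorized Gauss-Newton fit of the exponential itself (`method =
"nonlinear"`, started from the log-linear estimate, 30 damped iterations) is
kept for validation; `stats::nls` on single voxels is its oracle in the
tests. The two estimators agree within ~1% under the additive-noise model
they both assume at first-echo SNR ≥ 30; under Rician magnitude noise their
*bias* difference at the noise floor of late echoes can exceed that, which
is a property of magnitude MR, not of the fitters. For that regime
`noise_floor = TRUE` subtracts the Rician floor
(sqrt(max(S^2 - 2 sigma^2, 0)), the second-moment correction) before
fitting; it is off by default because gel SNR is high, but the calibration
uses it in bias-sensitive tests. Voxels with fewer than three positive
echoes, or a first echo below `snr_floor` x the background sigma (Rayleigh
estimate, mean/sqrt(pi/2), from a signal-free region), are masked, never
fitted. Reported `r2_sigma` comes from the fit covariance; Monte-Carlo
checks hold it within 15% of the empirical spread at SNR 50.

`correct_inhomogeneity()` divides a map by the correction field c(x) =
smooth(reference R2)/mean(reference R2), the reference being a uniform-gel
scan of the same session. The correction is deliberately *shape-only* (unit
mean): a global scale shared with the calibration vials cancels in the
relative analysis. The default smoothing (20 mm) suits noisy references;
round-trip accuracy on smooth bias fields is limited by the smoothing's
distortion of the field (~0.2% RMS at 10 mm smoothing for 60 mm-scale bias).

# Calibration

Vial ROIs are eroded 1.5 mm from the vial wall (susceptibility artifacts
concentrate at the glass), each remaining voxel is fitted, and the vial mean
and SD summarize the batch. The calibration line is fitted by
inverse-variance weighted least squares using the stated variance of each
vial mean (R2_sd^2/n); its standard errors come from the GLS covariance
without dispersion rescaling, the metrology convention when weights are
actual uncertainty estimates (an ordinary fit with textbook errors is the
`weighted = FALSE` fallback and the default whenever a vial SD is zero).
Diagnostics follow the field's definitions: Pearson r on the nine (dose,
mean R2) pairs; mean uncertainty = mean over vials of 100 sigma_D/D with
sigma_D = R2_sd/slope; dose resolution D_delta_p = k_p sqrt(2) sigma_D with
the two-sided Gaussian coverage factor k_95 = 1.96 (configurable, since
other conventions use e.g. 2.77).

# Reconstruction, registration, normalization

Dose conversion inverts the calibration line, clipping negative doses to
zero with a count. Frames are aligned by closed-form orthogonal Procrustes
(Kabsch) on labelled fiducials with a proper-rotation guarantee and reported
fiducial registration error; volumes move through rigid transforms by
trilinear pull-back, and points leaving the source grid become invalid (NA),
never zero. In synthetic mode both frames coincide, so the pipeline
exercises the registration path with an identity result.

Relative dose divides each volume by its own robust maximum — the 99.5th
percentile of eligible voxels rather than the single hottest voxel. In the
pipeline the percentile is evaluated on the gel mask eroded by 14 mm (the
largest margin that keeps a nonempty gel core on the default grid, and
enough that the wall deficit there is <0.4%) and on a 3 mm-presmoothed copy
of the volume; both guards exist because an extreme percentile of ~2 x 10^5
noisy voxels is biased upward by ~2 sigma, which would inflate every
reported deficit by the same amount. The volumes themselves are never
smoothed. `normalize_relative()` defaults to the plain percentile so the
literal maximum-normalization rule (percentile = 100) remains available.
Because each distribution is normalized to itself, the comparison is
insensitive to a global scale difference between measurement and plan — the
analysis is deliberately relative, and a uniform calibration error is
invisible to it. The calibrated dose map, not the raw R2 map, is what gets
normalized; with a nonzero intercept the two choices differ, and the dose
map is the quantity the comparison is about.

# Gamma analysis

For each reference voxel at or above the low-dose threshold (10% of the
global normalization dose), gamma is the minimum over candidate points c of
sqrt(|c - r|^2/dta^2 + (D_eval(c) - D_ref(r))^2/dd^2), with dd = 3% of the
global normalization and dta = 3 mm. The search (compiled) visits candidate
offsets on a spacing/interp_factor sub-voxel lattice in order of increasing
radius and stops as soon as the distance term alone exceeds the running
minimum (the standard pre-sorted search strategy); candidates are trilinear
interpolations of the evaluated volume, invalid values are skipped, and the
search is capped at 3 x dta. An exhaustive brute-force evaluator written in
plain R — same candidate lattice, no sorting, no termination — lives in the
test suite only and agrees with the engine to 10^-6 on random fixtures. A
voxel passes at gamma ≤ 1 (boundary passes; the flat +3% fixture exercises
the boundary exactly). Per-slice pass rates are reported along the y axis
(the port's diameter spans ~14 slices there, mirroring how the study
numbered its MRI slices); slices with no evaluated voxels are missing, not
0%. The pipeline evaluates gamma at the planned-grid voxels searching the
measured distribution; the swap is a configuration choice. Full-volume runs
default to `interp_factor = 2` (0.4-0.6 mm candidate steps), a resolution at
which pass rates are stable while a 96^3 pipeline run completes in seconds;
fixture-level verification uses finer lattices.

The wall-excluded statistic recomputes rates on the gel mask eroded by 3 mm,
an explicit margin for the qualitative practice of disregarding wall
failures when the question is the metal's effect.

# Profile analysis and the metal-attributed reduction

The comparison lines mirror the study's: a horizontal line (along x) through
the port-shadow slice at the port's height, and a vertical line (along z)
crossing the shadow at the lateral midpoint of its gel segment — placed
there, rather than through the isocenter, because an isocenter-crossing
vertical line would pass through the water cavity where there is nothing to
measure. Each line is paired with its mirror image (y → -y) on the side of
the phantom without the port; the dome and beams are symmetric, so the
mirror line is the matched no-metal control. The pointwise deficit is
100 (planned - measured)/planned over the region (the full in-gel span for
the horizontal lines; a ±1 mm band around the shadow centre for the vertical
ones, inside the softened edges); `metal_attributed_reduction()` averages
the with-minus-without differences over the two orientations and propagates
the SDs as a root-sum-square divided by the number of pairs — a documented
propagation rule, not one inherited from the study, which prints no
uncertainty for the attributed figure.

With the default generator, 20-seed averages recover ~9.6/9.7% (with metal,
horizontal/vertical), ~4.3/4.5% (without), and ~5.2-5.4% attributed to the
port; single-seed values scatter by 0.3-0.9 pp because a profile holds only
5-36 gel samples with ~1.7% per-voxel dose noise.

# Numerical choices and degenerate inputs

* Distances: exact Euclidean distance transform (two-pass parabolic
  envelope), anisotropic spacing in mm.
* Smoothing: separable Gaussian with normalized convolution over the mask,
  so masked-out voxels never bleed in; kernels truncate at 3.5 sigma.
* Interpolation: trilinear everywhere; any NA corner poisons the sample
  (conservative near mask boundaries); affine fields interpolate exactly,
  which several tests exploit as an oracle.
* Ties and caps: gamma returns the minimum found within the search radius
  (an upper bound where truncated); the optional cap only clips stored
  values.
* Degenerate inputs error early with named messages: ports outside the
  grid, empty vial dose lists, ROIs emptied by erosion, collinear or
  too-few fiducials, all-identical calibration doses, empty normalization
  or evaluation masks. All-zero voxels are masked, not errors.
* Seeds: a single integer drives every stochastic stage through R's RNG;
  identical seeds reproduce bit-identical volumes and summaries.

# Problem sizes used by the checks

The shipped verification suite runs the full pipeline at the study-like
96^3 default (a run takes a few seconds) and averages 12 seeded replicates
for the recovery checks; the standalone reproduction script uses 20 seeds
and 100 calibration replicates. Engine-level oracles use 16^3 fixtures and
10^4-voxel Monte-Carlo panels. These sizes were chosen so the whole suite
exercises every claim at full fidelity in minutes on one core.

# Known limitations

* The phantom silhouette and port placement are plausible reconstructions,
  not measured geometry; absolute coordinates (slice indices, line
  endpoints) are meaningful only within the synthetic frame.
* The beam surrogate has no divergence, scatter, or heterogeneity
  corrections; it is a smooth stand-in adequate for testing the comparison
  machinery, not a dose engine.
* Rician bias is uncorrected by default; at the default SNR it is <0.2% on
  vial means (and removable with `noise_floor = TRUE`), but analyses at
  substantially lower SNR should enable the correction.
* The overall gamma pass rate of the synthetic phantom is high (~99.8%)
  because the modelled wall deficit (~4.5%) sits near the 3%/3 mm criteria
  and the planned-dose gradients let the DTA search absorb much of it; the
  per-slice dip at the port band is robust, but the synthetic overall rate
  should not be read as a statement about physical wall artifacts, whose
  real-world severity (fully inhibited polymerization) is outside the
  generator's deficit model.
* Real-data mode expects NIfTI volumes on axis-aligned grids; DICOM RT-Dose
  import is out of scope.
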