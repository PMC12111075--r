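# geldose

3D polymer-gel dosimetry analysis with multi-echo MRI readout, for
radiotherapy physicists studying dose perturbations that point detectors and
film cannot map — here, the underdose cast by the metal injection port of a
tissue expander during postmastectomy chest-wall irradiation with opposed
tangential 6 MV beams.

A breast-shaped glass phantom filled with MAGIC-f polymer gel records the
delivered 3D dose: absorbed dose increases polymer cross-linking, which
raises the transverse relaxation rate R2 = 1/T2 linearly over the working
range. The package implements the full measurement chain and, because the
study's raw MRI and planning data are not public, a synthetic phantom and
scanner simulator that reproduces the study conditions so that every stage is
testable end to end:

1. **Simulation** (`make_phantom_labels`, `planned_dose`, `delivered_dose`,
   `simulate_echoes`, `simulate_reference`, `simulate_calibration_vials`) —
   hemiellipsoidal gel shell (~0.28 L) around a water-filled inner dome with
   a 17.9 mm x 3.9 mm metal-port disk; analytic two-tangent surrogate plan
   normalized to 3 Gy at the isocenter; a near-wall polymerization-inhibition
   deficit (~4.5%) plus a total ~9.8% deficit in the port's geometric beam
   shadow; 8-echo decay (TE = 35, 70, ..., 280 ms) with Rician noise and a
   smooth scanner bias field.
2. **R2 relaxometry** (`fit_r2`, `background_sigma`,
   `correct_inhomogeneity`) — voxelwise mono-exponential fits
   S(TE) = S0 exp(-R2 TE) by weighted log-linear least squares (two-pass
   delta-method weights) or vectorized Gauss-Newton, SNR masking, and
   reference-phantom correction of scanner spatial inhomogeneity.
3. **Calibration** (`vial_roi_stats`, `fit_calibration`,
   `mean_uncertainty`, `dose_resolution`) — linear R2-dose curve from nine
   vials at 0.5-4.5 Gy with Pearson r, mean relative dose uncertainty, and
   dose resolution D_delta_p = k_p sqrt(2) sigma_D.
4. **Reconstruction** (`r2_to_dose`, `rigid_from_fiducials`, `resample_to`,
   `normalize_relative`) — dose conversion, closed-form fiducial (orthogonal
   Procrustes) registration, trilinear resampling, and robust
   maximum-normalization to relative dose.
5. **Gamma analysis** (`gamma_3d`, `slice_pass_rates`, `export_fail_map`) —
   3D global gamma (3%/3 mm, 10% low-dose threshold) with a radially sorted,
   early-terminating search in compiled code, per-slice pass-rate profiles,
   and connected-component summaries of fail regions.
6. **Profile analysis** (`extract_profile`, `profile_reduction`,
   `metal_attributed_reduction`) — measured-vs-planned deficits along
   matched lines through the port shadow and through the mirror region
   without the port; their difference is the metal-attributed dose
   reduction.

`run_pipeline()` composes all stages and emits a machine-readable summary
(JSON), CSV tables, NIfTI volumes and report figures.

## Worked example

```r
library(geldose)
report <- run_pipeline(run_config(seed = 1))
report
#> <gel_run_report>
#>   calibration: r = 1.0000, mean uncertainty 2.91%
#>   gamma pass rate: 99.8% (wall-excluded 99.9%)
#>   deficits: with metal 10.10%/9.18% (h/v), without 4.27%/5.75%
#>   metal-attributed reduction: 4.63% +/- 1.58%
report$curve
#> <calibration_curve> R2 = 3.001 + 1.199 * D  (r = 1.0000, 9 vials, 0.5-4.5 Gy)
```

Reading the output: the simulated calibration batch is fitted to
R2 = 3.00 + 1.20 D (1/s per Gy) with a mean dose uncertainty of ~3%; the
measured relative dose agrees with the plan almost everywhere (the gamma
criteria absorb the ~4.5% near-wall deficit via the distance-to-agreement
search), while the per-slice pass-rate profile dips in the slice band holding
the metal port (minimum 99.0% inside the band vs a median 100% outside, seed
1). The four profile deficits are the percent dose the gel "measures" below
the plan along the horizontal/vertical comparison lines; a single seed
carries ~0.3-0.9 pp of sampling noise, and averaging over 20 seeds recovers
~9.7%/~4.3% with and without the port, i.e. a metal-attributed reduction of
~5.2-5.4%. `run_pipeline(cfg, out_dir = "out", figures = TRUE)` additionally
writes `summary.json`, per-slice and profile CSVs, and PNG figures
(calibration curve, pass-rate profile, profile overlays).

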