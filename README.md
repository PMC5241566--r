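# voxdosim

Patient-specific 3D internal dosimetry for theranostic radionuclide
therapy, in R. Given a time series of registered quantitative SPECT/CT
images acquired with a surrogate gamma emitter (In-111, T1/2 = 67.3 h),
`voxdosim` predicts the absorbed dose an Y-90-labelled therapy
injection would deliver, in cGy per injected MBq, at the voxel and
organ level, and grades lesion uptake against mediastinal blood-pool
and liver references.

The pipeline:

1. **Calibration** — patient-specific calibration factor
   `cf = C / (A_inj · e^(−λ t_acq) · FAF)`, where the fraction of
   activity in the limited SPECT field of view (FAF) is the in-FOV /
   total count ratio of the 1 h whole-body planar image.
2. **Kinetics** — VOI time-activity curves `A_h(t) = Σ_{x∈h} A_x(t)`
   (peak curves in a 1 cc sphere for lesions, SUV-peak style), tail
   fitting of `A₀ e^(−λt)` to the last 2–3 points by weighted
   Levenberg–Marquardt, with an artificial late point forcing a
   decreasing tail when needed.
3. **Time-integrated activity** — trapezoid over the measured curve
   (from `A(0) = 0`) plus the analytic tail `A₀/λ · e^(−λ t_last)`,
   per VOI and per voxel; effective half-lives `ln 2 / λ`.
4. **Decay substitution** — measured activities are rescaled by
   `e^((λ_In − λ_Y) t)` so the biological kinetics carry the therapy
   radionuclide's physical decay (Y-90 T1/2 = 64.05 h).
5. **Dose** — Monte Carlo beta transport (straight-line
   continuous-slowing-down approximation on the density-scaled
   electron range, Y-90 spectrum source, 3.6×10⁹ disintegrations per
   MBq·h) plus a closed-form local-deposition reference mode;
   mass-weighted mean VOI doses with batch-based Monte Carlo
   uncertainties.
6. **Grading** — lesion grades 0–IV: <20% of mediastinum → 0, <80% →
   I, 80–120% → II, >120% of mediastinum and <80% of liver → III,
   >120% of liver → IV; plus visual-vs-computed concordance tables.

A synthetic study generator (`synthesizeStudy()`) produces a torso
phantom with organs, lung lesions, bi-phasic uptake–washout kinetics,
system blur, Poisson noise and a limited axial FOV — with closed-form
ground truth for TIA, effective half-life and equilibrium dose — so the
whole chain is testable without any data download.

## Worked example

```r
library(voxdosim)

study <- synthesizeStudy(seed = 1, noise = TRUE, psfFwhmMm = 0)
res <- runPipeline(study,
  pipelineParams(transport = transportConfig(nHistories = 1e6, seed = 1)))

res$calibration
#> CalibrationResult: FAF 0.9366, calibration factor 29949 counts/MBq (t = 1.00 h)
```

The generator's true calibration factor is 30000 counts/MBq and its
true FAF 0.9366: the planar-based calibration recovers both to the
Poisson noise level. Organ results:

```r
merge(res$voiDose[, c("voi", "mass_g", "mean_dose_cgy_per_mbq")],
      res$halfLives[, c("voi", "t_eff_h")], by = "voi")
#>           voi mass_g mean_dose_cgy_per_mbq t_eff_h
#>         heart   92.9                 2.049    31.3
#>         liver  278.3                 2.872    46.9
#>        spleen   99.4                 0.935    40.2
#>  kidney_right   20.8                 2.437    35.8
#>   kidney_left   20.8                 2.469    36.2
#>   marrow_L2L4   33.2                 3.280    37.9
```

Each effective half-life matches the phantom's analytic
`ln 2 / (λ_bio + λ_phys)` (e.g. liver: 46.8 h) to well under a percent,
and each mean dose matches the closed-form equilibrium value within the
Monte Carlo and boundary-loss tolerance (<10%). Doses are per injected
MBq of Y-90; they are higher than clinical values because the compact
phantom concentrates the full injected activity in a 4.5 L body (see
the vignette). Lesion grading:

```r
res$grades[, c("lesion", "ratio_mediastinum", "ratio_liver", "grade")]
#>    lesion ratio_mediastinum ratio_liver grade
#>  lesion_1              4.01        2.86    IV
#>  lesion_2              1.30        0.93   III
#>  lesion_5              1.37        0.98   III
#>  lesion_8              0.18        0.13     0
#>  ...
```

`lesion_2` and `lesion_5` fall in the 80–120%-of-liver band that the
scale leaves unassigned; they are graded III and flagged
(`boundary_band`). The vignette
(`vignettes/voxel-dosimetry.Rmd`) documents the model, every numerical
convention and the generator's scope.

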