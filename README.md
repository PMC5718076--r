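# tvconcord

Concordance of tumour volume estimates across imaging modalities in
cervical cancer, on a shared voxel grid:

- **MTV** (metabolic tumour volume) from FDG-PET: the volume of voxels
  inside an operator VOI with SUV at or above *t*% of the VOI's SUVmax,
  swept over t = 20, 25, ..., 80;
- **FTV** (functional tumour volume) from diffusion-weighted MRI:
  voxel-wise mono-exponential ADC mapping
  (S_b = S0 · e^(−b·ADC), log-linear initialisation +
  Levenberg–Marquardt refinement), then either manual delineation or
  semi-automated three-class K-means clustering on the (S0, ADC)
  feature plane, keeping the intermediate-ADC/intermediate-S0 solid
  tumour cluster;
- **ATV** (anatomical tumour volume) from T2-weighted planimetry:
  per-slice delineated area × slice thickness, averaged over two
  readers;
- **concordance statistics**: per-modality cohort means, paired
  differences of means against ATV (mean ATV − mean modality), percent
  differences, two-tailed paired t tests, and Pearson product-moment
  correlations — the analysis that identifies which MTV threshold best
  agrees with the anatomical gold standard.

Because no patient images ship with the package, a synthetic phantom
module generates paired PET + DWI digital phantoms with analytic ground
truth (Gaussian uptake profiles whose percent-of-max superlevel-set
volumes are known in closed form; three-tissue DWI phantoms with
planted class masks and Rician noise), so every pipeline stage is
testable end to end.

## Worked example

```r
library(tvconcord)

cfg <- pipeline_config("phantom", n_patients = 8, master_seed = 42,
                       pet_shape = c(48, 48, 48),
                       dwi_shape = c(64, 64, 64),
                       axis_range_mm = c(12, 20))
res <- run_pipeline(cfg)
print(res$report)
```

```
Tumour volume concordance report (ATV mean 20.6 cm^3)
   modality mean_cm3 diff_cm3   pct p_paired     r p_pearson
 ftv_manual     11.3      9.2  44.9 1.65e-05 0.926  9.61e-04
   ftv_semi     11.3      9.2  44.9 1.69e-05 0.925  9.89e-04
     mtv_20     31.7    -11.2 -54.4 1.66e-05 0.999  3.97e-10
     mtv_25     25.6     -5.1 -24.7 1.16e-05 0.998  3.08e-08
     mtv_30     20.7     -0.1  -0.6 2.88e-02 1.000  2.69e-11
     mtv_35     16.7      3.8  18.7 2.56e-05 0.997  6.78e-08
     mtv_40     13.7      6.8  33.2 2.29e-05 0.999  6.93e-09
     mtv_45     11.0      9.5  46.3 1.50e-05 1.000  2.32e-10
     mtv_50      9.0     11.5  56.1 1.90e-05 0.994  4.70e-07
     mtv_55      7.1     13.4  65.2 1.71e-05 0.996  1.25e-07
     mtv_60      5.6     15.0  72.8 1.54e-05 1.000  1.41e-10
     mtv_65      4.3     16.2  78.9 2.08e-05 0.993  8.81e-07
     mtv_70      3.3     17.3  84.1 1.46e-05 0.996  2.01e-07
     mtv_75      2.4     18.1  88.1 1.74e-05 0.984  1.04e-05
     mtv_80      1.7     18.8  91.6 1.69e-05 0.990  2.29e-06
closest to ATV: mtv_30; best correlated: mtv_30
```

Reading the output: each row compares one modality against the
anatomical volume. `diff_cm3` is mean(ATV) − mean(modality), so a
positive value means the modality under-estimates the anatomical
volume; `pct` expresses the same difference relative to the ATV mean.
The metabolic means decrease monotonically with the threshold (nested
superlevel sets) and cross the ATV mean near the 30% threshold — on
this phantom cohort, as in clinical cohorts, `mtv_30` has by far the
smallest paired difference (0.1 cm³, 0.6%) and the weakest evidence of
a systematic difference, while every other modality differs from ATV
by orders of magnitude more.

Individual stages are available directly: `fit_adc()` (returns a
classed map object with `summary()` and `predict()` methods),
`mtv_sweep()`, `ftv_semi_automated()`, `kmeans_segment()`,
`build_report()`, plus NIfTI/CSV readers and writers for file-backed
cohorts (`pipeline_config("files", manifest = ...)`). A shell wrapper
lives at `inst/scripts/run_pipeline.R`.

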