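---
title: "Methods: multimodal tumour volume concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal tumour volume concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvconcord)
```

## The problem

Radiotherapy planning for cervical cancer needs a tumour volume. Three
imaging routes give three different answers: manual planimetry on
T2-weighted MRI (the anatomical volume, ATV, treated as the gold
standard), percent-of-SUVmax thresholding on FDG-PET (the metabolic
volume, MTV, one value per threshold), and segmentation of
diffusion-weighted MRI (the functional volume, FTV, manual or
clustering-based). This package implements all three measurements on a
common voxel-grid representation plus the paired statistics that decide
which comparator agrees best with ATV — and a synthetic phantom
generator so the whole chain can be validated without patient data.

All stages share two conventions. Grids are voxel-centred with axis
order (slice, row, column) and physical spacing in mm; masks must live
on the grid of the image they annotate, and mismatched grids are
rejected rather than resampled, because silent resampling hides
registration errors that the analysis could never detect afterwards.
Volumes are computed in mm³ internally and reported in cm³ (one decimal
in formatted reports, full precision in returned objects).

## Metabolic volume: percent-of-SUVmax thresholding

`suv_max()` takes the single hottest voxel inside the operator VOI — no
peak-averaging — and `mtv_at_threshold()` keeps the VOI voxels with
SUV ≥ (t/100)·SUVmax. The comparison is inclusive, so ties at the
threshold are counted. No connected-component filtering is applied: the
VOI is the spatial gate, which is exactly how the clinical workflow
avoids the adjacent urinary bladder. Two consequences are tested as
invariants: superlevel sets are nested, so the sweep
`mtv_sweep()` is non-increasing in the threshold; and thresholds are
relative, so rescaling the SUV volume by any positive constant changes
nothing.

## Functional volume: ADC mapping and tissue clustering

`fit_adc()` fits the mono-exponential decay S_b = S0·e^(−b·ADC)
independently per voxel. A log-linear regression of ln S_b on b (using
only positive samples) gives the starting point; by default a
Levenberg–Marquardt refinement then minimises the untransformed
sum-of-squares, which weights the (noisier, log-amplified) high-b tail
correctly. The refinement is vectorised: all voxels iterate
simultaneously with per-voxel damping factors, and the damped 2×2
normal equations are solved in closed form, so whole-VOI maps fit in
well under a second. Numerical choices: convergence at relative
parameter change < 1e-8 or 200 iterations (results are insensitive well
before this); ADC is floored during iteration so e^(−b·ADC) cannot
overflow; negative final ADC estimates (possible in noise) are clamped
to 0 and flagged; voxels with fewer than two positive samples are
flagged `fit_ok = FALSE` rather than aborting. Air background carries
no tissue signal, so voxels whose b = 0 signal falls below 5% (default,
configurable) of the robust maximum are skipped. ADC is kept in mm²/s
internally; the conventional ×10⁻³ scaling appears only in printed
summaries. The default 13-point b-schedule (0–1000 s/mm², dense at low
b) is a typical pelvic acquisition; it is fully replaceable and no
result depends on its exact spacing.

`kmeans_segment()` clusters the VOI voxels on the two features
(fitted S0, ADC). Raw S0 and ADC differ by roughly five orders of
magnitude, and Euclidean K-means is scale-sensitive, so each feature is
z-scored over the VOI first — this also makes the labels invariant to
any positive affine rescaling of a feature (scanner gain, unit
changes). `stats::kmeans` runs with 10 restarts by default under a
caller-supplied seed (the global RNG stream is saved and restored), and
the best solution by within-cluster sum of squares is kept; on
well-separated tissue classes every restart reaches the same optimum,
which the test suite checks across 20 seeds. When the VOI contains
exactly k distinct feature vectors the partition is computed directly
from them instead of from random restarts, which is both the optimum
and immune to duplicate initial centres.

The three clusters are mapped to tissues by ranking the
un-standardised ADC centroids: lowest → fat/fibrotic, middle → solid
tumour (high cellularity restricts diffusion to intermediate ADC at
intermediate S0), highest → normal/cystic. Exact centroid ties — a
measure-zero event on continuous data, but reachable on constructed
input — fall back to the S0 centroid, lower S0 taking the lower-ADC
role. `ftv_semi_automated()` discards the fat/fibrotic and
normal/cystic clusters and returns the tumour-cluster volume;
`ftv_manual()` is plain voxel counting of a delineated mask. Whole-VOI
(volumetric) clustering is the default; nothing in the implementation
precludes running it slice by slice, but the volumetric form uses all
the evidence at once and is what the pipeline calls.

## Anatomical volume and reader averaging

`planimetric_volume()` sums per-slice delineated areas times the slice
thickness; `mask_slice_areas()` makes the planimetric and
voxel-counting routes provably identical on a shared grid (a property
test exercises this). `reader_average()` is a plain two-value mean. In
the clinical design each reader delineated a different plane, so the
average conflates reader and plane; the operation is agnostic to this
and simply averages the two volumes it is given.

## Concordance statistics

For each comparator modality, `paired_difference()` reports
mean(ATV) − mean(modality) over complete pairs, its percent form with
mean(ATV) as denominator (the convention that reproduces the published
cohort arithmetic), and a two-tailed paired-samples t test; a Wilcoxon
signed-rank option sits behind a flag, since printed p-values alone
cannot identify which test a given study used. `pearson_correlation()`
uses the product-moment estimate with the t transform on n − 2 degrees
of freedom. No multiple-testing correction is applied across the 15
modality rows, matching the analysis this mirrors. Degenerate inputs
are explicit: all-identical differences give p = 1 (zero difference) or
NaN; zero-variance columns make the correlation an error, reported as
NA in the assembled report. `build_report()` emits one row per modality
and flags the smallest |paired difference| and the largest r.
Formatted output rounds half-away-from-zero (volumes and percents to
one decimal, r to three), the convention used when comparing against
printed tables.

## The phantom generator

The phantoms define the synthetic study conditions; they are engineered
to make every downstream quantity checkable, not to look like a pelvis.

**PET.** A Gaussian radial uptake profile
SUV(r) = bg + (peak − bg)·e^(−r²/2σ²) centred on the tumour (the
default centre sits on a voxel centre so the peak SUV is attained
exactly), inside a spherical VOI, with a high-uptake "bladder" sphere
outside the VOI that must not intersect it (a spec error otherwise).
The profile is radially monotone, so the percent-of-max superlevel set
is a sphere with radius σ√(−2 ln q) and the analytic MTV curve is
returned with the phantom. Default peak SUV 9.2 (a typical cervical
tumour SUVmax; the cohort samples uniformly from the reported 3.3–16.7
range), default grid 64³ at 2 mm. Optional additive Gaussian noise
models post-reconstruction PET noise.

**DWI.** Three tissue classes inside a spherical VOI: a central solid
tumour ellipsoid (ADC 0.934 ± 0.120 ×10⁻³ mm²/s, intermediate S0 —
values typical of cellular cervical tumours), a cystic blob plus the
VOI margin as normal/cystic tissue (2.0 ×10⁻³, high S0), and
fat/fibrotic fill (0.30 ×10⁻³, low S0). Per voxel, class-conditional
ADC and S0 are drawn once (normal, truncated at 0), noiseless signals
follow the mono-exponential model, and Rician corruption
√((S + g₁σ)² + (g₂σ)²) is applied when σ > 0 — the correct magnitude-MR
noise model, and the source of the noise-floor ADC bias the tests
bound. Default grid 96³ at 2 mm.

**Cohorts.** `generate_cohort()` samples per-patient parameters
(peak SUV, ellipsoid semi-axes, solid fraction ~ U(0.45, 0.65)) from a
single master seed through per-patient sub-seeds; reruns are
bit-identical. The PET falloff σ is calibrated per patient so the 30%
isocontour volume equals the anatomical volume. This is the one
deliberately "rigged" element, and it is the point: it plants the
mechanism under study — metabolic means that decrease with threshold
and cross the anatomical mean between adjacent thresholds — so the
end-to-end test can verify that the pipeline recovers a planted
crossing, without claiming to predict where a clinical cohort's
crossing falls.

Two phantom regimes appear in the tests. The *noiseless* regime sets
both the Rician σ and the within-class SDs to zero, making every class
a single point in feature space; segmentation must then recover the
planted partition exactly (Dice = 1, exact volumes), and the only
residual error anywhere in the chain is voxelisation, bounded by one
surface-voxel layer (4πr²·h). The *realistic* regime keeps class
heterogeneity and adds Rician noise at SNR 30; there the requirements
are statistical (tumour Dice ≥ 0.95, volume within 5%, median ADC bias
within 2%). What passing does **not** show about real data: phantoms
have no partial-volume boundary voxels, no motion or eddy-current
distortion, no spatially correlated noise, and their classes really are
three Gaussian blobs — clinical FTV segmentation is harder than this in
ways the phantom deliberately excludes.

## Problem sizes and runtime

Unit tests run phantoms at 32³–64³; the end-to-end check runs the full
29-patient cohort at the default grids (PET 64³, DWI 96³), processing
patients one at a time so memory stays flat. The whole suite completes
in about a minute on a single core; `scripts/acceptance.R` (which
re-derives the headline numbers from scratch, including the 29-patient
cohort) takes under a minute as well.

## Known limitations

- No DICOM ingestion, SUV calibration from raw counts, or PET
  reconstruction modelling: inputs are already-calibrated SUV volumes.
- Mono-exponential ADC only; IVIM/kurtosis behaviour at low b-values is
  outside the model and will bias ADC slightly on real data.
- The K-means tissue model assumes exactly three classes with ADC-ordered
  centroids; necrotic or haemorrhagic components that break the ordering
  would be mis-assigned.
- Planimetric and voxel-counting volumes ignore partial-volume effects
  at the boundary (no sub-voxel weighting).
- The paired t test is a convention; with n < 10 or heavy-tailed
  differences the Wilcoxon flag is the safer choice.
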