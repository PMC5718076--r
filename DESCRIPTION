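Package: tvconcord
Title: Concordance of PET Metabolic, DW-MRI Functional and Anatomical Tumour Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing tumour volume estimates across imaging
    modalities on a shared voxel grid: metabolic tumour volume (MTV) from
    percent-of-SUVmax thresholding of calibrated PET volumes, functional
    tumour volume (FTV) from diffusion-weighted MRI via voxel-wise
    mono-exponential ADC mapping and K-means tissue clustering on
    (S0, ADC) features, and anatomical tumour volume (ATV) from
    planimetry. Includes paired concordance statistics (differences of
    means, percent differences, paired tests, Pearson correlation) and a
    synthetic multimodal phantom generator with analytic ground truth so
    that every pipeline stage can be validated without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
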