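# Shared fixtures, all generated in code at test time.

# a small mask with `n` TRUE voxels filled in array order
make_mask <- function(n_true, shape = c(10, 10, 10), spacing = c(1, 1, 1)) {
  v <- array(FALSE, dim = shape)
  if (n_true > 0) v[seq_len(n_true)] <- TRUE
  vol_mask(v, spacing)
}

# deterministic class parameters: zero within-class spread, so the
# planted partition is exactly recoverable from noiseless data
deterministic_tissue_params <- function() {
  p <- default_tissue_params()
  for (k in seq_along(p)) {
    p[[k]]$adc_sd <- 0
    p[[k]]$s0_sd <- 0
  }
  p
}

# one-voxel-layer volume tolerance (cm^3) for a spherical isocontour of
# radius r_mm sampled at voxel size h_mm: surface area times one voxel
one_voxel_layer_cm3 <- function(r_mm, h_mm) {
  4 * pi * r_mm^2 * h_mm / 1000
}

# small DWI phantom used across tests (64^3 keeps each call well under
# a second)
small_dwi_phantom <- function(...) {
  generate_dwi_phantom(shape = c(64, 64, 64), ...)
}

# a cohort table with exactly the requested column means: per-patient
# values are mean + zero-sum perturbations so the means are exact while
# per-patient differences still vary
cohort_with_means <- function(means, n = 29, seed = 42) {
  set.seed(seed)
  cols <- lapply(names(means), function(m) {
    e <- stats::rnorm(n, 0, 0.5)
    means[[m]] + (e - mean(e))
  })
  names(cols) <- names(means)
  df <- data.frame(patient_id = sprintf("P%02d", seq_len(n)), cols)
  cohort_table(df)
}

# reference cohort-level summary means (cm^3) that the concordance
# arithmetic is checked against
reference_cohort_means <- function() {
  c(atv = 55.5, ftv_manual = 44.3, ftv_semi = 30.5,
    mtv_20 = 83.3, mtv_25 = 69.2, mtv_30 = 58.4, mtv_35 = 49.0,
    mtv_40 = 41.4, mtv_45 = 34.9, mtv_50 = 29.3, mtv_55 = 24.3,
    mtv_60 = 19.4, mtv_65 = 15.0, mtv_70 = 11.0, mtv_75 = 7.3,
    mtv_80 = 4.4)
}
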