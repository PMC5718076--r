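#' Synthetic PET hot-spot phantom with analytic MTV curve
#'
#' A digital phantom emulating a focal hypermetabolic cervical lesion on
#' calibrated PET: a smooth Gaussian radial uptake profile
#' \eqn{SUV(r) = bg + (peak - bg) e^{-r^2 / 2\sigma^2}} centred on the
#' tumour, sitting in a low background, plus a nearby high-uptake
#' confounder sphere (the "bladder") that must stay outside the VOI.
#' The VOI is a sphere centred on the tumour. Because the noiseless
#' profile is radially monotone, the percent-of-SUVmax superlevel-set
#' volume has a closed form, which is returned alongside the voxelised
#' data as the analytic truth for the MTV sweep.
#'
#' @param shape grid dimensions (default 64 x 64 x 64).
#' @param spacing voxel spacing in mm (default 2 mm isotropic).
#' @param centre tumour centre in mm (default: grid centre).
#' @param peak_suv peak tumour SUV (default 9.2, a typical cervical
#'   tumour SUVmax).
#' @param background_suv background SUV, must be below
#'   \code{peak_suv * min(thresholds)/100} for the closed form to remain
#'   a simple sphere (default 0).
#' @param sigma_mm radial falloff scale of the uptake profile in mm.
#' @param voi_radius_mm radius of the spherical VOI; default 1.35 times
#'   the 20 percent isocontour radius so the whole default sweep lies
#'   inside the VOI.
#' @param confounder list with \code{centre} (mm), \code{radius_mm} and
#'   \code{suv}; \code{NULL} to omit. Default: a 15 mm sphere at 3x the
#'   peak SUV placed beyond the VOI.
#' @param noise_sd additive Gaussian noise SD in SUV units (default 0;
#'   PET reconstruction noise is approximately Gaussian post-smoothing).
#' @param thresholds percent thresholds for the analytic truth curve.
#' @param seed RNG seed used when \code{noise_sd > 0}.
#' @return A list of class \code{pet_phantom}: \code{pet}
#'   (\code{\link{image_volume}}), \code{voi} (\code{\link{vol_mask}}),
#'   \code{truth_mtv} (data.frame threshold_percent, volume_cm3 from the
#'   closed form), and \code{params}.
#' @export
generate_pet_phantom <- function(shape = c(64, 64, 64),
                                 spacing = c(2, 2, 2),
                                 centre = NULL,
                                 peak_suv = 9.2,
                                 background_suv = 0,
                                 sigma_mm = 12,
                                 voi_radius_mm = NULL,
                                 confounder = NULL,
                                 noise_sd = 0,
                                 thresholds = seq(20, 80, by = 5),
                                 seed = 1L) {
  spacing <- check_spacing(spacing)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (!(peak_suv > background_suv) || background_suv < 0 || sigma_mm <= 0)
    stop("need peak_suv > background_suv >= 0 and sigma_mm > 0",
         call. = FALSE)
  fov <- shape * spacing
  # default centre sits on a voxel centre so the profile peak (and hence
  # the exact peak SUV) is attained by a voxel
  if (is.null(centre)) centre <- (ceiling(shape / 2) - 0.5) * spacing
  if (is.null(voi_radius_mm))
    voi_radius_mm <- 1.35 * sigma_mm * sqrt(-2 * log(min(thresholds) / 100))
  if (is.null(confounder))
    confounder <- list(centre = centre + c(voi_radius_mm + 18, 0, 0),
                       radius_mm = 15, suv = 3 * peak_suv)

  if (!is.null(confounder)) {
    gap <- sqrt(sum((confounder$centre - centre)^2))
    if (gap <= voi_radius_mm + confounder$radius_mm)
      stop("confounder sphere intersects the VOI", call. = FALSE)
  }

  r2 <- radial_dist2(shape, spacing, centre)
  suv <- background_suv +
    (peak_suv - background_suv) * exp(-r2 / (2 * sigma_mm^2))
  if (!is.null(confounder)) {
    rc2 <- radial_dist2(shape, spacing, confounder$centre)
    suv[rc2 <= confounder$radius_mm^2] <- confounder$suv
  }
  if (noise_sd > 0)
    suv <- suv + with_seed(seed, array(stats::rnorm(length(suv), 0,
                                                    noise_sd), dim = shape))

  voi <- vol_mask(array(r2 <= voi_radius_mm^2, dim = shape), spacing)

  truth <- data.frame(
    threshold_percent = as.numeric(thresholds),
    volume_cm3 = analytic_mtv(thresholds, peak_suv, background_suv,
                              sigma_mm, voi_radius_mm))

  structure(list(pet = image_volume(suv, spacing), voi = voi,
                 truth_mtv = truth,
                 params = list(shape = shape, spacing = spacing,
                               centre = centre, peak_suv = peak_suv,
                               background_suv = background_suv,
                               sigma_mm = sigma_mm,
                               voi_radius_mm = voi_radius_mm,
                               confounder = confounder,
                               noise_sd = noise_sd, seed = seed)),
            class = "pet_phantom")
}

# Closed-form superlevel-set volume of the noiseless Gaussian profile:
# voxels with SUV >= t% of peak form the sphere of radius
# r_t = sigma * sqrt(-2 log(q)), q = (t*peak/100 - bg) / (peak - bg),
# truncated by the VOI sphere. If the threshold falls at or below the
# background the whole VOI qualifies.
analytic_mtv <- function(thresholds, peak, bg, sigma, voi_radius) {
  vapply(thresholds, function(t) {
    lev <- t / 100 * peak
    if (lev <= bg) return(4 / 3 * pi * voi_radius^3 / 1000)
    q <- (lev - bg) / (peak - bg)
    r <- if (q >= 1) 0 else sigma * sqrt(-2 * log(q))
    4 / 3 * pi * min(r, voi_radius)^3 / 1000
  }, numeric(1))
}

# squared distance (mm^2) of every voxel centre from a point;
# voxel i (1-based) is centred at (i - 0.5) * spacing
radial_dist2 <- function(shape, spacing, centre) {
  ax <- lapply(1:3, function(k)
    ((seq_len(shape[k]) - 0.5) * spacing[k] - centre[k])^2)
  outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
}

# solid ellipsoid indicator around a centre (mm), semi-axes in mm
ellipsoid_mask <- function(shape, spacing, centre, semi_axes) {
  ax <- lapply(1:3, function(k)
    (((seq_len(shape[k]) - 0.5) * spacing[k] - centre[k]) /
       semi_axes[k])^2)
  outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+") <= 1
}

#' Synthetic three-tissue DWI phantom
#'
#' A multi-b-value DWI phantom emulating a heterogeneous cervical tumour
#' and its surroundings inside an operator-style VOI. The VOI (sphere)
#' contains three tissue classes with the canonical (S0, ADC) structure:
#' solid tumour (intermediate ADC, intermediate S0) as a central
#' ellipsoid; normal/cystic tissue (high ADC, high S0) as an offset
#' spherical blob plus the VOI margin outside the anatomical tumour; and
#' fat/fibrotic tissue (low ADC, low S0) filling the rest of the
#' anatomical tumour. Per voxel, class-conditional ADC and S0 are drawn
#' once from truncated normal distributions, noiseless signals follow
#' the mono-exponential model at every scheduled b-value, and Rician
#' corruption \eqn{\tilde S = \sqrt{(S + g_1\sigma)^2 + (g_2\sigma)^2}}
#' with independent unit normals is applied when \code{rician_sigma > 0}.
#'
#' @param shape grid dimensions (default 96^3).
#' @param spacing voxel spacing in mm (default 2 mm isotropic; axial DWI
#'   of the pelvis is typically 1.5-4 mm).
#' @param centre tumour centre in mm (default grid centre).
#' @param anat_semi_axes semi-axes (mm) of the anatomical tumour
#'   ellipsoid whose voxel volume is the planted ATV.
#' @param solid_fraction fraction of the anatomical volume occupied by
#'   the solid tumour class (isotropically shrunken ellipsoid).
#' @param cyst list with \code{offset} (mm, relative to centre) and
#'   \code{radius_mm} for the cystic blob; \code{"auto"} (default)
#'   scales the blob to the tumour; \code{NULL} omits it.
#' @param voi_margin VOI radius as a multiple of the largest anatomical
#'   semi-axis (default 1.2).
#' @param class_params per-class list of \code{adc_mean}, \code{adc_sd}
#'   (mm^2/s), \code{s0_mean}, \code{s0_sd}. Defaults: fat/fibrotic
#'   (0.30e-3, 50), tumour (0.934e-3, 120), normal/cystic (2.0e-3, 240),
#'   the tumour ADC matching typical cervical-cancer values.
#' @param b_values b-value schedule (default
#'   \code{\link{default_b_values}}).
#' @param rician_sigma Rician noise scale in signal units (0 =
#'   noiseless).
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return A list of class \code{dwi_phantom}: \code{dwi}
#'   (\code{\link{dwi_series}}), \code{voi}, \code{anat_mask}, per-class
#'   \code{truth} masks, \code{truth_volumes} (cm^3, incl. \code{atv}),
#'   \code{adc_truth}/\code{s0_truth} maps and \code{params}.
#' @export
generate_dwi_phantom <- function(shape = c(96, 96, 96),
                                 spacing = c(2, 2, 2),
                                 centre = NULL,
                                 anat_semi_axes = c(24, 21, 21),
                                 solid_fraction = 0.55,
                                 cyst = "auto",
                                 voi_margin = 1.2,
                                 class_params = NULL,
                                 b_values = default_b_values(),
                                 rician_sigma = 0,
                                 seed = 1L) {
  spacing <- check_spacing(spacing)
  shape <- as.integer(shape)
  fov <- shape * spacing
  if (is.null(centre)) centre <- fov / 2
  if (is.null(class_params)) class_params <- default_tissue_params()
  stopifnot(identical(names(class_params), tissue_classes))
  adc_means <- vapply(class_params, `[[`, numeric(1), "adc_mean")
  if (!(adc_means[1] < adc_means[2] && adc_means[2] < adc_means[3]))
    stop("class ADC means must be strictly ordered ",
         "fat_fibrotic < tumour < normal_cystic", call. = FALSE)
  if (solid_fraction <= 0 || solid_fraction >= 1)
    stop("solid_fraction must lie in (0, 1)", call. = FALSE)

  anat <- ellipsoid_mask(shape, spacing, centre, anat_semi_axes)
  voi_radius <- voi_margin * max(anat_semi_axes)
  voi <- radial_dist2(shape, spacing, centre) <= voi_radius^2
  if (!all(voi | !anat))
    stop("anatomical tumour extends beyond the VOI; increase voi_margin",
         call. = FALSE)

  solid <- ellipsoid_mask(shape, spacing, centre,
                          anat_semi_axes * solid_fraction^(1 / 3))
  if (identical(cyst, "auto"))
    # default cystic blob scales with the tumour so any lesion size works
    cyst <- list(offset = c(0, 0.55 * anat_semi_axes[2], 0),
                 radius_mm = 0.4 * min(anat_semi_axes))
  cystic <- array(FALSE, dim = shape)
  if (!is.null(cyst)) {
    cyst_centre <- centre + cyst$offset
    if (sqrt(sum(cyst$offset^2)) + cyst$radius_mm > voi_radius)
      stop("cystic blob extends beyond the VOI", call. = FALSE)
    cystic <- radial_dist2(shape, spacing, cyst_centre) <=
      cyst$radius_mm^2
  }
  # precedence: solid tumour > cyst > fat/fibrotic; VOI margin outside
  # the anatomical tumour is normal tissue (same class as cystic)
  cls <- array(0L, dim = shape)           # 0 = background (outside VOI)
  cls[voi] <- 3L                          # normal/cystic margin
  cls[anat] <- 1L                         # fat/fibrotic fill
  cls[cystic & anat] <- 3L
  cls[solid] <- 2L

  truth <- list(
    fat_fibrotic = vol_mask(cls == 1L, spacing),
    tumour = vol_mask(cls == 2L, spacing),
    normal_cystic = vol_mask(cls == 3L, spacing))

  nvox <- prod(shape)
  draws <- with_seed(seed, {
    adc <- numeric(nvox); s0 <- numeric(nvox)
    for (k in 1:3) {
      sel <- which(cls == k)
      p <- class_params[[tissue_classes[k]]]
      adc[sel] <- pmax(stats::rnorm(length(sel), p$adc_mean, p$adc_sd), 0)
      s0[sel] <- pmax(stats::rnorm(length(sel), p$s0_mean, p$s0_sd), 0)
    }
    noise <- if (rician_sigma > 0)
      stats::rnorm(2 * nvox * length(b_values), 0, rician_sigma)
    else NULL
    list(adc = adc, s0 = s0, noise = noise)
  })

  sig <- array(0, dim = c(length(b_values), shape))
  for (i in seq_along(b_values))
    sig[i, , , ] <- draws$s0 * exp(-b_values[i] * draws$adc)
  if (rician_sigma > 0) {
    half <- nvox * length(b_values)
    g1 <- draws$noise[seq_len(half)]
    g2 <- draws$noise[half + seq_len(half)]
    # noise arrays in (b, x, y, z) order to match sig's layout
    sig <- sqrt((sig + array(g1, dim = dim(sig)))^2 +
                  array(g2, dim = dim(sig))^2)
  }

  vox_cm3 <- prod(spacing) / 1000
  truth_volumes <- c(vapply(truth, voxel_count_volume, numeric(1)),
                     atv = sum(anat) * vox_cm3,
                     voi = sum(voi) * vox_cm3)

  structure(list(
    dwi = dwi_series(sig, b_values, spacing),
    voi = vol_mask(voi, spacing),
    anat_mask = vol_mask(anat, spacing),
    truth = truth,
    truth_volumes = truth_volumes,
    adc_truth = array(draws$adc, dim = shape),
    s0_truth = array(draws$s0, dim = shape),
    params = list(shape = shape, spacing = spacing, centre = centre,
                  anat_semi_axes = anat_semi_axes,
                  solid_fraction = solid_fraction, cyst = cyst,
                  voi_radius = voi_radius, class_params = class_params,
                  b_values = b_values, rician_sigma = rician_sigma,
                  seed = seed)),
    class = "dwi_phantom")
}

#' Default three-tissue (S0, ADC) parameters
#'
#' Class-conditional means and SDs used by the DWI phantom: low ADC/low
#' S0 fat and fibrotic tissue, intermediate ADC/intermediate S0 solid
#' tumour (ADC 0.934e-3 +/- 0.120e-3 mm^2/s, typical of cellular
#' cervical tumours), and high ADC/high S0 normal or cystic tissue.
#'
#' @return Named list of per-class parameter lists.
#' @export
default_tissue_params <- function() {
  list(
    fat_fibrotic = list(adc_mean = 0.30e-3, adc_sd = 0.05e-3,
                        s0_mean = 60, s0_sd = 6),
    tumour = list(adc_mean = 0.934e-3, adc_sd = 0.120e-3,
                  s0_mean = 120, s0_sd = 12),
    normal_cystic = list(adc_mean = 2.0e-3, adc_sd = 0.25e-3,
                         s0_mean = 240, s0_sd = 24))
}

#' Generate a synthetic multimodal cohort with known truth
#'
#' Draws \code{n_patients} paired PET + DWI phantoms with per-patient
#' parameters sampled from realistic ranges (peak SUV uniform in
#' 3.3-16.7, the SUVmax range of cervical tumours; anatomical ellipsoid
#' semi-axes uniform in \code{axis_range_mm}; solid-tumour fraction
#' uniform in \code{solid_fraction_range}). The PET falloff scale is
#' calibrated per patient so the 30 percent isocontour volume equals the
#' anatomical volume — the mechanism by which the metabolic sweep
#' crosses the anatomical mean between adjacent thresholds. All
#' randomness flows from \code{master_seed} through per-patient
#' sub-seeds, so cohorts are fully reproducible.
#'
#' @param n_patients cohort size (>= 2; the reference design uses 29).
#' @param master_seed integer master seed.
#' @param axis_range_mm range for anatomical semi-axes (default 15-28).
#' @param suv_range peak SUV range (default c(3.3, 16.7)).
#' @param solid_fraction_range range for the solid-tumour volume
#'   fraction (default 0.45-0.65).
#' @param cross_threshold percent threshold whose isocontour is
#'   calibrated to the anatomical volume (default 30).
#' @param pet_shape,pet_spacing PET grid (default 64^3 at 2 mm).
#' @param dwi_shape,dwi_spacing DWI grid (default 96^3 at 2 mm).
#' @param rician_sigma DWI Rician noise scale (default 0).
#' @param pet_noise_sd PET Gaussian noise SD (default 0).
#' @param thresholds MTV threshold percents.
#' @return A list of class \code{phantom_cohort}: \code{patients} (list
#'   of per-patient bundles with \code{pet_phantom} and
#'   \code{dwi_phantom}), and \code{truth_table} — a
#'   \code{\link{cohort_table}} of planted/analytic volumes (ATV and
#'   FTVs from voxel counts, MTVs from the closed form).
#' @export
generate_cohort <- function(n_patients = 29, master_seed = 1L,
                            axis_range_mm = c(15, 28),
                            suv_range = c(3.3, 16.7),
                            solid_fraction_range = c(0.45, 0.65),
                            cross_threshold = 30,
                            pet_shape = c(64, 64, 64),
                            pet_spacing = c(2, 2, 2),
                            dwi_shape = c(96, 96, 96),
                            dwi_spacing = c(2, 2, 2),
                            rician_sigma = 0,
                            pet_noise_sd = 0,
                            class_params = NULL,
                            thresholds = seq(20, 80, by = 5)) {
  spec <- cohort_spec(n_patients = n_patients, master_seed = master_seed,
                      axis_range_mm = axis_range_mm,
                      suv_range = suv_range,
                      solid_fraction_range = solid_fraction_range,
                      cross_threshold = cross_threshold,
                      pet_shape = pet_shape, pet_spacing = pet_spacing,
                      dwi_shape = dwi_shape, dwi_spacing = dwi_spacing,
                      rician_sigma = rician_sigma,
                      pet_noise_sd = pet_noise_sd,
                      class_params = class_params,
                      thresholds = thresholds)
  patients <- vector("list", n_patients)
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    patients[[i]] <- generate_patient_bundle(spec, i)
    rows[[i]] <- patients[[i]]$truth_row
  }
  truth_table <- cohort_table(do.call(rbind, rows), thresholds)
  structure(list(patients = patients, truth_table = truth_table,
                 params = list(n_patients = n_patients,
                               master_seed = master_seed,
                               thresholds = thresholds,
                               rician_sigma = rician_sigma,
                               pet_noise_sd = pet_noise_sd)),
            class = "phantom_cohort")
}

# Frozen per-patient parameter draws for a cohort: everything downstream
# (bundle generation, the streaming pipeline) derives deterministically
# from this table, so patients can be regenerated one at a time without
# holding the whole cohort's images in memory.
cohort_spec <- function(n_patients, master_seed, axis_range_mm, suv_range,
                        solid_fraction_range, cross_threshold, pet_shape,
                        pet_spacing, dwi_shape, dwi_spacing, rician_sigma,
                        pet_noise_sd, thresholds, class_params = NULL) {
  if (n_patients < 2)
    stop("a cohort needs at least 2 patients", call. = FALSE)
  pars <- with_seed(master_seed, {
    data.frame(
      patient_id = sprintf("P%02d", seq_len(n_patients)),
      peak_suv = stats::runif(n_patients, suv_range[1], suv_range[2]),
      a = stats::runif(n_patients, axis_range_mm[1], axis_range_mm[2]),
      b = stats::runif(n_patients, axis_range_mm[1], axis_range_mm[2]),
      c = stats::runif(n_patients, axis_range_mm[1], axis_range_mm[2]),
      solid_fraction = stats::runif(n_patients, solid_fraction_range[1],
                                    solid_fraction_range[2]),
      sub_seed = sample.int(.Machine$integer.max - 1L, n_patients),
      stringsAsFactors = FALSE)
  })
  list(pars = pars, cross_threshold = cross_threshold,
       pet_shape = pet_shape, pet_spacing = pet_spacing,
       dwi_shape = dwi_shape, dwi_spacing = dwi_spacing,
       rician_sigma = rician_sigma, pet_noise_sd = pet_noise_sd,
       thresholds = thresholds, class_params = class_params)
}

# Generate the i-th patient's paired PET + DWI phantoms and truth row.
generate_patient_bundle <- function(spec, i) {
  p <- spec$pars[i, ]
  axes <- c(p$a, p$b, p$c)
  # equivalent sphere radius of the anatomical ellipsoid; the PET
  # profile's cross_threshold isocontour is placed at this radius
  r_eq <- prod(axes)^(1 / 3)
  sigma <- r_eq / sqrt(-2 * log(spec$cross_threshold / 100))
  pet <- generate_pet_phantom(
    shape = spec$pet_shape, spacing = spec$pet_spacing,
    peak_suv = p$peak_suv, background_suv = 0, sigma_mm = sigma,
    noise_sd = spec$pet_noise_sd, thresholds = spec$thresholds,
    seed = p$sub_seed)
  dwi <- generate_dwi_phantom(
    shape = spec$dwi_shape, spacing = spec$dwi_spacing,
    anat_semi_axes = axes, solid_fraction = p$solid_fraction,
    class_params = spec$class_params,
    rician_sigma = spec$rician_sigma, seed = p$sub_seed + 1L)
  mtv <- stats::setNames(pet$truth_mtv$volume_cm3,
                         paste0("mtv_", spec$thresholds))
  truth_row <- data.frame(
    patient_id = p$patient_id,
    atv = unname(dwi$truth_volumes["atv"]),
    ftv_manual = unname(dwi$truth_volumes["tumour"]),
    ftv_semi = unname(dwi$truth_volumes["tumour"]),
    t(mtv), stringsAsFactors = FALSE)
  list(patient_id = p$patient_id, pet_phantom = pet, dwi_phantom = dwi,
       truth_row = truth_row)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x$patients),
      " synthetic patients (master seed ", x$params$master_seed, ")\n",
      sep = "")
  cat(sprintf("  truth ATV mean: %.1f cm^3\n",
              mean(x$truth_table$atv)))
  invisible(x)
}
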