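#' Pipeline configuration
#'
#' Assembles and validates the configuration for
#' \code{\link{run_pipeline}}. Two modes are supported: \code{"phantom"}
#' (a synthetic cohort generated from a master seed) and \code{"files"}
#' (per-patient NIfTI/bval inputs listed in a manifest CSV).
#'
#' @param mode \code{"phantom"} or \code{"files"}.
#' @param n_patients phantom-mode cohort size.
#' @param master_seed phantom-mode master seed; also seeds the K-means
#'   restarts.
#' @param thresholds MTV threshold percents.
#' @param kmeans_n_init K-means restarts.
#' @param rician_sigma phantom-mode DWI Rician noise scale.
#' @param pet_noise_sd phantom-mode PET Gaussian noise SD.
#' @param manifest files-mode manifest CSV: columns patient_id, pet,
#'   pet_voi, dwi, bvals, dwi_voi, tumour_mask, anat_mask (paths).
#' @param out_dir output directory for table3.csv / table4.csv /
#'   cohort.csv; \code{NULL} writes nothing.
#' @param ... overrides passed to \code{\link{generate_cohort}} in
#'   phantom mode (grid shapes, parameter ranges, ...).
#' @return A validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mode = c("phantom", "files"),
                            n_patients = 29, master_seed = 1L,
                            thresholds = seq(20, 80, by = 5),
                            kmeans_n_init = 10L,
                            rician_sigma = 0, pet_noise_sd = 0,
                            manifest = NULL, out_dir = NULL, ...) {
  mode <- match.arg(mode)
  if (any(thresholds <= 0 | thresholds > 100))
    stop("thresholds must lie in (0, 100]", call. = FALSE)
  if (mode == "files") {
    if (is.null(manifest))
      stop("files mode needs a manifest CSV", call. = FALSE)
    if (!file.exists(manifest))
      stop("manifest not found: ", manifest, call. = FALSE)
  }
  structure(list(mode = mode, n_patients = n_patients,
                 master_seed = as.integer(master_seed),
                 thresholds = thresholds,
                 kmeans_n_init = as.integer(kmeans_n_init),
                 rician_sigma = rician_sigma,
                 pet_noise_sd = pet_noise_sd,
                 manifest = manifest, out_dir = out_dir,
                 extra = list(...)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{pipeline_config}}.
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file's values.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  if (!is.null(cfg$thresholds)) cfg$thresholds <- unlist(cfg$thresholds)
  do.call(pipeline_config, cfg)
}

#' Run the end-to-end volume-concordance pipeline
#'
#' For every patient: fit the mono-exponential ADC model to the DWI
#' series, compute the semi-automated FTV by three-class K-means on the
#' fitted (S0, ADC) features, the manual FTV and ATV by planimetry of
#' the supplied masks, and the MTV sweep on the PET volume; then
#' assemble the per-patient cohort table and build the concordance
#' report. All seeds derive from the configuration, so outputs are
#' byte-identical across reruns with the same config. In phantom mode
#' patients are generated and processed one at a time (memory stays
#' flat) and the planted truth table is attached to the result.
#'
#' @param config a \code{\link{pipeline_config}} (or a YAML path).
#' @param verbose log per-patient progress to stderr (default FALSE).
#' @return A list of class \code{pipeline_result}: \code{cohort}
#'   (measured \code{\link{cohort_table}}), \code{report}
#'   (\code{\link{build_report}} output), and in phantom mode
#'   \code{truth_table}. If \code{out_dir} is set, writes cohort.csv,
#'   table3.csv (means/differences/p) and table4.csv (correlations).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (verbose) message(sprintf(...))

  if (config$mode == "phantom") {
    spec <- do.call(cohort_spec, c(list(
      n_patients = config$n_patients,
      master_seed = config$master_seed,
      cross_threshold = 30,
      rician_sigma = config$rician_sigma,
      pet_noise_sd = config$pet_noise_sd,
      thresholds = config$thresholds),
      modifyList(list(axis_range_mm = c(15, 28),
                      suv_range = c(3.3, 16.7),
                      solid_fraction_range = c(0.45, 0.65),
                      pet_shape = c(64, 64, 64),
                      pet_spacing = c(2, 2, 2),
                      dwi_shape = c(96, 96, 96),
                      dwi_spacing = c(2, 2, 2)),
                 config$extra)))
    n <- config$n_patients
    rows <- vector("list", n)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      bundle <- generate_patient_bundle(spec, i)
      rows[[i]] <- tryCatch(
        process_patient(bundle$patient_id,
                        pet = bundle$pet_phantom$pet,
                        pet_voi = bundle$pet_phantom$voi,
                        dwi = bundle$dwi_phantom$dwi,
                        dwi_voi = bundle$dwi_phantom$voi,
                        tumour_mask = bundle$dwi_phantom$truth$tumour,
                        anat_mask = bundle$dwi_phantom$anat_mask,
                        config = config),
        error = function(e) stop("patient ", bundle$patient_id,
                                 " failed at pipeline stage: ",
                                 conditionMessage(e), call. = FALSE))
      truth_rows[[i]] <- bundle$truth_row
      log_msg("processed %s (%d/%d)", bundle$patient_id, i, n)
    }
    truth_table <- cohort_table(do.call(rbind, truth_rows),
                                config$thresholds)
  } else {
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    need <- c("patient_id", "pet", "pet_voi", "dwi", "bvals", "dwi_voi",
              "tumour_mask", "anat_mask")
    if (!all(need %in% names(man)))
      stop("manifest needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    rows <- lapply(seq_len(nrow(man)), function(i) {
      m <- man[i, ]
      tryCatch(
        process_patient(m$patient_id,
                        pet = read_image_nifti(m$pet),
                        pet_voi = read_mask_nifti(m$pet_voi),
                        dwi = read_dwi_nifti(m$dwi, m$bvals),
                        dwi_voi = read_mask_nifti(m$dwi_voi),
                        tumour_mask = read_mask_nifti(m$tumour_mask),
                        anat_mask = read_mask_nifti(m$anat_mask),
                        config = config),
        error = function(e) stop("patient ", m$patient_id,
                                 " failed at pipeline stage: ",
                                 conditionMessage(e), call. = FALSE))
    })
    truth_table <- NULL
  }

  cohort <- cohort_table(do.call(rbind, rows), config$thresholds)
  report <- build_report(cohort, config$thresholds)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                     row.names = FALSE)
    write_report_csvs(report, config$out_dir, config$master_seed)
  }

  structure(list(cohort = cohort, report = report,
                 truth_table = truth_table, config = config),
            class = "pipeline_result")
}

# One patient through every stage; seeds derive from the config master
# seed and the patient id so results do not depend on processing order.
process_patient <- function(patient_id, pet, pet_voi, dwi, dwi_voi,
                            tumour_mask, anat_mask, config) {
  fit <- fit_adc(dwi, mask = dwi_voi)
  km_seed <- (config$master_seed +
                strtoi(sub("^P", "", patient_id), base = 36L)) %%
    .Machine$integer.max
  ftv_semi <- ftv_semi_automated(dwi_voi, fit$s0, fit$adc,
                                 seed = km_seed,
                                 n_init = config$kmeans_n_init)
  ftv_man <- planimetric_volume(mask_slice_areas(tumour_mask))
  atv <- planimetric_volume(mask_slice_areas(anat_mask))
  sweep <- mtv_sweep(pet, pet_voi, config$thresholds)
  row <- data.frame(patient_id = patient_id, atv = atv,
                    ftv_manual = ftv_man,
                    ftv_semi = as.numeric(ftv_semi),
                    stringsAsFactors = FALSE)
  row[paste0("mtv_", config$thresholds)] <- as.list(sweep$volumes_cm3)
  row
}

write_report_csvs <- function(report, out_dir, seed) {
  t3 <- data.frame(modality = report$modality,
                   mean_cm3 = round_half_up(report$mean_cm3, 1),
                   paired_diff_cm3 = round_half_up(report$paired_diff_cm3, 1),
                   pct_diff = round_half_up(report$pct_diff, 1),
                   p_paired = signif(report$p_paired, 3))
  t4 <- data.frame(modality = report$modality,
                   pearson_r = round_half_up(report$pearson_r, 3),
                   p_pearson = signif(report$p_pearson, 3))
  for (f in c("table3.csv", "table4.csv")) {
    con <- file(file.path(out_dir, f), "w")
    writeLines(sprintf("# atv_mean_cm3,%.6g # seed,%d",
                       attr(report, "atv_mean"), seed), con)
    utils::write.csv(if (f == "table3.csv") t3 else t4, con,
                     row.names = FALSE)
    close(con)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$cohort), " patients (mode: ",
      x$config$mode, ")\n", sep = "")
  print(x$report)
  invisible(x)
}
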