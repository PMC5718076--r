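#' Read a 3D image volume from NIfTI
#'
#' Voxel spacing is taken from the header pixdim zooms (mm).
#'
#' @param path path to a .nii or .nii.gz file.
#' @return An \code{\link{image_volume}}.
#' @export
read_image_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  image_volume(vals, RNifti::pixdim(img)[1:3])
}

#' Read a boolean mask from NIfTI
#'
#' Any strictly positive voxel value counts as inside the mask.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return A \code{\link{vol_mask}}.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI mask: ", path, call. = FALSE)
  vol_mask(vals > 0, RNifti::pixdim(img)[1:3])
}

#' Read a 4D DWI series from NIfTI plus a b-value sidecar
#'
#' The NIfTI stores volumes with the b-value on the fourth axis (the
#' on-disk convention); internally the b-value axis comes first. The
#' sidecar is FSL-style bval text: whitespace- or newline-separated
#' values, in s/mm^2.
#'
#' @param path path to the 4D NIfTI.
#' @param bval_path path to the b-value text file.
#' @return A \code{\link{dwi_series}}.
#' @export
read_dwi_nifti <- function(path, bval_path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 4L)
    stop("expected a 4D NIfTI series: ", path, call. = FALSE)
  b <- read_bvals(bval_path)
  dwi_series(aperm(vals, c(4, 1, 2, 3)), b, RNifti::pixdim(img)[1:3])
}

#' Read an FSL-style b-value file
#'
#' @param path text file of b-values, one row or one value per line.
#' @return Numeric vector of b-values in s/mm^2.
#' @export
read_bvals <- function(path) {
  as.numeric(scan(path, what = numeric(), quiet = TRUE))
}

#' Write a volume, mask or map to NIfTI
#'
#' @param x an \code{\link{image_volume}}, \code{\link{vol_mask}} or a
#'   plain 3D array (then \code{spacing} is required).
#' @param path output .nii or .nii.gz path.
#' @param spacing voxel spacing in mm for plain arrays.
#' @return The path, invisibly.
#' @export
write_nifti_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, c("image_volume", "vol_mask"))) {
    vals <- x$values
    spacing <- x$spacing
  } else {
    vals <- x
    spacing <- check_spacing(spacing)
  }
  if (is.logical(vals)) storage.mode(vals) <- "integer"
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a DWI series to NIfTI plus a bval sidecar
#'
#' @param series a \code{\link{dwi_series}}.
#' @param path output 4D NIfTI path.
#' @param bval_path output b-value text path.
#' @return The NIfTI path, invisibly.
#' @export
write_dwi_nifti <- function(series, path, bval_path) {
  stopifnot(inherits(series, "dwi_series"))
  vals <- aperm(series$values, c(2, 3, 4, 1))
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- c(series$spacing, 1)
  RNifti::writeNifti(img, path)
  writeLines(paste(format(series$b_values, trim = TRUE,
                          scientific = FALSE), collapse = " "),
             bval_path)
  invisible(path)
}

#' Read a slice-area series from CSV
#'
#' Expects columns \code{slice_index} and \code{area_mm2}; the slice
#' thickness is supplied separately (it is an acquisition constant, not
#' a per-slice quantity).
#'
#' @param path CSV path.
#' @param thickness_mm slice thickness in mm.
#' @return A \code{\link{slice_area_series}}.
#' @export
read_slice_areas_csv <- function(path, thickness_mm) {
  df <- utils::read.csv(path)
  need <- c("slice_index", "area_mm2")
  if (!all(need %in% names(df)))
    stop("slice-area CSV needs columns slice_index, area_mm2",
         call. = FALSE)
  df <- df[order(df$slice_index), ]
  slice_area_series(df$area_mm2, thickness_mm)
}

#' Read a per-patient cohort volume table from CSV
#'
#' @param path CSV with header patient_id, atv, ftv_manual, ftv_semi,
#'   mtv_20, ..., mtv_80 (volumes in cm^3; empty cells allowed).
#' @param thresholds expected MTV threshold percents.
#' @return A validated \code{\link{cohort_table}}.
#' @export
read_cohort_csv <- function(path, thresholds = seq(20, 80, by = 5)) {
  cohort_table(utils::read.csv(path), thresholds)
}

#' Write an MTV sweep to CSV
#'
#' Columns threshold_percent and volume_cm3, preceded by a comment
#' header line carrying the SUVmax.
#'
#' @param sweep an \code{\link{mtv_sweep}}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_mtv_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "mtv_sweep"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# suv_max,%.6g", sweep$suv_max), con)
  utils::write.csv(as.data.frame(sweep), con, row.names = FALSE)
  invisible(path)
}
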