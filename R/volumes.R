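#' Construct a 3D image volume
#'
#' The common currency of every stage of the pipeline: a 3D scalar grid
#' (SUV units for PET, arbitrary signal units for MRI) together with its
#' physical voxel spacing in mm. Axis order is (slice, row, column) and
#' grids are voxel-centred; no world-coordinate transforms are applied,
#' so masks must live on the same grid as the image they annotate.
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing numeric length-3 vector, per-axis voxel edge length in mm.
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(values, spacing) {
  values <- check_grid(values, "values")
  spacing <- check_spacing(spacing)
  structure(list(values = values, spacing = spacing,
                 axis_order = "slice-row-column"),
            class = "image_volume")
}

#' Construct a boolean mask on an image grid
#'
#' @param values logical (or coercible) 3D array; \code{TRUE} marks voxels
#'   inside the region.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return An object of class \code{vol_mask}.
#' @export
vol_mask <- function(values, spacing) {
  values <- check_grid(values, "values")
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask contains NA values", call. = FALSE)
  spacing <- check_spacing(spacing)
  structure(list(values = values, spacing = spacing,
                 axis_order = "slice-row-column"),
            class = "vol_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(format(x$spacing), collapse = " x "), " mm\n",
      "  range: [", format(min(x$values)), ", ", format(max(x$values)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.vol_mask <- function(x, ...) {
  cat("<vol_mask> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(format(x$spacing), collapse = " x "), " mm; ",
      sum(x$values), " voxels inside (",
      format(voxel_count_volume(x), digits = 4), " cm^3)\n", sep = "")
  invisible(x)
}

check_grid <- function(values, what) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop(sprintf("'%s' must be a 3D array", what), call. = FALSE)
  if (any(dim(values) < 1L))
    stop(sprintf("'%s' needs at least one voxel per axis", what), call. = FALSE)
  values
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("spacing must be 3 positive voxel edge lengths in mm",
         call. = FALSE)
  spacing
}

# Masks on mismatched grids are rejected, never resampled: silent
# resampling would hide registration errors the analysis cannot detect.
check_same_grid <- function(image, mask) {
  if (!identical(dim(image$values), dim(mask$values)))
    stop("mask and image grids differ in shape; resampling is not supported",
         call. = FALSE)
  if (max(abs(image$spacing - mask$spacing)) > 1e-6)
    stop("mask and image voxel spacings differ", call. = FALSE)
  invisible(TRUE)
}

#' Volume of a mask by voxel counting
#'
#' Counts the voxels inside the mask and multiplies by the physical voxel
#' volume; the result is in cm^3. An empty mask has volume 0.
#'
#' @param mask a \code{\link{vol_mask}}.
#' @return Volume in cm^3.
#' @export
voxel_count_volume <- function(mask) {
  stopifnot(inherits(mask, "vol_mask"))
  sum(mask$values) * prod(mask$spacing) / 1000
}

#' Per-slice delineated areas with a common slice thickness
#'
#' @param areas_mm2 numeric vector of per-slice delineated areas in mm^2.
#' @param thickness_mm slice thickness in mm.
#' @return An object of class \code{slice_area_series}.
#' @export
slice_area_series <- function(areas_mm2, thickness_mm) {
  areas_mm2 <- as.numeric(areas_mm2)
  if (length(areas_mm2) == 0L)
    stop("empty slice-area series", call. = FALSE)
  if (anyNA(areas_mm2) || any(areas_mm2 < 0))
    stop("slice areas must be non-negative", call. = FALSE)
  thickness_mm <- as.numeric(thickness_mm)
  if (length(thickness_mm) != 1L || is.na(thickness_mm) || thickness_mm <= 0)
    stop("slice thickness must be a single positive value in mm",
         call. = FALSE)
  structure(list(areas_mm2 = areas_mm2, thickness_mm = thickness_mm),
            class = "slice_area_series")
}

#' Planimetric volume from per-slice areas
#'
#' Sums the delineated cross-sectional areas and multiplies by the slice
#' thickness, the standard planimetric volumetry used for anatomical
#' tumour volume (ATV) and manual functional tumour volume.
#'
#' @param areas a \code{\link{slice_area_series}}.
#' @return Volume in cm^3.
#' @export
planimetric_volume <- function(areas) {
  stopifnot(inherits(areas, "slice_area_series"))
  sum(areas$areas_mm2) * areas$thickness_mm / 1000
}

#' Per-slice areas of a mask
#'
#' In-plane area per slice computed as in-plane voxel count times in-plane
#' voxel area, so that \code{planimetric_volume(mask_slice_areas(m))} equals
#' \code{voxel_count_volume(m)} exactly on a shared grid.
#'
#' @param mask a \code{\link{vol_mask}}; the first axis indexes slices.
#' @return A \code{\link{slice_area_series}}.
#' @export
mask_slice_areas <- function(mask) {
  stopifnot(inherits(mask, "vol_mask"))
  counts <- apply(mask$values, 1L, sum)
  slice_area_series(counts * mask$spacing[2] * mask$spacing[3],
                    mask$spacing[1])
}

#' Average two readers' volume estimates
#'
#' The two independently delineated volumes are combined by their
#' arithmetic mean, as done for both ATV and FTV.
#'
#' @param volume_a,volume_b volumes in cm^3, both non-negative.
#' @return Mean volume in cm^3.
#' @export
reader_average <- function(volume_a, volume_b) {
  if (any(c(volume_a, volume_b) < 0) || anyNA(c(volume_a, volume_b)))
    stop("volumes must be non-negative", call. = FALSE)
  (volume_a + volume_b) / 2
}
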