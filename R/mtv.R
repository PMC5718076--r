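#' Maximum SUV inside a volume of interest
#'
#' The single hottest voxel value inside the VOI; no peak averaging.
#' High-uptake structures outside the VOI (typically the urinary bladder)
#' cannot influence the result.
#'
#' @param volume an \code{\link{image_volume}} of SUV values.
#' @param voi a non-empty \code{\link{vol_mask}} on the same grid.
#' @return SUVmax (dimensionless).
#' @export
suv_max <- function(volume, voi) {
  stopifnot(inherits(volume, "image_volume"))
  stopifnot(inherits(voi, "vol_mask"))
  check_same_grid(volume, voi)
  if (!any(voi$values)) stop("the VOI is empty", call. = FALSE)
  max(volume$values[voi$values])
}

#' Metabolic tumour volume at one percent-of-SUVmax threshold
#'
#' Volume of the VOI voxels whose SUV is at or above
#' \code{percent}/100 of the SUVmax computed over the same VOI. The
#' comparison is inclusive (ties at the threshold are kept) and no
#' connected-component filtering is applied: the VOI itself provides the
#' spatial gating.
#'
#' @param volume an \code{\link{image_volume}} of SUV values.
#' @param voi a non-empty \code{\link{vol_mask}} on the same grid.
#' @param percent threshold as an integer percent in (0, 100].
#' @return Volume in cm^3.
#' @export
mtv_at_threshold <- function(volume, voi, percent) {
  if (length(percent) != 1L || is.na(percent) || percent <= 0 ||
      percent > 100)
    stop("percent must be a single value in (0, 100]", call. = FALSE)
  smax <- suv_max(volume, voi)
  keep <- voi$values & (volume$values >= (percent / 100) * smax)
  voxel_count_volume(vol_mask(keep, voi$spacing))
}

#' Metabolic tumour volume sweep over percent thresholds
#'
#' Computes the MTV at every threshold in \code{thresholds} (default
#' 20, 25, ..., 80 percent of SUVmax, 13 thresholds). Because the
#' superlevel sets are nested, the volumes are non-increasing in the
#' threshold, and the SUVmax voxel itself always survives.
#'
#' @param volume an \code{\link{image_volume}} of SUV values.
#' @param voi a non-empty \code{\link{vol_mask}} on the same grid.
#' @param thresholds integer percents in (0, 100].
#' @return An object of class \code{mtv_sweep} with elements
#'   \code{suv_max}, \code{thresholds} and \code{volumes_cm3}.
#' @export
mtv_sweep <- function(volume, voi, thresholds = seq(20, 80, by = 5)) {
  if (length(thresholds) == 0L)
    stop("thresholds must be non-empty", call. = FALSE)
  smax <- suv_max(volume, voi)
  rel <- volume$values[voi$values] / smax
  vox_cm3 <- prod(voi$spacing) / 1000
  vols <- vapply(thresholds, function(t) {
    if (t <= 0 || t > 100)
      stop("percent must be a single value in (0, 100]", call. = FALSE)
    sum(rel >= t / 100) * vox_cm3
  }, numeric(1))
  structure(list(suv_max = smax,
                 thresholds = as.numeric(thresholds),
                 volumes_cm3 = vols),
            class = "mtv_sweep")
}

#' @export
print.mtv_sweep <- function(x, ...) {
  cat(sprintf("<mtv_sweep> SUVmax = %.1f\n", x$suv_max))
  print(data.frame(threshold_percent = x$thresholds,
                   volume_cm3 = round_half_up(x$volumes_cm3, 1)),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.mtv_sweep <- function(x, ...) {
  data.frame(threshold_percent = x$thresholds,
             volume_cm3 = x$volumes_cm3)
}

#' @export
plot.mtv_sweep <- function(x, ...) {
  plot(x$thresholds, x$volumes_cm3, type = "b", pch = 16,
       xlab = "threshold (% of SUVmax)", ylab = expression(MTV~(cm^3)),
       ...)
  invisible(x)
}
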