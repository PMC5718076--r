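#' Manual functional tumour volume
#'
#' Volume of a manually delineated tumour mask, by voxel counting
#' (equivalent to per-slice area times slice thickness on a shared grid).
#'
#' @param tumour_mask a \code{\link{vol_mask}}.
#' @return Volume in cm^3; 0 with a warning for an empty mask.
#' @export
ftv_manual <- function(tumour_mask) {
  stopifnot(inherits(tumour_mask, "vol_mask"))
  if (!any(tumour_mask$values)) {
    warning("manual tumour mask is empty; FTV = 0", call. = FALSE)
    return(0)
  }
  voxel_count_volume(tumour_mask)
}

tissue_classes <- c("fat_fibrotic", "tumour", "normal_cystic")

#' K-means tissue clustering on (S0, ADC) features
#'
#' Partitions the VOI voxels into \code{k} clusters by K-means on the
#' two-dimensional feature vector (fitted S0, ADC). Each feature is
#' z-scored over the VOI before clustering (raw S0 and ADC differ by
#' orders of magnitude and Euclidean K-means is scale-sensitive), so any
#' positive affine rescaling of either feature leaves the labels
#' unchanged. The best of \code{n_init} restarts by within-cluster sum of
#' squares is kept, and the result is deterministic given \code{seed};
#' the global R random stream is left untouched.
#'
#' @param voi a \code{\link{vol_mask}} with at least \code{k} voxels.
#' @param s0_map,adc_map 3D arrays on the VOI grid (e.g. the \code{s0}
#'   and \code{adc} fields of an \code{\link{fit_adc}} result).
#' @param k number of clusters; the three-tissue model uses 3.
#' @param seed integer seed making the restarts reproducible.
#' @param n_init number of random restarts (default 10).
#' @param standardize z-score the features over the VOI (default TRUE).
#' @return An object of class \code{tissue_clusters}: per-VOI-voxel
#'   \code{labels}, per-cluster \code{centroids} in original (s0, adc)
#'   units, the within-cluster sum of squares, and for k = 3 the
#'   \code{tissue_assignment} from \code{\link{assign_clusters}}.
#' @export
kmeans_segment <- function(voi, s0_map, adc_map, k = 3L, seed = 1L,
                           n_init = 10L, standardize = TRUE) {
  stopifnot(inherits(voi, "vol_mask"))
  if (!identical(dim(s0_map), dim(voi$values)) ||
      !identical(dim(adc_map), dim(voi$values)))
    stop("s0 and adc maps must share the VOI grid", call. = FALSE)
  inside <- voi$values
  X <- cbind(s0 = as.vector(s0_map[inside]),
             adc = as.vector(adc_map[inside]))
  if (anyNA(X))
    stop("NA feature values inside the VOI; fit or mask them first",
         call. = FALSE)
  uX <- unique(X)
  if (nrow(uX) < k)
    stop(sprintf("fewer than k = %d distinct (s0, adc) vectors in the VOI",
                 k), call. = FALSE)

  Z <- X
  if (standardize) {
    for (j in 1:2) {
      s <- stats::sd(Z[, j])
      Z[, j] <- (Z[, j] - mean(Z[, j])) / (if (s > 0) s else 1)
    }
  }

  if (nrow(uX) == k) {
    # exactly k distinct feature vectors: the optimal partition is the
    # one-cluster-per-vector assignment; random restarts would only risk
    # sampling duplicate initial centres
    uZ <- unique(Z)
    km <- stats::kmeans(Z, centers = uZ, iter.max = 100L)
  } else {
    km <- with_seed(seed, stats::kmeans(Z, centers = k, nstart = n_init,
                                        iter.max = 100L))
  }

  # centroids in original units, by averaging the member voxels
  cent <- t(vapply(seq_len(k), function(cl) {
    colMeans(X[km$cluster == cl, , drop = FALSE])
  }, numeric(2)))
  colnames(cent) <- c("s0", "adc")

  out <- structure(list(
    k = k,
    labels = km$cluster,
    centroids = cent,
    tot_withinss = km$tot.withinss,
    voi_index = which(inside),
    grid_dim = dim(voi$values),
    spacing = voi$spacing,
    seed = seed,
    n_init = n_init,
    standardized = standardize
  ), class = "tissue_clusters")
  if (k == 3L) out$tissue_assignment <- assign_clusters(out)
  out
}

#' Map clusters to the three tissue classes
#'
#' Ranks the three cluster centroids by their (un-standardised) ADC:
#' the lowest-ADC cluster is labelled fat/fibrotic tissue, the middle
#' cluster solid tumour (high cellularity, intermediate ADC and S0), and
#' the highest-ADC cluster normal or cystic tissue. Exact ADC ties are
#' broken by the S0 centroid: the lower-S0 cluster takes the lower-ADC
#' role.
#'
#' @param model a \code{\link{kmeans_segment}} result with k = 3.
#' @return Named integer vector mapping each tissue class
#'   (\code{fat_fibrotic}, \code{tumour}, \code{normal_cystic}) to its
#'   cluster index.
#' @export
assign_clusters <- function(model) {
  stopifnot(inherits(model, "tissue_clusters"))
  if (model$k != 3L)
    stop("tissue assignment is defined for k = 3 clusters", call. = FALSE)
  ord <- order(model$centroids[, "adc"], model$centroids[, "s0"])
  stats::setNames(ord, tissue_classes)
}

#' @export
print.tissue_clusters <- function(x, ...) {
  cat("<tissue_clusters> k =", x$k, "on", length(x$labels),
      "VOI voxels (seed", x$seed, ",", x$n_init, "restarts)\n")
  cent <- data.frame(cluster = seq_len(x$k),
                     s0 = round(x$centroids[, "s0"], 1),
                     adc_1e3 = round(1000 * x$centroids[, "adc"], 3),
                     n_voxels = as.vector(table(factor(x$labels,
                                                       seq_len(x$k)))))
  if (!is.null(x$tissue_assignment)) {
    tis <- character(x$k)
    tis[x$tissue_assignment] <- names(x$tissue_assignment)
    cent$tissue <- tis
  }
  print(cent, row.names = FALSE)
  invisible(x)
}

#' Per-tissue-class masks from a clustering
#'
#' @param model a \code{\link{kmeans_segment}} result with k = 3.
#' @return Named list of \code{\link{vol_mask}} objects, one per tissue
#'   class; together they partition the VOI.
#' @export
cluster_masks <- function(model) {
  stopifnot(inherits(model, "tissue_clusters"))
  assign <- model$tissue_assignment
  if (is.null(assign)) assign <- assign_clusters(model)
  out <- lapply(assign, function(cl) {
    v <- array(FALSE, dim = model$grid_dim)
    v[model$voi_index[model$labels == cl]] <- TRUE
    vol_mask(v, model$spacing)
  })
  names(out) <- names(assign)
  out
}

#' Semi-automated functional tumour volume
#'
#' Clusters the VOI voxels into the three tissue classes with
#' \code{\link{kmeans_segment}}, discards the fat/fibrotic and
#' normal/cystic clusters, and returns the volume of the retained solid
#' tumour cluster.
#'
#' @inheritParams kmeans_segment
#' @return Volume in cm^3, with the fitted \code{tissue_clusters} model
#'   attached as attribute \code{"model"}.
#' @export
ftv_semi_automated <- function(voi, s0_map, adc_map, seed = 1L,
                               n_init = 10L, standardize = TRUE) {
  model <- kmeans_segment(voi, s0_map, adc_map, k = 3L, seed = seed,
                          n_init = n_init, standardize = standardize)
  tum <- model$tissue_assignment[["tumour"]]
  vox_cm3 <- prod(voi$spacing) / 1000
  vol <- sum(model$labels == tum) * vox_cm3
  attr(vol, "model") <- model
  vol
}

#' Dice overlap coefficient between two masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 1 for identical non-empty masks.
#'
#' @param a,b \code{\link{vol_mask}} objects on the same grid.
#' @return Dice coefficient in [0, 1]; NaN if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "vol_mask"), inherits(b, "vol_mask"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("masks must share a grid", call. = FALSE)
  2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}
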